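# Delimited-table readers/writers and JSON serialization for models and
# comparison reports.
#
# Table dialect: plain text, tab- or comma-delimited (sniffed from the
# header line), one header row, first column `subject_id`, remaining
# columns numeric. Missing values are schema errors -- complete cases
# only, no imputation. This is the package's own documented dialect; a
# site-specific exporter (e.g. a NeuroGuide connectivity dump) can be
# adapted to it upstream.

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

read_validated_table <- function(path) {
  if (!file.exists(path)) stop_schema(sprintf("file not found: %s", path))
  delim <- sniff_delim(path)
  raw <- readr::read_delim(path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, trim_ws = TRUE
  )
  if (!identical(names(raw)[1], "subject_id")) {
    stop_schema(sprintf(
      "first column must be `subject_id` (got `%s`) in %s.", names(raw)[1], path
    ))
  }
  for (col in setdiff(names(raw), "subject_id")) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(parsed))
    if (length(bad)) {
      stop_schema(sprintf(
        "non-numeric or missing value in column `%s`, row %d (subject `%s`) of %s.",
        col, bad[1], raw$subject_id[bad[1]], path
      ))
    }
    raw[[col]] <- parsed
  }
  raw
}

#' Read a connectivity feature table
#'
#' Reads a delimited text file (tab or comma, sniffed) with a header row,
#' a `subject_id` first column and one numeric column per connectivity
#' feature. Duplicate ids, duplicate labels, and missing or non-numeric
#' cells are schema errors (complete cases only; nothing is imputed).
#'
#' @param path Path to the file.
#' @return Tibble: `subject_id` plus numeric feature columns, row order
#'   preserved.
#' @export
read_connectivity_table <- function(path) {
  tbl <- read_validated_table(path)
  table_to_matrix(tbl, min_rows = 1L, min_cols = 2L) # validation only
  tbl
}

#' Read a behavioral score table
#'
#' Two columns: `subject_id` and `score`.
#'
#' @param path Path to the file.
#' @return Tibble with columns `subject_id`, `score`.
#' @export
read_behavior_table <- function(path) {
  tbl <- read_validated_table(path)
  if (!identical(names(tbl), c("subject_id", "score"))) {
    stop_schema(sprintf(
      "behavior table must have exactly the columns `subject_id`, `score` (got: %s).",
      paste(names(tbl), collapse = ", ")
    ))
  }
  behavior_to_vector(tbl) # validation only
  tbl
}

#' Write a connectivity or behavior table
#'
#' Tab-separated text with full floating-point round-trip precision, so
#' write-then-read reproduces the values exactly.
#'
#' @param tbl The table (as returned by [generate_cohort()] or the
#'   readers).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(tbl, path) {
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Serialize an unmixing model to JSON
#'
#' Writes every matrix (standardization, sphere, ICA weights, total
#' transform), the labels, the fit configuration and the seed as a JSON
#' document for audit and later re-projection.
#'
#' @param model A `covica_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_unmixing_model()]
#' @export
write_unmixing_model <- function(model, path) {
  stopifnot(inherits(model, "covica_model"))
  payload <- list(
    kind = model$kind,
    n_features_total = model$n_features_total,
    feature_labels = model$feature_labels,
    covariate_column = model$covariate_column,
    standardization = list(
      mean = unname(model$standardization$mean),
      sd = unname(model$standardization$sd)
    ),
    sphere = model$sphere,
    ica_weights = model$ica_weights,
    total_transform = model$total_transform,
    converged = model$converged,
    iterations = model$iterations,
    config = unclass(model$config),
    seed = model$seed,
    subject_ids = model$subject_ids
  )
  jsonlite::write_json(payload, path,
    digits = NA, auto_unbox = TRUE, null = "null", matrix = "rowmajor"
  )
  invisible(path)
}

#' Read an unmixing model from JSON
#'
#' @param path Path written by [write_unmixing_model()].
#' @return A `covica_model` (without training sources, which are not
#'   serialized; all projection functionality is available).
#' @export
read_unmixing_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  std <- structure(
    list(
      mean = stats::setNames(
        p$standardization$mean,
        c(p$feature_labels, if (p$kind == "augmented") .covariate_label)
      ),
      sd = stats::setNames(
        p$standardization$sd,
        c(p$feature_labels, if (p$kind == "augmented") .covariate_label)
      )
    ),
    class = "covica_standardization"
  )
  structure(
    list(
      kind = p$kind,
      n_features_total = p$n_features_total,
      feature_labels = p$feature_labels,
      covariate_column = p$covariate_column,
      standardization = std,
      sphere = p$sphere,
      ica_weights = p$ica_weights,
      total_transform = p$total_transform,
      converged = p$converged,
      iterations = p$iterations,
      config = do.call(ica_config, p$config),
      seed = p$seed,
      subject_ids = p$subject_ids,
      training_sources = NULL
    ),
    class = "covica_model"
  )
}

#' Write a comparison report to disk
#'
#' Writes `report.json` (summary statistics, histograms, resolved run
#' configuration and master seed) and `iterations.tsv` (per-iteration
#' jackknife records with the paired differences) into `dir`.
#'
#' @param report A `covica_comparison`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_comparison_report <- function(report, dir) {
  stopifnot(inherits(report, "covica_comparison"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- report$config
  payload <- list(
    n_iterations = report$n_iterations,
    n_excluded = report$n_excluded,
    p_tests = report$p_tests,
    r2_tests = report$r2_tests,
    pooled_oos = report$pooled_oos,
    hist_delta_p = report$hist_delta_p,
    hist_delta_r2 = report$hist_delta_r2,
    n_permutations = report$n_permutations,
    seed = report$seed,
    config = list(
      ica = unclass(cfg$ica),
      projection = cfg$projection,
      evaluation_set = cfg$evaluation_set,
      n_permutations = cfg$n_permutations,
      alternative = cfg$alternative,
      histogram_bins = cfg$histogram_bins
    )
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
    digits = NA, auto_unbox = TRUE, null = "null"
  )
  readr::write_tsv(tidy(report), file.path(dir, "iterations.tsv"), progress = FALSE)
  invisible(dir)
}
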