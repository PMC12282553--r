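# Shared validation helpers and error conditions.
#
# All user-facing errors carry a subclass so callers (and the CLI) can react
# programmatically:
#   covica_error_parameter   -- invalid argument values
#   covica_error_schema      -- malformed tables / id or label mismatches
#   covica_error_degenerate  -- constant features, zero-variance inputs
#   covica_error_rank        -- rank-deficient covariance (n too small)
#   covica_error_sample_size -- too few observations for a statistic

stop_parameter <- function(msg) abort(msg, class = "covica_error_parameter")
stop_schema <- function(msg) abort(msg, class = "covica_error_schema")
stop_degenerate <- function(msg) abort(msg, class = "covica_error_degenerate")
stop_rank <- function(msg) abort(msg, class = "covica_error_rank")
stop_sample_size <- function(msg) abort(msg, class = "covica_error_sample_size")

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_scalar_int <- function(x, name, min = 1L) {
  if (!is_scalar_number(x) || x != as.integer(x) || x < min) {
    stop_parameter(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

# Derive a per-task seed from a master seed; kept inside 32-bit integer range.
derive_seed <- function(master_seed, index) {
  as.integer((as.double(master_seed) + 7919 * as.double(index)) %%
    .Machine$integer.max)
}

#' Extract the numeric matrix from a subjects-by-features tibble
#'
#' Connectivity and behavior tables are plain tibbles whose first column is
#' `subject_id`; the remaining columns are numeric. This helper validates the
#' layout and returns the numeric part as a matrix with subject ids as row
#' names.
#'
#' @param tbl A data frame with a `subject_id` first column.
#' @param min_rows Minimum number of subjects required.
#' @param min_cols Minimum number of numeric columns required.
#' @return A numeric matrix (subjects x features).
#' @keywords internal
#' @noRd
table_to_matrix <- function(tbl, min_rows = 3L, min_cols = 1L) {
  if (!is.data.frame(tbl) || !identical(names(tbl)[1], "subject_id")) {
    stop_schema("expected a data frame whose first column is `subject_id`.")
  }
  ids <- as.character(tbl[["subject_id"]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop_schema(sprintf(
      "duplicate subject ids: %s.", paste(dup, collapse = ", ")
    ))
  }
  vals <- tbl[setdiff(names(tbl), "subject_id")]
  if (ncol(vals) < min_cols) {
    stop_schema(sprintf("at least %d feature column(s) required.", min_cols))
  }
  not_num <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(not_num)) {
    stop_schema(sprintf(
      "non-numeric feature column(s): %s.", paste(not_num, collapse = ", ")
    ))
  }
  m <- as.matrix(vals)
  if (anyNA(m) || !all(is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, , drop = TRUE]
    stop_schema(sprintf(
      "missing or non-finite value at subject `%s`, column `%s` (no imputation is performed).",
      ids[bad[1]], colnames(m)[bad[2]]
    ))
  }
  if (nrow(m) < min_rows) {
    stop_schema(sprintf("at least %d subjects required, got %d.", min_rows, nrow(m)))
  }
  if (anyDuplicated(colnames(m))) {
    stop_schema("feature labels must be unique.")
  }
  rownames(m) <- ids
  m
}

check_matched_ids <- function(ids_a, ids_b, what_a = "connectivity", what_b = "behavior") {
  if (!identical(as.character(ids_a), as.character(ids_b))) {
    only_a <- setdiff(ids_a, ids_b)
    only_b <- setdiff(ids_b, ids_a)
    detail <- c(
      if (length(only_a)) sprintf("only in %s: %s", what_a, paste(head(only_a, 5), collapse = ", ")),
      if (length(only_b)) sprintf("only in %s: %s", what_b, paste(head(only_b, 5), collapse = ", "))
    )
    if (!length(detail)) detail <- "same ids but different order"
    stop_schema(sprintf(
      "subject ids of %s and %s tables must match exactly (%s).",
      what_a, what_b, paste(detail, collapse = "; ")
    ))
  }
  invisible(TRUE)
}
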