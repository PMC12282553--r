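# Method 1 (plain ICA on the connectivity table) and Method 2 (ICA on the
# table augmented with the standardized behavioral covariate), plus the
# leakage-free held-out projection shared by both.

.covariate_label <- "behavior_score"

new_unmixing_model <- function(kind, feature_labels, covariate_column,
                               standardization, sphere, ica, subject_ids,
                               training_sources) {
  total <- ica$weights %*% sphere
  structure(
    list(
      kind = kind,
      n_features_total = ncol(total),
      feature_labels = feature_labels,
      covariate_column = covariate_column,
      standardization = standardization,
      sphere = sphere,
      ica_weights = ica$weights,
      total_transform = total,
      converged = ica$converged,
      iterations = ica$iterations,
      config = ica$config,
      seed = ica$seed,
      subject_ids = subject_ids,
      training_sources = training_sources
    ),
    class = "covica_model"
  )
}

fit_ica_pipeline <- function(X, config, seed) {
  std <- fit_standardization(X)
  Z <- apply_standardization(std, X)
  sphere <- fit_whitening(Z)
  ica <- infomax_ica(Z %*% sphere, config = config, seed = seed)
  list(std = std, Z = Z, sphere = sphere, ica = ica)
}

#' Fit plain ICA on a connectivity table (Method 1)
#'
#' Standardizes each connectivity feature (z-score), applies symmetric
#' whitening, and runs Infomax ICA, yielding one independent component per
#' feature. The model stores the full linear map from raw feature space to
#' component space (`total_transform`, applied after standardization), so
#' held-out subjects can be projected without refitting.
#'
#' @param connectivity Tibble: `subject_id` plus `m >= 2` numeric feature
#'   columns; requires more subjects than features.
#' @param config An [ica_config()].
#' @param seed Integer seed for the ICA fit.
#' @return An unmixing model (class `covica_model`, kind `"plain"`) with
#'   `m` components.
#' @seealso [fit_method2()], [project_heldout()]
#' @examples
#' cohort <- generate_cohort(synthetic_params(n_subjects = 60, n_features = 5, seed = 2))
#' m1 <- fit_method1(cohort$connectivity, seed = 2)
#' glance(m1)
#' @export
fit_method1 <- function(connectivity, config = ica_config(), seed = 1L) {
  X <- table_to_matrix(connectivity, min_cols = 2L)
  if (nrow(X) <= ncol(X)) {
    stop_rank(sprintf(
      "Method 1 needs more subjects (%d) than features (%d).", nrow(X), ncol(X)
    ))
  }
  parts <- fit_ica_pipeline(X, config, seed)
  total <- parts$ica$weights %*% parts$sphere
  new_unmixing_model(
    kind = "plain",
    feature_labels = colnames(X),
    covariate_column = NULL,
    standardization = parts$std,
    sphere = parts$sphere,
    ica = parts$ica,
    subject_ids = rownames(X),
    training_sources = total %*% t(parts$Z)
  )
}

#' Fit covariate-augmented ICA (Method 2)
#'
#' Appends the behavioral score as one extra feature column (z-scored with
#' the training sample's mean and SD, putting it on the same footing as the
#' standardized connectivity values), then fits ICA on all `m + 1` columns.
#' The decomposition can thus be steered by the covariate, while held-out
#' evaluation through [project_heldout()] uses only the connectivity
#' weights.
#'
#' @param connectivity Tibble: `subject_id` plus `m` numeric feature
#'   columns.
#' @param behavior Tibble: `subject_id`, `score`; ids must match
#'   `connectivity` exactly (same order).
#' @param config An [ica_config()].
#' @param seed Integer seed for the ICA fit.
#' @return An unmixing model (class `covica_model`, kind `"augmented"`)
#'   with `m + 1` components; the covariate occupies the last column
#'   (`covariate_column`).
#' @examples
#' cohort <- generate_cohort(synthetic_params(n_subjects = 60, n_features = 5, seed = 2))
#' m2 <- fit_method2(cohort$connectivity, cohort$behavior, seed = 2)
#' m2$covariate_column
#' @export
fit_method2 <- function(connectivity, behavior, config = ica_config(), seed = 1L) {
  X <- table_to_matrix(connectivity, min_cols = 2L)
  J <- behavior_to_vector(behavior)
  check_matched_ids(rownames(X), names(J))
  Xa <- cbind(X, matrix(J, ncol = 1, dimnames = list(NULL, .covariate_label)))
  if (nrow(Xa) <= ncol(Xa)) {
    stop_rank(sprintf(
      "Method 2 needs more subjects (%d) than augmented features (%d).",
      nrow(Xa), ncol(Xa)
    ))
  }
  parts <- fit_ica_pipeline(Xa, config, seed)
  total <- parts$ica$weights %*% parts$sphere
  new_unmixing_model(
    kind = "augmented",
    feature_labels = colnames(X),
    covariate_column = ncol(Xa),
    standardization = parts$std,
    sphere = parts$sphere,
    ica = parts$ica,
    subject_ids = rownames(X),
    training_sources = total %*% t(parts$Z)
  )
}

behavior_to_vector <- function(behavior) {
  if (!is.data.frame(behavior) ||
    !all(c("subject_id", "score") %in% names(behavior))) {
    stop_schema("`behavior` must be a data frame with columns `subject_id` and `score`.")
  }
  ids <- as.character(behavior$subject_id)
  if (anyDuplicated(ids)) {
    stop_schema(sprintf(
      "duplicate subject ids in behavior table: %s.",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  scores <- behavior$score
  if (!is.numeric(scores) || anyNA(scores) || !all(is.finite(scores))) {
    stop_schema("behavior scores must be finite numbers (complete cases only).")
  }
  stats::setNames(as.numeric(scores), ids)
}

sources_to_tibble <- function(S, subject_ids) {
  k <- nrow(S)
  out <- tibble::as_tibble(t(S), .name_repair = "minimal")
  names(out) <- sprintf("IC%d", seq_len(k))
  dplyr::bind_cols(tibble::tibble(subject_id = subject_ids), out)
}

#' Project subjects through a fitted unmixing model
#'
#' Applies the model's full linear map (standardization, then
#' `total_transform`) to a table whose columns match everything the model
#' was trained on. For augmented models this requires a `behavior_score`
#' column; use [project_heldout()] for the leakage-free evaluation rule.
#'
#' @param model A `covica_model`.
#' @param newdata Tibble: `subject_id` plus exactly the model's training
#'   columns (for augmented models, including `behavior_score`).
#' @return Tibble of sources: `subject_id` plus one column per component
#'   (`IC1`, `IC2`, ...).
#' @seealso [project_heldout()]
#' @export
unmix <- function(model, newdata) {
  stopifnot(inherits(model, "covica_model"))
  X <- table_to_matrix(newdata, min_rows = 1L)
  expected <- c(
    model$feature_labels,
    if (model$kind == "augmented") .covariate_label
  )
  if (!identical(colnames(X), expected)) {
    stop_schema(sprintf(
      "column labels do not match the model (expected %d columns ending with %s).",
      length(expected), expected[length(expected)]
    ))
  }
  Z <- apply_standardization(model$standardization, X)
  sources_to_tibble(model$total_transform %*% t(Z), rownames(X))
}

#' Leakage-free held-out projection
#'
#' Computes component sources for held-out subjects from their
#' connectivity alone. For plain models this is the ordinary projection.
#' For augmented models the covariate channel is fixed at its training
#' mean (0 after standardization) -- equivalently, only the `m`
#' connectivity columns of the transform are applied -- so held-out
#' behavior scores are never consulted and cannot leak into their own
#' predictor.
#'
#' @param model A `covica_model`.
#' @param connectivity Tibble: `subject_id` plus exactly the model's
#'   connectivity feature columns (no behavior needed or used). One or
#'   more subjects.
#' @param projection `"connectivity_only"` (default) or `"full"`. `"full"`
#'   applies the literal augmented map and therefore requires a
#'   `behavior_score` column; it leaks the held-out score and is provided
#'   for comparison only (a warning is issued).
#' @return Tibble of sources: `subject_id` plus `IC1..ICk` columns
#'   (`k = m` for plain models, `m + 1` for augmented).
#' @examples
#' cohort <- generate_cohort(synthetic_params(n_subjects = 60, n_features = 5, seed = 2))
#' m2 <- fit_method2(cohort$connectivity, cohort$behavior, seed = 2)
#' project_heldout(m2, cohort$connectivity[1:3, ])
#' @export
project_heldout <- function(model, connectivity,
                            projection = c("connectivity_only", "full")) {
  stopifnot(inherits(model, "covica_model"))
  projection <- match.arg(projection)
  if (projection == "full") {
    if (model$kind == "augmented") {
      warn(paste(
        "full projection feeds held-out behavior scores into their own",
        "predictor; use it for diagnostics only."
      ))
    }
    return(unmix(model, connectivity))
  }
  X <- table_to_matrix(connectivity, min_rows = 1L)
  if (!identical(colnames(X), model$feature_labels)) {
    stop_schema("connectivity column labels do not match the model's feature labels.")
  }
  if (model$kind == "augmented") {
    m <- length(model$feature_labels)
    std_conn <- list(
      mean = model$standardization$mean[seq_len(m)],
      sd = model$standardization$sd[seq_len(m)]
    )
    Z <- cbind(apply_standardization(std_conn, X), 0)
  } else {
    Z <- apply_standardization(model$standardization, X)
  }
  sources_to_tibble(model$total_transform %*% t(Z), rownames(X))
}

#' @export
print.covica_model <- function(x, ...) {
  cat(sprintf(
    "<covica_model> %s ICA: %d components over %d feature(s)%s\n  fit on %d subjects; converged: %s (%d sweeps), seed %d\n",
    x$kind, x$n_features_total, length(x$feature_labels),
    if (x$kind == "augmented") " + 1 covariate" else "",
    length(x$subject_ids), x$converged, x$iterations, x$seed
  ))
  invisible(x)
}

#' @describeIn fit_method1 Long tibble of the model's total linear map:
#'   one row per (component, input column) with the applied weight.
#' @param x,object A `covica_model`.
#' @param ... Unused.
#' @method tidy covica_model
#' @export
tidy.covica_model <- function(x, ...) {
  labels <- c(x$feature_labels, if (x$kind == "augmented") .covariate_label)
  tibble::tibble(
    component = rep(sprintf("IC%d", seq_len(x$n_features_total)), times = length(labels)),
    feature = rep(labels, each = x$n_features_total),
    weight = as.vector(x$total_transform)
  )
}

#' @describeIn fit_method1 One-row model summary.
#' @method glance covica_model
#' @export
glance.covica_model <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    n_components = x$n_features_total,
    n_features = length(x$feature_labels),
    n_subjects = length(x$subject_ids),
    converged = x$converged,
    iterations = x$iterations,
    seed = x$seed
  )
}
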