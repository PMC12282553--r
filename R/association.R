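# Component-behavior association: Pearson correlation with exact two-sided
# p-values, and the max-absolute-correlation selection statistic rho_max.

#' Pearson correlation with exact two-sided p-value
#'
#' Computes `r = cov(x, y) / (sd(x) sd(y))` and its exact two-sided
#' p-value from `t = r sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of
#' freedom. A perfect correlation (`|r| = 1`) is assigned `p = 0` by
#' convention.
#'
#' @param x,y Numeric vectors of equal length `>= 3`, neither constant.
#' @return One-row tibble with columns `r`, `p`, `df`.
#' @examples
#' pearson(c(1, 2, 3), c(1, 3, 2)) # r = 0.5, p = 2/3 exactly
#' @export
pearson <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    stop_parameter("`x` and `y` must be numeric vectors of equal length.")
  }
  n <- length(x)
  if (n < 3L) stop_sample_size("at least 3 paired observations are required.")
  if (anyNA(x) || anyNA(y)) stop_schema("missing values are not allowed.")
  if (sd(x) == 0 || sd(y) == 0) {
    stop_degenerate("constant input: correlation is undefined.")
  }
  r <- cor(x, y)
  df <- n - 2L
  if (1 - r^2 <= .Machine$double.eps) {
    p <- 0
  } else {
    tval <- r * sqrt(df) / sqrt(1 - r^2)
    p <- 2 * pt(-abs(tval), df)
  }
  tibble::tibble(r = r, p = p, df = df)
}

#' Max-absolute-correlation component selection (rho_max)
#'
#' Correlates every component of a source table with the behavioral score
#' and selects the component with the largest absolute Pearson
#' correlation (ties broken toward the lowest component index). The
#' absolute value is used because ICA component signs are arbitrary. The
#' reported p-value is the uncorrected two-sided p of the selected
#' component; with `correct = TRUE` a max-statistic permutation adjustment
#' (behavior relabeling) is applied instead.
#'
#' @param sources Tibble of sources as returned by [project_heldout()]:
#'   `subject_id` plus one numeric column per component.
#' @param behavior Tibble: `subject_id`, `score`; ids must match `sources`
#'   exactly.
#' @param correct Logical; apply the max-statistic permutation correction
#'   (off by default, matching the uncorrected selection statistic).
#' @param n_permutations,seed Permutation settings used when
#'   `correct = TRUE`.
#' @return Object of class `covica_assoc` with fields `per_component`
#'   (tibble: component, r, p), `best_component`, `rho_max`, `signed_r`,
#'   `p_value`, `n_subjects`. `tidy()` returns the per-component tibble,
#'   `glance()` the one-row summary.
#' @examples
#' cohort <- generate_cohort(synthetic_params(n_subjects = 60, n_features = 5, seed = 2))
#' m1 <- fit_method1(cohort$connectivity, seed = 2)
#' a <- max_abs_association(project_heldout(m1, cohort$connectivity), cohort$behavior)
#' glance(a)
#' @export
max_abs_association <- function(sources, behavior, correct = FALSE,
                                n_permutations = 2000L, seed = 1L) {
  S <- table_to_matrix(sources, min_cols = 1L)
  J <- behavior_to_vector(behavior)
  check_matched_ids(rownames(S), names(J), "sources", "behavior")
  n <- nrow(S)
  if (n < 3L) stop_sample_size("at least 3 subjects are required.")
  if (sd(J) == 0) stop_degenerate("behavior scores are constant.")
  comp_sd <- apply(S, 2, sd)
  if (all(comp_sd == 0)) stop_degenerate("all components are constant.")
  if (any(comp_sd == 0)) {
    warn(sprintf(
      "skipping constant component(s): %s.",
      paste(colnames(S)[comp_sd == 0], collapse = ", ")
    ))
  }
  usable <- which(comp_sd > 0)
  per <- purrr::map_dfr(usable, function(i) {
    res <- pearson(S[, i], J)
    tibble::tibble(component = i, r = res$r, p = res$p)
  })
  best_row <- which.max(abs(per$r)) # which.max takes the first maximum: lowest index wins ties
  best <- per$component[best_row]
  p_sel <- per$p[best_row]
  if (correct) {
    p_sel <- max_stat_correction(S[, usable, drop = FALSE], J,
      observed = abs(per$r[best_row]),
      n_permutations = n_permutations, seed = seed
    )
  }
  structure(
    list(
      per_component = per,
      best_component = best,
      rho_max = abs(per$r[best_row]),
      signed_r = per$r[best_row],
      p_value = p_sel,
      n_subjects = n,
      corrected = isTRUE(correct)
    ),
    class = "covica_assoc"
  )
}

# Permutation null of max_i |cor(S_i, J)| under behavior relabeling.
max_stat_correction <- function(S, J, observed, n_permutations, seed) {
  withr::with_seed(seed, {
    null_max <- vapply(seq_len(n_permutations), function(b) {
      max(abs(cor(S, sample(J))))
    }, numeric(1))
  })
  (1 + sum(null_max >= observed)) / (1 + n_permutations)
}

#' @export
print.covica_assoc <- function(x, ...) {
  cat(sprintf(
    "<covica_assoc> rho_max = %.4f (component %d of %d, signed r = %.4f)\n  p = %.4g%s, n = %d\n",
    x$rho_max, x$best_component, nrow(x$per_component), x$signed_r,
    x$p_value, if (x$corrected) " (max-statistic corrected)" else " (uncorrected)",
    x$n_subjects
  ))
  invisible(x)
}

#' @method tidy covica_assoc
#' @export
tidy.covica_assoc <- function(x, ...) {
  x$per_component
}

#' @method glance covica_assoc
#' @export
glance.covica_assoc <- function(x, ...) {
  tibble::tibble(
    rho_max = x$rho_max,
    signed_r = x$signed_r,
    best_component = x$best_component,
    p_value = x$p_value,
    n_subjects = x$n_subjects,
    corrected = x$corrected
  )
}
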