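# Leave-one-out jackknife comparison of plain vs covariate-augmented ICA,
# and the statistics used to compare the two per-iteration distributions:
# paired t-test, Monte-Carlo Lilliefors normality check, and the sign-flip
# permutation test for paired differences.

#' Paired t-test on a difference vector
#'
#' Classical one-sample t-test of the paired differences against zero:
#' `t = mean(d) sqrt(n) / sd(d)` on `n - 1` degrees of freedom, two-sided.
#'
#' @param d Numeric vector of paired differences, length `>= 3`, with
#'   nonzero sample SD.
#' @return One-row tibble with columns `t`, `df`, `p`.
#' @examples
#' paired_t(c(1, 2, 3)) # t = 2*sqrt(3), df = 2
#' @export
paired_t <- function(d) {
  if (!is.numeric(d) || length(d) < 3L) {
    stop_sample_size("`d` must be a numeric vector of length >= 3.")
  }
  if (anyNA(d)) stop_schema("missing values are not allowed.")
  if (sd(d) == 0) stop_degenerate("differences have zero variance; t is undefined.")
  fit <- t.test(d)
  tibble::tibble(
    t = unname(fit$statistic),
    df = as.integer(unname(fit$parameter)),
    p = fit$p.value
  )
}

lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  Fz <- pnorm(z)
  max(seq_len(n) / n - Fz, Fz - (seq_len(n) - 1) / n)
}

lilliefors_null_table <- function(n, n_draws, seed) {
  key <- sprintf("lillie_%d_%d_%d", n, n_draws, seed)
  cached <- .covica_cache[[key]]
  if (!is.null(cached)) {
    return(cached)
  }
  withr::with_seed(seed, {
    Z <- matrix(rnorm(n * n_draws), nrow = n)
  })
  Zs <- scale(Z)
  P <- apply(Zs, 2, function(col) pnorm(sort(col)))
  i_hi <- seq_len(n) / n
  i_lo <- (seq_len(n) - 1) / n
  tab <- pmax(apply(i_hi - P, 2, max), apply(P - i_lo, 2, max))
  .covica_cache[[key]] <- tab
  tab
}

#' Monte-Carlo Lilliefors test of Gaussianity
#'
#' Kolmogorov-Smirnov test of normality with mean and SD estimated from
#' the sample (Lilliefors correction). Because the parameters are
#' estimated, the classical KS null distribution does not apply; the null
#' table is generated by Monte-Carlo simulation at the observed sample
#' size (seeded, cached per size).
#'
#' @param d Numeric vector, length `>= 5`.
#' @param n_draws Number of Monte-Carlo null draws (default 10000).
#' @param seed Seed for the null table.
#' @return The Monte-Carlo p-value (add-one estimator, so never below
#'   `1 / (n_draws + 1)`).
#' @examples
#' ks_gaussianity(rnorm(100))
#' @export
ks_gaussianity <- function(d, n_draws = 10000L, seed = 1L) {
  if (!is.numeric(d) || length(d) < 5L) {
    stop_sample_size("`d` must be a numeric vector of length >= 5.")
  }
  if (anyNA(d)) stop_schema("missing values are not allowed.")
  if (sd(d) == 0) stop_degenerate("zero-variance input.")
  n_draws <- check_scalar_int(n_draws, "n_draws", 100L)
  D <- lilliefors_stat(d)
  tab <- lilliefors_null_table(length(d), n_draws, seed)
  (1 + sum(tab >= D)) / (1 + n_draws)
}

#' Sign-flip permutation test for paired differences
#'
#' Surrogate test of the null that the paired differences are
#' symmetrically distributed around zero: the null distribution of
#' `mean(d)` is built by randomly negating each difference. All `2^n`
#' sign patterns are enumerated exactly when `n <= 20`; otherwise
#' `n_permutations` random patterns are drawn and the add-one estimator
#' `p = (1 + #{null at least as extreme}) / (1 + B)` is used.
#'
#' @param d Numeric vector of paired differences, length `>= 5`.
#' @param n_permutations Random draws when enumeration is infeasible.
#' @param seed Seed for random sign patterns.
#' @param alternative `"less"` (default; observed mean below the null,
#'   e.g. augmented-method p-values systematically smaller), `"greater"`,
#'   or `"two_sided"`.
#' @return The permutation p-value.
#' @examples
#' sign_flip_test(rep(1, 5), alternative = "greater") # 1/32, exhaustive
#' @export
sign_flip_test <- function(d, n_permutations = 10000L, seed = 1L,
                           alternative = c("less", "greater", "two_sided")) {
  if (!is.numeric(d) || length(d) < 5L) {
    stop_sample_size("`d` must be a numeric vector of length >= 5.")
  }
  if (anyNA(d)) stop_schema("missing values are not allowed.")
  alternative <- match.arg(alternative)
  n <- length(d)
  obs <- mean(d)
  eps <- 1e-12 * max(1, abs(obs))
  if (n <= 20L) {
    sums <- 0
    for (di in d) sums <- c(sums + di, sums - di)
    null_means <- sums / n
    count <- switch(alternative,
      less = sum(null_means <= obs + eps),
      greater = sum(null_means >= obs - eps),
      two_sided = sum(abs(null_means) >= abs(obs) - eps)
    )
    return(count / length(null_means))
  }
  B <- check_scalar_int(n_permutations, "n_permutations", 10L)
  withr::with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n * B, replace = TRUE), nrow = n)
  })
  null_means <- colMeans(signs * d)
  count <- switch(alternative,
    less = sum(null_means <= obs + eps),
    greater = sum(null_means >= obs - eps),
    two_sided = sum(abs(null_means) >= abs(obs) - eps)
  )
  (1 + count) / (1 + B)
}

#' Leave-one-out jackknife comparison of Method 1 and Method 2
#'
#' For each subject in turn, fits plain ICA (Method 1) and
#' covariate-augmented ICA (Method 2) on the remaining `n - 1` subjects,
#' computes each method's max-absolute-correlation association on the
#' training subjects (through the leakage-free connectivity-only
#' projection for both methods), and projects the left-out subject to
#' record their out-of-sample value on each method's selected component.
#' Per-iteration ICA seeds are derived deterministically from the master
#' seed and the iteration index. An iteration whose ICA fit fails outright
#' is recorded with `NA` statistics and later excluded from the paired
#' tests; a merely non-converged fit is used and flagged.
#'
#' @param connectivity Tibble: `subject_id` plus `m` numeric feature
#'   columns.
#' @param behavior Tibble: `subject_id`, `score`; ids matching
#'   `connectivity`.
#' @param config A [run_config()].
#' @param seed Master integer seed.
#' @return Tibble of class `covica_jackknife`, one row per subject:
#'   `iteration`, `left_out_subject`, `score`, `m1_r2`, `m1_p`, `m2_r2`,
#'   `m2_p`, `m1_oos_source`, `m2_oos_source`, `m1_converged`,
#'   `m2_converged`. The run config and master seed are attached as
#'   attributes.
#' @seealso [compare_methods()]
#' @export
jackknife_compare <- function(connectivity, behavior, config = run_config(),
                              seed = 1L) {
  if (!inherits(config, "covica_run_config")) {
    stop_parameter("`config` must be a run_config() object.")
  }
  seed <- check_scalar_int(seed, "seed", min = -.Machine$integer.max)
  X <- table_to_matrix(connectivity, min_cols = 2L)
  J <- behavior_to_vector(behavior)
  check_matched_ids(rownames(X), names(J))
  n <- nrow(X)
  if (n < 10L) stop_sample_size("jackknife needs at least 10 subjects.")

  if (config$projection == "full") {
    warn(paste(
      "projection = \"full\" feeds each held-out subject's behavior score",
      "into their own predicted sources (diagnostic mode)."
    ))
  }
  # Under the default connectivity-only rule the covariate channel is fixed
  # at the training mean, so behavior tables are never consulted at
  # projection time; the "full" diagnostic mode applies the literal
  # augmented map and therefore needs the scores appended.
  project_for_eval <- function(model, conn_tbl, beh_tbl) {
    if (config$projection == "full" && model$kind == "augmented") {
      aug <- dplyr::mutate(conn_tbl, behavior_score = beh_tbl$score)
      unmix(model, aug)
    } else {
      project_heldout(model, conn_tbl)
    }
  }

  one_iteration <- function(i) {
    train_conn <- connectivity[-i, , drop = FALSE]
    train_beh <- behavior[-i, , drop = FALSE]
    test_conn <- connectivity[i, , drop = FALSE]
    test_beh <- behavior[i, , drop = FALSE]
    eval_method <- function(fit_fun, offset) {
      model <- fit_fun(derive_seed(seed, 2L * i + offset))
      src_train <- project_for_eval(model, train_conn, train_beh)
      assoc <- max_abs_association(src_train, train_beh)
      src_test <- project_for_eval(model, test_conn, test_beh)
      # orient the selected component so its training correlation with the
      # score is positive; ICA signs are arbitrary and pooling left-out
      # values across iterations is meaningless without this alignment
      orient <- if (assoc$signed_r >= 0) 1 else -1
      list(
        r2 = assoc$rho_max^2, p = assoc$p_value,
        oos = orient * src_test[[sprintf("IC%d", assoc$best_component)]][1],
        converged = model$converged
      )
    }
    m1 <- tryCatch(
      eval_method(function(s) fit_method1(train_conn, config$ica, s), 0L),
      error = function(e) NULL
    )
    m2 <- tryCatch(
      eval_method(function(s) fit_method2(train_conn, train_beh, config$ica, s), 1L),
      error = function(e) NULL
    )
    na_res <- list(r2 = NA_real_, p = NA_real_, oos = NA_real_, converged = FALSE)
    m1 <- m1 %||% na_res
    m2 <- m2 %||% na_res
    tibble::tibble(
      iteration = i,
      left_out_subject = rownames(X)[i],
      score = unname(J[i]),
      m1_r2 = m1$r2, m1_p = m1$p,
      m2_r2 = m2$r2, m2_p = m2$p,
      m1_oos_source = m1$oos, m2_oos_source = m2$oos,
      m1_converged = m1$converged, m2_converged = m2$converged
    )
  }

  records <- purrr::map_dfr(seq_len(n), one_iteration)
  n_failed <- sum(!stats::complete.cases(records[c("m1_p", "m2_p")]))
  if (n_failed > 0) {
    inform(sprintf("%d of %d jackknife iterations failed and will be excluded.", n_failed, n))
  }
  structure(
    records,
    class = c("covica_jackknife", class(records)),
    config = config,
    seed = seed
  )
}
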