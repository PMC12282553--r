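# Aggregation of jackknife records into a comparison report: paired tests
# on the per-iteration differences, pooled out-of-sample correlations, and
# difference histograms.

delta_histogram <- function(d, bins) {
  if (length(unique(d)) == 1L) {
    edges <- seq(d[1] - 0.5, d[1] + 0.5, length.out = bins + 1)
  } else {
    edges <- seq(min(d), max(d), length.out = bins + 1)
  }
  h <- graphics::hist(d, breaks = edges, plot = FALSE, include.lowest = TRUE)
  list(edges = h$breaks, counts = h$counts)
}

paired_block <- function(d, n_permutations, alternative, perm_direction, seed) {
  degenerate <- sd(d) == 0
  tt <- if (degenerate) {
    tibble::tibble(t = NA_real_, df = length(d) - 1L, p = NA_real_)
  } else {
    paired_t(d)
  }
  ks <- if (degenerate) NA_real_ else ks_gaussianity(d, seed = derive_seed(seed, 101L))
  perm_alt <- if (alternative == "two_sided") "two_sided" else perm_direction
  perm <- sign_flip_test(d,
    n_permutations = n_permutations,
    seed = derive_seed(seed, 202L), alternative = perm_alt
  )
  list(
    mean = mean(d), t_stat = tt$t, t_df = tt$df, t_p = tt$p,
    ks_p = ks, perm_p = perm, perm_alternative = perm_alt,
    degenerate = degenerate
  )
}

#' Aggregate jackknife records into a method-comparison report
#'
#' Forms the per-iteration difference vectors `delta_p = m2_p - m1_p` and
#' `delta_r2 = m2_r2 - m1_r2` (so negative `delta_p` means the augmented
#' method was more significant), then for each difference vector runs the
#' paired t-test, the Monte-Carlo Lilliefors Gaussianity check, and the
#' sign-flip permutation test. The `delta_p` block is the headline
#' comparison; `delta_r2` is reported alongside. Pooled out-of-sample
#' correlations are computed by correlating each method's recorded
#' left-out source values against the left-out behavior scores. Iterations
#' with failed fits are dropped pairwise.
#'
#' @param records A `covica_jackknife` tibble from [jackknife_compare()].
#' @param config A [run_config()]; defaults to the config attached to
#'   `records`.
#' @param seed Seed for the Monte-Carlo components (normality null table,
#'   random sign flips); defaults to the records' master seed.
#' @return Object of class `covica_comparison`. Key fields:
#'   `n_iterations` (usable), `delta_p`, `delta_r2`, per-difference test
#'   blocks (`p_tests`, `r2_tests` with `t_stat`, `t_df`, `t_p`, `ks_p`,
#'   `perm_p`), `pooled_oos` (per-method r/p), histograms, the resolved
#'   config and seed. Use `tidy()` for per-iteration rows, `glance()` for
#'   the one-row summary, `autoplot()` for the difference histograms.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(synthetic_params(
#'   n_subjects = 30, n_features = 4,
#'   n_sources = 3, effect_size = 0.6, seed = 5
#' ))
#' rec <- jackknife_compare(cohort$connectivity, cohort$behavior, seed = 5)
#' glance(compare_methods(rec))
#' }
#' @export
compare_methods <- function(records, config = NULL, seed = NULL) {
  if (!inherits(records, "covica_jackknife")) {
    stop_parameter("`records` must come from jackknife_compare().")
  }
  config <- config %||% attr(records, "config")
  seed <- seed %||% attr(records, "seed")
  rec <- tibble::as_tibble(records)
  usable <- stats::complete.cases(rec[c("m1_r2", "m1_p", "m2_r2", "m2_p")])
  n_excluded <- sum(!usable)
  rec <- rec[usable, , drop = FALSE]
  if (nrow(rec) < 10L) {
    stop_sample_size("fewer than 10 usable jackknife iterations.")
  }
  delta_p <- rec$m2_p - rec$m1_p
  delta_r2 <- rec$m2_r2 - rec$m1_r2
  # directional readings: improvement = smaller p, larger r^2
  p_tests <- paired_block(delta_p, config$n_permutations, config$alternative,
    perm_direction = "less", seed = seed
  )
  r2_tests <- paired_block(delta_r2, config$n_permutations, config$alternative,
    perm_direction = "greater", seed = derive_seed(seed, 303L)
  )
  pooled <- purrr::map(c(m1 = "m1", m2 = "m2"), function(m) {
    src <- rec[[paste0(m, "_oos_source")]]
    ok <- stats::complete.cases(src, rec$score)
    if (sum(ok) >= 3 && sd(src[ok]) > 0 && sd(rec$score[ok]) > 0) {
      res <- pearson(src[ok], rec$score[ok])
      list(r = res$r, p = res$p, n = sum(ok))
    } else {
      list(r = NA_real_, p = NA_real_, n = sum(ok))
    }
  })
  structure(
    list(
      n_iterations = nrow(rec),
      n_excluded = n_excluded,
      iterations = rec,
      delta_p = delta_p,
      delta_r2 = delta_r2,
      p_tests = p_tests,
      r2_tests = r2_tests,
      pooled_oos = pooled,
      hist_delta_p = delta_histogram(delta_p, config$histogram_bins),
      hist_delta_r2 = delta_histogram(delta_r2, config$histogram_bins),
      n_permutations = config$n_permutations,
      config = config,
      seed = seed
    ),
    class = "covica_comparison"
  )
}

#' @export
print.covica_comparison <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<covica_comparison> %d jackknife iterations (%d excluded)\n",
      "  delta_p  (augmented - plain): mean %+.4g | t(%d) = %.3f, p = %.4g | KS p = %.4g | sign-flip p = %.4g (%s)\n",
      "  delta_r2 (augmented - plain): mean %+.4g | sign-flip p = %.4g (%s)\n",
      "  pooled out-of-sample r: plain %.3f (p = %.3g), augmented %.3f (p = %.3g)\n"
    ),
    x$n_iterations, x$n_excluded,
    x$p_tests$mean, x$p_tests$t_df, x$p_tests$t_stat, x$p_tests$t_p,
    x$p_tests$ks_p, x$p_tests$perm_p, x$p_tests$perm_alternative,
    x$r2_tests$mean, x$r2_tests$perm_p, x$r2_tests$perm_alternative,
    x$pooled_oos$m1$r, x$pooled_oos$m1$p, x$pooled_oos$m2$r, x$pooled_oos$m2$p
  ))
  invisible(x)
}

#' @describeIn compare_methods Per-iteration tibble with the paired
#'   differences appended.
#' @param x,object A `covica_comparison`.
#' @param ... Unused.
#' @method tidy covica_comparison
#' @export
tidy.covica_comparison <- function(x, ...) {
  dplyr::mutate(x$iterations, delta_r2 = x$delta_r2, delta_p = x$delta_p)
}

#' @describeIn compare_methods One-row summary of the headline tests.
#' @method glance covica_comparison
#' @export
glance.covica_comparison <- function(x, ...) {
  tibble::tibble(
    n_iterations = x$n_iterations,
    n_excluded = x$n_excluded,
    mean_delta_r2 = x$r2_tests$mean,
    mean_delta_p = x$p_tests$mean,
    t_stat = x$p_tests$t_stat,
    t_df = x$p_tests$t_df,
    t_p = x$p_tests$t_p,
    ks_p = x$p_tests$ks_p,
    perm_p = x$p_tests$perm_p,
    perm_p_r2 = x$r2_tests$perm_p,
    pooled_oos_r_m1 = x$pooled_oos$m1$r,
    pooled_oos_p_m1 = x$pooled_oos$m1$p,
    pooled_oos_r_m2 = x$pooled_oos$m2$r,
    pooled_oos_p_m2 = x$pooled_oos$m2$p,
    seed = x$seed
  )
}

#' @describeIn compare_methods Histograms of the per-iteration differences
#'   in R-squared and p-value (augmented minus plain), one facet each;
#'   negative p-value differences mean the augmented method was more
#'   significant.
#' @method autoplot covica_comparison
#' @export
autoplot.covica_comparison <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::tibble(
      `difference in R-squared (augmented - plain)` = object$delta_r2,
      `difference in p-value (augmented - plain)` = object$delta_p
    ),
    cols = dplyr::everything(),
    names_to = "metric", values_to = "difference"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$difference)) +
    ggplot2::geom_histogram(
      bins = object$config$histogram_bins,
      fill = "steelblue", colour = "white"
    ) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(
      x = "per-iteration difference (augmented - plain)",
      y = "jackknife iterations"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the jackknife difference histograms
#'
#' Convenience wrapper around [autoplot()] for a `covica_comparison`.
#'
#' @param report A `covica_comparison` object.
#' @param ... Passed to `autoplot()`.
#' @return A ggplot object.
#' @export
plot_comparison <- function(report, ...) {
  autoplot(report, ...)
}
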