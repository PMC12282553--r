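test_that("paired t-test matches the closed form", {
  res <- paired_t(c(1, 2, 3))
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2L)
  # df = 2 CDF F(t) = 1/2 + t / (2 sqrt(t^2 + 2)); two-sided p = 2 (1 - F)
  p_exact <- 2 * (1 - (0.5 + 2 * sqrt(3) / (2 * sqrt(12 + 2))))
  expect_equal(res$p, p_exact, tolerance = 1e-12)
  expect_equal(res$p, 0.0742, tolerance = 1e-3)
  expect_error(paired_t(c(0, 0, 0)), class = "covica_error_degenerate")
  expect_error(paired_t(c(1, 2)), class = "covica_error_sample_size")
  expect_equal(paired_t(rnorm(175))$df, 174L)
})

test_that("the normality check rejects uniform and accepts normal data", {
  withr::with_seed(25, {
    for (s in 1:5) {
      expect_lt(ks_gaussianity(runif(500), n_draws = 2000, seed = s), 0.01)
    }
  })
  expect_error(ks_gaussianity(c(1, 2, 3)), class = "covica_error_sample_size")
})

test_that("the normality check is calibrated at the nominal level", {
  n_rep <- 500
  rej <- withr::with_seed(26, {
    vapply(seq_len(n_rep), function(b) {
      ks_gaussianity(rnorm(60), n_draws = 2000, seed = 7) < 0.05
    }, logical(1))
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("the normality check agrees with an independent Lilliefors implementation", {
  skip_if_not_installed("nortest")
  withr::with_seed(27, x <- rexp(200))
  p_ours <- ks_gaussianity(x, n_draws = 5000, seed = 1)
  p_ref <- nortest::lillie.test(x)$p.value
  # both should emphatically reject
  expect_lt(p_ours, 0.01)
  expect_lt(p_ref, 0.01)
  # and broadly agree on a borderline sample
  withr::with_seed(28, y <- rt(80, df = 5))
  p_ours_y <- ks_gaussianity(y, n_draws = 5000, seed = 1)
  p_ref_y <- nortest::lillie.test(y)$p.value
  expect_lt(abs(p_ours_y - p_ref_y), 0.15)
})

test_that("sign-flip test matches exhaustive enumeration anchors", {
  expect_equal(sign_flip_test(rep(0, 6)), 1)
  expect_equal(sign_flip_test(rep(1, 5), alternative = "greater"), 1 / 32)
  expect_equal(sign_flip_test(rep(-1, 5), alternative = "less"), 1 / 32)
  expect_equal(sign_flip_test(rep(1, 5), alternative = "two_sided"), 2 / 32)
  # exhaustive two-sided p for asymmetric d, cross-checked by direct enumeration
  d <- c(0.3, -1.2, 0.8, 2.1, -0.4, 0.9)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 6)))
  null_means <- as.vector(signs %*% d) / 6
  p_manual <- mean(abs(null_means) >= abs(mean(d)) - 1e-12)
  expect_equal(sign_flip_test(d, alternative = "two_sided"), p_manual)
  expect_error(sign_flip_test(c(1, 2, 3)), class = "covica_error_sample_size")
})

test_that("random-draw sign-flip test is calibrated under the null", {
  n_rep <- 400
  rej <- withr::with_seed(29, {
    vapply(seq_len(n_rep), function(b) {
      d <- rnorm(100)
      sign_flip_test(d, n_permutations = 2000, seed = b, alternative = "less") < 0.05
    }, logical(1))
  })
  # 0.05 +/- 2 binomial SEs at 400 replicates
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_gte(mean(rej), 0.05 - 2.5 * se)
  expect_lte(mean(rej), 0.05 + 2.5 * se)
})

test_that("sign-flip p is reproducible for a fixed seed", {
  withr::with_seed(30, d <- rnorm(50))
  expect_identical(
    sign_flip_test(d, n_permutations = 1000, seed = 3),
    sign_flip_test(d, n_permutations = 1000, seed = 3)
  )
})

test_that("jackknife produces one record per subject with exact partitioning", {
  co <- tiny_cohort(n_subjects = 14, n_features = 4, n_sources = 2, seed = 33)
  cfg <- run_config(ica = ica_config(max_iter = 128), n_permutations = 500)
  rec <- jackknife_compare(co$connectivity, co$behavior, config = cfg, seed = 33)
  expect_equal(nrow(rec), 14)
  expect_identical(sort(rec$left_out_subject), sort(co$connectivity$subject_id))
  expect_identical(rec$score, co$behavior$score)
  expect_true(all(rec$m1_r2 >= 0 & rec$m1_r2 <= 1, na.rm = TRUE))
  expect_true(all(rec$m2_r2 >= 0 & rec$m2_r2 <= 1, na.rm = TRUE))
  expect_true(all(rec$m1_p > 0 & rec$m1_p <= 1, na.rm = TRUE))
  # determinism
  rec2 <- jackknife_compare(co$connectivity, co$behavior, config = cfg, seed = 33)
  expect_identical(tibble::as_tibble(rec), tibble::as_tibble(rec2))
  # different master seed changes the fits
  rec3 <- jackknife_compare(co$connectivity, co$behavior, config = cfg, seed = 34)
  expect_false(identical(rec$m1_p, rec3$m1_p))
  expect_error(
    jackknife_compare(co$connectivity[1:8, ], co$behavior[1:8, ], config = cfg),
    class = "covica_error_sample_size"
  )
})

test_that("compare_methods assembles paired deltas, tests and histograms", {
  co <- tiny_cohort(n_subjects = 16, n_features = 4, n_sources = 2, seed = 35)
  cfg <- run_config(ica = ica_config(max_iter = 128), n_permutations = 500)
  rec <- jackknife_compare(co$connectivity, co$behavior, config = cfg, seed = 35)
  rep <- compare_methods(rec)
  expect_equal(rep$n_iterations, 16)
  expect_equal(rep$p_tests$t_df, 15)
  expect_equal(rep$delta_p, rec$m2_p - rec$m1_p)
  expect_equal(sum(rep$hist_delta_p$counts), rep$n_iterations)
  expect_equal(sum(rep$hist_delta_r2$counts), rep$n_iterations)
  expect_equal(length(rep$hist_delta_p$edges), cfg$histogram_bins + 1)
  gl <- glance(rep)
  expect_equal(gl$t_df, 15)
  td <- tidy(rep)
  expect_equal(td$delta_p, rep$delta_p)
  plt <- autoplot(rep)
  expect_s3_class(plt, "ggplot")
})

test_that("identical per-iteration p-values hit the degenerate path", {
  n <- 12
  df <- tibble::tibble(
    iteration = 1:n, left_out_subject = sprintf("S%02d", 1:n),
    score = rnorm(n),
    m1_r2 = 0.25, m1_p = 0.2, m2_r2 = 0.25, m2_p = 0.2,
    m1_oos_source = rnorm(n), m2_oos_source = rnorm(n),
    m1_converged = TRUE, m2_converged = TRUE
  )
  rep <- compare_methods(fake_records(df))
  expect_true(rep$p_tests$degenerate)
  expect_true(is.na(rep$p_tests$t_stat))
  expect_equal(rep$p_tests$perm_p, 1)
})

test_that("flagged iterations are dropped pairwise", {
  n <- 14
  withr::with_seed(36, df <- tibble::tibble(
    iteration = 1:n, left_out_subject = sprintf("S%02d", 1:n),
    score = rnorm(n),
    m1_r2 = runif(n), m1_p = runif(n),
    m2_r2 = runif(n), m2_p = runif(n),
    m1_oos_source = rnorm(n), m2_oos_source = rnorm(n),
    m1_converged = TRUE, m2_converged = TRUE
  ))
  df$m1_p[3] <- NA
  df$m2_r2[7] <- NA
  rep <- compare_methods(fake_records(df))
  expect_equal(rep$n_iterations, 12)
  expect_equal(rep$n_excluded, 2)
  expect_equal(rep$p_tests$t_df, 11)
  expect_equal(length(rep$delta_p), length(rep$delta_r2))
  # too few usable records errors
  df_bad <- df
  df_bad$m1_p[1:6] <- NA
  expect_error(compare_methods(fake_records(df_bad)), class = "covica_error_sample_size")
})

test_that("pooled out-of-sample correlations use the recorded left-out values", {
  n <- 20
  withr::with_seed(37, {
    oos1 <- rnorm(n)
    score <- oos1 * 0.8 + rnorm(n) * 0.3
    df <- tibble::tibble(
      iteration = 1:n, left_out_subject = sprintf("S%02d", 1:n),
      score = score,
      m1_r2 = runif(n), m1_p = runif(n),
      m2_r2 = runif(n), m2_p = runif(n),
      m1_oos_source = oos1, m2_oos_source = rnorm(n),
      m1_converged = TRUE, m2_converged = TRUE
    )
  })
  rep <- compare_methods(fake_records(df))
  ref <- pearson(df$m1_oos_source, df$score)
  expect_equal(rep$pooled_oos$m1$r, ref$r, tolerance = 1e-12)
  expect_equal(rep$pooled_oos$m1$p, ref$p, tolerance = 1e-12)
})
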