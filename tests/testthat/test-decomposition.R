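test_that("plain models carry one component per feature (m = 30 included)", {
  co30 <- tiny_cohort(n_subjects = 60, n_features = 30, n_sources = 5, seed = 17)
  m1 <- fit_method1(co30$connectivity, seed = 17)
  expect_equal(dim(m1$ica_weights), c(30, 30))
  expect_equal(m1$n_features_total, 30)
  expect_identical(m1$kind, "plain")
  expect_null(m1$covariate_column)
  # training sources are centered per component
  expect_equal(rowMeans(m1$training_sources), rep(0, 30), tolerance = 1e-10)
})

test_that("augmented models carry m + 1 components with the covariate last", {
  co30 <- tiny_cohort(n_subjects = 60, n_features = 30, n_sources = 5, seed = 18)
  m2 <- fit_method2(co30$connectivity, co30$behavior, seed = 18)
  expect_equal(dim(m2$ica_weights), c(31, 31))
  expect_identical(m2$kind, "augmented")
  expect_equal(m2$covariate_column, 31)
  # the appended covariate column is z-scored with training statistics
  expect_equal(
    unname(m2$standardization$mean[31]), mean(co30$behavior$score),
    tolerance = 1e-12
  )
  expect_equal(
    unname(m2$standardization$sd[31]), sd(co30$behavior$score),
    tolerance = 1e-12
  )
})

test_that("fits fail cleanly on too few subjects or mismatched ids", {
  co <- tiny_cohort(n_subjects = 5, n_features = 5, n_sources = 2, seed = 1)
  expect_error(fit_method1(co$connectivity, seed = 1), class = "covica_error_rank")
  expect_error(
    fit_method2(co$connectivity, co$behavior, seed = 1),
    class = "covica_error_rank"
  )
  # n = m + 1 subjects: enough for plain, one short for augmented
  co7 <- tiny_cohort(n_subjects = 6, n_features = 5, n_sources = 2, seed = 1)
  expect_s3_class(fit_method1(co7$connectivity, seed = 1), "covica_model")
  expect_error(
    fit_method2(co7$connectivity, co7$behavior, seed = 1),
    class = "covica_error_rank"
  )
  co2 <- tiny_cohort(n_subjects = 20, n_features = 4, seed = 2)
  beh_wrong <- co2$behavior
  beh_wrong$subject_id[3] <- "GHOST"
  expect_error(
    fit_method2(co2$connectivity, beh_wrong, seed = 2),
    regexp = "GHOST", class = "covica_error_schema"
  )
})

test_that("fits are deterministic given data and seed", {
  co <- tiny_cohort(seed = 23)
  a <- fit_method2(co$connectivity, co$behavior, seed = 5)
  b <- fit_method2(co$connectivity, co$behavior, seed = 5)
  expect_identical(a$total_transform, b$total_transform)
})

test_that("a perfectly behavior-aligned source is found by the augmented fit", {
  # effect_size = 1 with a trace of measurement noise (exactly zero noise
  # makes the planted score collinear with the features, so the augmented
  # covariance is singular and rejected by design): the augmented
  # decomposition must dedicate a component to the planted signal
  for (s in 1:5) {
    co <- generate_cohort(synthetic_params(
      n_subjects = 2000, n_features = 5, n_sources = 5,
      effect_size = 1, connectivity_noise_sd = 0.1, seed = s
    ))
    m2 <- fit_method2(co$connectivity, co$behavior, seed = s)
    rs <- abs(cor(t(m2$training_sources), co$behavior$score))
    expect_gt(max(rs), 0.95)
  }
})

test_that("plain ICA recovers a component tracking the planted source", {
  co <- generate_cohort(synthetic_params(
    n_subjects = 2000, n_features = 5, n_sources = 5,
    effect_size = 0.8, connectivity_noise_sd = 0, seed = 37
  ))
  m1 <- fit_method1(co$connectivity, seed = 37)
  rs <- abs(cor(t(m1$training_sources), co$truth$sources[co$truth$linked_source, ]))
  expect_gt(max(rs), 0.8)
})

test_that("unmix reproduces training sources and inverts exactly", {
  co <- tiny_cohort(seed = 41)
  m1 <- fit_method1(co$connectivity, seed = 41)
  src <- unmix(m1, co$connectivity)
  S <- t(as.matrix(src[, -1]))
  expect_equal(S, m1$training_sources, tolerance = 1e-10, ignore_attr = TRUE)
  # invert: de-standardize inverse(total_transform) %*% sources
  X_rec <- invert_standardization(
    m1$standardization,
    t(solve(m1$total_transform) %*% S)
  )
  expect_equal(X_rec, as.matrix(co$connectivity[, -1]),
    tolerance = 1e-8, ignore_attr = TRUE
  )
  # single-subject projection works and is finite
  one <- unmix(m1, co$connectivity[5, ])
  expect_equal(nrow(one), 1)
  expect_true(all(is.finite(as.matrix(one[, -1]))))
})

test_that("held-out projection of augmented models never sees behavior", {
  co <- tiny_cohort(n_subjects = 30, n_features = 4, seed = 43)
  m2 <- fit_method2(co$connectivity[1:25, ], co$behavior[1:25, ], seed = 43)
  test_conn <- co$connectivity[26:30, ]
  s1 <- project_heldout(m2, test_conn)
  s2 <- project_heldout(m2, test_conn) # no behavior argument even exists
  expect_identical(s1, s2)
  # the zero-filled projection equals the connectivity-only linear map
  m <- length(m2$feature_labels)
  Zc <- apply_standardization(
    list(
      mean = m2$standardization$mean[1:m],
      sd = m2$standardization$sd[1:m]
    ),
    as.matrix(test_conn[, -1])
  )
  manual <- m2$total_transform[, 1:m, drop = FALSE] %*% t(Zc)
  expect_equal(as.matrix(s1[, -1]), t(manual), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a test subject equal to a training subject differs from the training
           source by exactly the covariate contribution", {
  co <- tiny_cohort(n_subjects = 20, n_features = 3, seed = 47)
  m2 <- fit_method2(co$connectivity, co$behavior, seed = 47)
  i <- 4
  s_heldout <- project_heldout(m2, co$connectivity[i, ])
  z_j <- (co$behavior$score[i] - m2$standardization$mean[[4]]) / m2$standardization$sd[[4]]
  covar_contrib <- m2$total_transform[, 4] * z_j
  expect_equal(
    as.numeric(s_heldout[1, -1]),
    unname(m2$training_sources[, i] - covar_contrib),
    tolerance = 1e-10
  )
})

test_that("full projection mode warns and reproduces the literal augmented map", {
  co <- tiny_cohort(n_subjects = 25, n_features = 4, seed = 53)
  m2 <- fit_method2(co$connectivity, co$behavior, seed = 53)
  aug <- dplyr::mutate(co$connectivity, behavior_score = co$behavior$score)
  expect_warning(
    s_full <- project_heldout(m2, aug, projection = "full"),
    regexp = "held-out behavior"
  )
  S <- t(as.matrix(s_full[, -1]))
  expect_equal(S, m2$training_sources, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("near-duplicate covariate collapses the augmented decomposition's rank", {
  # behavior that is an affine copy of feature 2 (plus tiny jitter so the
  # covariance stays numerically full-rank): the augmented sources span the
  # same m-dimensional subject space as the plain sources, with the extra
  # direction nearly degenerate in the raw (unwhitened) augmented data
  co <- tiny_cohort(n_subjects = 50, n_features = 4, seed = 59)
  f2 <- co$connectivity[[3]]
  withr::with_seed(59, {
    beh <- beh_tbl(10 + 3 * f2 + rnorm(50, sd = 1e-3 * sd(f2)),
      ids = co$connectivity$subject_id
    )
  })
  Xa <- cbind(scale(as.matrix(co$connectivity[, -1])), scale(beh$score))
  sv <- svd(Xa)$d
  expect_lt(sv[5] / sv[1], 1e-2) # near-duplicate direction in the data
  m2 <- fit_method2(co$connectivity, beh, seed = 59)
  # connectivity-only projected augmented sources live in the plain model's
  # m-dimensional row space
  m1 <- fit_method1(co$connectivity, seed = 59)
  s1 <- as.matrix(project_heldout(m1, co$connectivity)[, -1])
  s2 <- as.matrix(project_heldout(m2, co$connectivity)[, -1])
  combined <- cbind(s1, s2)
  sv_c <- svd(combined)$d
  expect_lt(sv_c[5] / sv_c[1], 1e-6)
  # an exactly duplicated covariate is degenerate by design
  beh_exact <- beh_tbl(10 + 3 * f2, ids = co$connectivity$subject_id)
  expect_error(
    fit_method2(co$connectivity, beh_exact, seed = 59),
    class = "covica_error_rank"
  )
})

test_that("model tidiers expose weights and fit metadata", {
  co <- tiny_cohort(seed = 61)
  m2 <- fit_method2(co$connectivity, co$behavior, seed = 61)
  td <- tidy(m2)
  expect_equal(nrow(td), 6 * 6)
  expect_equal(
    td$weight[td$component == "IC2" & td$feature == m2$feature_labels[1]],
    unname(m2$total_transform[2, 1])
  )
  gl <- glance(m2)
  expect_identical(gl$kind, "augmented")
  expect_equal(gl$n_components, 6)
})
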