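# Numerical ICA engine: standardization, symmetric (ZCA) whitening, and
# natural-gradient Infomax. All three operate on plain numeric matrices
# (subjects in rows); the tibble-facing wrappers live in fit_method1() /
# fit_method2().

#' Fit a per-feature standardization
#'
#' Computes per-feature means and sample SDs (n-1 denominator) so that
#' `(X - mean) / sd` has column means 0 and sample SDs 1.
#'
#' @param X Numeric matrix, subjects x features (column names = labels).
#' @return List of class `covica_standardization` with `mean` and `sd`
#'   vectors (named by feature label when available).
#' @examples
#' fit_standardization(cbind(a = c(1, 2, 3), b = c(2, 4, 9)))
#' @export
fit_standardization <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 3L) stop_sample_size("at least 3 subjects are required.")
  if (!all(is.finite(X))) stop_schema("non-finite values in input matrix.")
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  if (any(sdev == 0)) {
    bad <- colnames(X)[sdev == 0] %||% which(sdev == 0)
    stop_degenerate(sprintf(
      "constant feature(s) cannot be standardized: %s.",
      paste(bad, collapse = ", ")
    ))
  }
  structure(list(mean = mu, sd = sdev), class = "covica_standardization")
}

apply_standardization <- function(std, X) {
  sweep(sweep(as.matrix(X), 2, std$mean, "-"), 2, std$sd, "/")
}

invert_standardization <- function(std, Z) {
  sweep(sweep(as.matrix(Z), 2, std$sd, "*"), 2, std$mean, "+")
}

#' Fit a symmetric (ZCA) whitening transform
#'
#' Returns the inverse principal square root of the sample covariance of
#' `Z`, i.e. the unique symmetric matrix `V` with `V %*% cov(Z) %*% V = I`.
#' Multiplying the data by it makes the sample covariance the identity.
#' No dimensionality reduction is performed, so the covariance must have
#' full rank (more subjects than features).
#'
#' @param Z Numeric matrix, subjects x features (typically standardized).
#' @param rank_tol Relative eigenvalue threshold below which the covariance
#'   is declared rank-deficient.
#' @return Symmetric features x features whitening matrix.
#' @examples
#' Z <- matrix(rnorm(600), 100, 6)
#' V <- fit_whitening(Z)
#' round(cov(Z %*% V), 8)[1:3, 1:3]
#' @export
fit_whitening <- function(Z, rank_tol = 1e-10) {
  Z <- as.matrix(Z)
  if (nrow(Z) <= ncol(Z)) {
    stop_rank(sprintf(
      "whitening needs more subjects (%d) than features (%d); reduce the feature set.",
      nrow(Z), ncol(Z)
    ))
  }
  S <- stats::cov(Z)
  eig <- eigen(S, symmetric = TRUE)
  if (any(eig$values < rank_tol * max(eig$values))) {
    stop_rank(
      "sample covariance is rank deficient (collinear or duplicated features); reduce the feature set."
    )
  }
  V <- eig$vectors %*% (t(eig$vectors) / sqrt(eig$values))
  dimnames(V) <- list(colnames(Z), colnames(Z))
  V
}

#' Infomax ICA by natural-gradient ascent
#'
#' Estimates a square unmixing matrix on whitened data by maximizing the
#' Infomax objective with a logistic nonlinearity `g(u) = 1/(1 + exp(-u))`
#' and the natural-gradient update `dW = lr * (I + (1 - 2 g(U)) U') W`,
#' applied over seeded, reshuffled mini-batches. Starts from the identity.
#' The learning rate is annealed (and the sweep rolled back) whenever an
#' update produces non-finite or exploding weights, and also whenever the
#' direction of successive sweep updates turns by more than 60 degrees --
#' the classic sign that the iterate is orbiting a fixed point at too
#' large a step. Stops when the
#' per-sweep weight change drops below `config$tol` or after
#' `config$max_iter` sweeps; non-convergence is reported as a flag, never
#' as an error, so resampling loops survive an occasional hard fit.
#'
#' @param Zw Numeric matrix, subjects x channels, whitened.
#' @param config An [ica_config()].
#' @param seed Integer seed controlling batch shuffling (the only source of
#'   randomness; initialization is deterministic).
#' @return List of class `covica_infomax`: `weights` (channels x channels),
#'   `converged`, `iterations`, `final_weight_change`, `learning_rate`
#'   (final, after any annealing), `config`, `seed`.
#' @examples
#' S <- matrix(rlaplace_unit(2 * 2000), 2)
#' X <- t(matrix(c(1, .5, .5, 1), 2) %*% S)
#' Zw <- X %*% fit_whitening(X)
#' fit <- infomax_ica(Zw, seed = 1)
#' fit$converged
#' @export
infomax_ica <- function(Zw, config = ica_config(), seed = 1L) {
  Zw <- as.matrix(Zw)
  if (!inherits(config, "covica_ica_config")) {
    stop_parameter("`config` must be an ica_config() object.")
  }
  seed <- check_scalar_int(seed, "seed", min = -.Machine$integer.max)
  k <- ncol(Zw)
  n <- nrow(Zw)
  if (n < 2L || k < 1L) stop_parameter("need at least 2 subjects and 1 channel.")
  lr <- config$learning_rate %||% (0.01 / log(max(k, exp(1))))
  bs <- min(config$batch_size, n)
  Xk <- t(Zw) # channels x subjects
  W <- diag(k)
  I_k <- diag(k)
  converged <- FALSE
  wchange <- NA_real_
  iter <- 0L
  dW_prev <- NULL
  withr::with_seed(seed, {
    for (sweep in seq_len(config$max_iter)) {
      iter <- sweep
      perm <- sample.int(n)
      starts <- seq(1L, n, by = bs)
      W_sweep <- W
      blown <- FALSE
      for (s in starts) {
        idx <- perm[s:min(s + bs - 1L, n)]
        U <- W %*% Xk[, idx, drop = FALSE]
        nb <- length(idx)
        if (config$extended) {
          # kurtosis-sign switch: +1 super-Gaussian, -1 sub-Gaussian
          kt <- rowMeans(U^4) / (rowMeans(U^2)^2) - 3
          K <- sign(kt)
          K[K == 0] <- 1
          G <- I_k - (K * tanh(U)) %*% t(U) / nb - U %*% t(U) / nb
        } else {
          Y <- 1 / (1 + exp(-U))
          G <- I_k + ((1 - 2 * Y) %*% t(U)) / nb
        }
        W_new <- W + lr * G %*% W
        if (!all(is.finite(W_new)) || max(abs(W_new)) > 1e8) {
          blown <- TRUE
          break
        }
        W <- W_new
      }
      if (blown) {
        W <- W_sweep
        lr <- lr * 0.9
        next
      }
      dW <- W - W_sweep
      wchange <- sqrt(sum(dW^2))
      if (wchange < config$tol) {
        converged <- TRUE
        break
      }
      # anneal when successive sweep directions disagree (> 60 degrees):
      # the iterate is orbiting a fixed point at the current step size
      if (!is.null(dW_prev)) {
        denom <- sqrt(sum(dW^2) * sum(dW_prev^2))
        if (denom > 0 && sum(dW * dW_prev) / denom < 0.5) {
          lr <- lr * config$anneal_factor
        }
      }
      dW_prev <- dW
    }
  })
  structure(
    list(
      weights = W, converged = converged, iterations = iter,
      final_weight_change = wchange, learning_rate = lr,
      config = config, seed = seed
    ),
    class = "covica_infomax"
  )
}

#' Amari index of an unmixing-times-mixing product
#'
#' Permutation- and scale-invariant distance between a square matrix and
#' the set of signed, scaled permutation matrices. For the product of an
#' estimated unmixing transform with the true mixing matrix it measures
#' source-recovery error: 0 for perfect recovery (up to sign, scale and
#' order), 1 for the maximally confused all-ones matrix. Each row
#' contributes `sum_j |p_ij| / max_j |p_ij| - 1`, columns symmetrically;
#' the total is divided by `2 k (k - 1)`.
#'
#' @param P Square numeric matrix (e.g. `total_transform %*% mixing`).
#' @return A number in `[0, 1]`.
#' @examples
#' amari_index(diag(4)) # 0
#' amari_index(matrix(1, 4, 4)) # 1
#' @export
amari_index <- function(P) {
  P <- as.matrix(P)
  k <- nrow(P)
  if (k != ncol(P) || k < 2L) stop_parameter("`P` must be square with k >= 2.")
  if (!all(is.finite(P))) stop_parameter("`P` must be finite.")
  Q <- abs(P)
  if (any(rowSums(Q) == 0) || any(colSums(Q) == 0)) {
    stop_degenerate("`P` has an all-zero row or column.")
  }
  row_term <- sum(rowSums(Q / apply(Q, 1, max)) - 1)
  col_term <- sum(colSums(sweep(Q, 2, apply(Q, 2, max), "/")) - 1)
  (row_term + col_term) / (2 * k * (k - 1))
}

#' Source-recovery error of a fitted model against a known mixing matrix
#'
#' Convenience wrapper for synthetic benchmarks: forms the product of the
#' model's effective unmixing map with the true mixing matrix and returns
#' its [amari_index()]. Because the model's transform acts on
#' standardized features, the mixing matrix is first divided row-wise by
#' the training feature SDs so both maps live in the same coordinates.
#'
#' @param model A `covica_model` fitted on data generated as
#'   `t(mixing %*% sources)` (plus noise).
#' @param mixing The true features x sources mixing matrix; for plain
#'   models `nrow(mixing)` must equal the number of features, and the
#'   number of sources must equal the number of components for the index
#'   to be defined (square product).
#' @return Amari index in `[0, 1]`; 0 is perfect recovery.
#' @examples
#' cohort <- generate_cohort(synthetic_params(
#'   n_subjects = 1000, n_features = 4, n_sources = 4,
#'   connectivity_noise_sd = 0, seed = 9
#' ))
#' m1 <- fit_method1(cohort$connectivity, seed = 9)
#' recovery_index(m1, cohort$truth$mixing)
#' @export
recovery_index <- function(model, mixing) {
  stopifnot(inherits(model, "covica_model"))
  mixing <- as.matrix(mixing)
  m <- length(model$feature_labels)
  if (nrow(mixing) != m) {
    stop_parameter("`mixing` must have one row per model feature.")
  }
  scaled <- sweep(mixing, 1, model$standardization$sd[seq_len(m)], "/")
  P <- model$total_transform[, seq_len(m), drop = FALSE] %*% scaled
  if (nrow(P) != ncol(P)) {
    stop_parameter("recovery product is not square (components != sources).")
  }
  amari_index(P)
}
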