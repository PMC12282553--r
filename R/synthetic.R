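# Synthetic cohort generator: the ground-truth test bed for the pipeline.
#
# Generative model
#   sources   S  : k x n, entries iid unit-scale Laplace (super-Gaussian,
#                  excess kurtosis 3) -- what Infomax with a logistic
#                  nonlinearity is designed to recover
#   mixing    A  : m x k, entries iid standard normal
#   features  C  = t(A S) + Gaussian noise            (n subjects x m)
#   behavior  J  = mu + sigma * ( r * z(S[linked,]) + sqrt(1-r^2) * eta )
# so the population correlation between J and the linked source is exactly r.

.default_regions <- c(
  "mPFC", "PCC", "Prec", "lAG", "rAG", "lLTC", "rLTC", "lHF", "rHF",
  "dACC", "vmPFC", "Rsp"
)

synthetic_feature_labels <- function(n_features) {
  pairs <- utils::combn(.default_regions, 2)
  labels <- paste0(pairs[1, ], "-", pairs[2, ], "/upper-alpha")
  if (n_features > length(labels)) {
    extra <- n_features - length(labels)
    labels <- c(labels, sprintf("R%02da-R%02db/upper-alpha", seq_len(extra), seq_len(extra)))
  }
  labels[seq_len(n_features)]
}

#' Unit-scale Laplace deviates
#'
#' Draws from the Laplace (double-exponential) distribution with location
#' 0 and scale 1 (variance 2, excess kurtosis 3) by inverse-CDF sampling.
#' This super-Gaussian distribution is the package's default latent-source
#' law: it is exactly the family the logistic-nonlinearity Infomax rule is
#' tuned to recover.
#'
#' @param n Number of deviates.
#' @return Numeric vector of length `n`.
#' @examples
#' mean(abs(rlaplace_unit(1e4))) # ~1
#' @export
rlaplace_unit <- function(n) {
  u <- runif(n, -0.5, 0.5)
  -sign(u) * log1p(-2 * abs(u))
}

#' Parameters for a synthetic connectivity-plus-behavior cohort
#'
#' Describes a cohort in which `n_sources` statistically independent,
#' super-Gaussian latent sources are linearly mixed into `n_features`
#' connectivity values per subject, and a norm-referenced behavioral score
#' (default scale: mean 100, SD 15, as for standardized cognitive
#' composites) is correlated with exactly one source at a controlled
#' population effect size.
#'
#' @param n_subjects Number of subjects (rows of the connectivity table).
#' @param n_features Number of connectivity features (region-pair values);
#'   default 30.
#' @param n_sources Number of latent sources, at most `n_features`;
#'   default 5.
#' @param linked_source 1-based index of the source the behavioral score is
#'   tied to.
#' @param effect_size Target population correlation (in `[0, 1]`) between
#'   the behavioral score and the linked source.
#' @param connectivity_noise_sd SD of the iid Gaussian measurement noise
#'   added to every connectivity value.
#' @param behavior_mean,behavior_sd Location and scale of the behavioral
#'   score (norm-referenced standard-score units).
#' @param seed Integer seed; the cohort is a pure function of the
#'   parameters including this seed.
#' @return A list of class `covica_synthetic_params`.
#' @seealso [generate_cohort()]
#' @examples
#' synthetic_params(n_subjects = 50, effect_size = 0.6, seed = 7)
#' @export
synthetic_params <- function(n_subjects,
                             n_features = 30L,
                             n_sources = 5L,
                             linked_source = 1L,
                             effect_size = 0.4,
                             connectivity_noise_sd = 1,
                             behavior_mean = 100,
                             behavior_sd = 15,
                             seed = 1L) {
  n_subjects <- check_scalar_int(n_subjects, "n_subjects", 1L)
  n_features <- check_scalar_int(n_features, "n_features", 1L)
  n_sources <- check_scalar_int(n_sources, "n_sources", 1L)
  linked_source <- check_scalar_int(linked_source, "linked_source", 1L)
  seed <- check_scalar_int(seed, "seed", min = -.Machine$integer.max)
  if (n_sources > n_features) {
    stop_parameter("`n_sources` must not exceed `n_features`.")
  }
  if (linked_source > n_sources) {
    stop_parameter("`linked_source` must be in 1..n_sources.")
  }
  if (!is_scalar_number(effect_size) || effect_size < 0 || effect_size > 1) {
    stop_parameter("`effect_size` must be in [0, 1].")
  }
  if (!is_scalar_number(connectivity_noise_sd) || connectivity_noise_sd < 0) {
    stop_parameter("`connectivity_noise_sd` must be non-negative.")
  }
  if (!is_scalar_number(behavior_mean)) stop_parameter("`behavior_mean` must be a number.")
  if (!is_scalar_number(behavior_sd) || behavior_sd <= 0) {
    stop_parameter("`behavior_sd` must be positive.")
  }
  structure(
    list(
      n_subjects = n_subjects, n_features = n_features,
      n_sources = n_sources, linked_source = linked_source,
      effect_size = effect_size,
      connectivity_noise_sd = connectivity_noise_sd,
      behavior_mean = behavior_mean, behavior_sd = behavior_sd,
      seed = seed
    ),
    class = "covica_synthetic_params"
  )
}

#' Generate a synthetic connectivity + behavior cohort
#'
#' Draws independent unit-scale Laplace sources, mixes them through a
#' standard-normal mixing matrix into connectivity features with additive
#' Gaussian noise, and constructs a behavioral score whose population
#' correlation with one designated source equals `effect_size` exactly
#' (convex combination of the standardized source and independent noise in
#' z-space, rescaled to the behavioral norm).
#'
#' @param params A [synthetic_params()] object.
#' @return A list of class `covica_cohort` with elements
#'   \describe{
#'     \item{connectivity}{tibble: `subject_id` plus one numeric column per
#'       connectivity feature (labels like `mPFC-PCC/upper-alpha`).}
#'     \item{behavior}{tibble: `subject_id`, `score`.}
#'     \item{truth}{ground truth: `mixing` (features x sources), `sources`
#'       (sources x subjects), `linked_source`, `effect_size`, and the
#'       generating `params`.}
#'   }
#' @examples
#' cohort <- generate_cohort(synthetic_params(n_subjects = 40, seed = 3))
#' dim(cohort$connectivity)
#' cor(cohort$behavior$score, cohort$truth$sources[1, ])
#' @export
generate_cohort <- function(params) {
  if (!inherits(params, "covica_synthetic_params")) {
    stop_parameter("`params` must be created by synthetic_params().")
  }
  p <- params
  withr::with_seed(p$seed, {
    sources <- matrix(
      rlaplace_unit(p$n_sources * p$n_subjects),
      nrow = p$n_sources, ncol = p$n_subjects
    )
    mixing <- matrix(
      rnorm(p$n_features * p$n_sources),
      nrow = p$n_features, ncol = p$n_sources
    )
    noise <- if (p$connectivity_noise_sd > 0) {
      matrix(rnorm(p$n_subjects * p$n_features, sd = p$connectivity_noise_sd),
        nrow = p$n_subjects
      )
    } else {
      0
    }
    conn <- t(mixing %*% sources) + noise
    s_linked <- sources[p$linked_source, ]
    z <- as.vector(scale(s_linked))
    eta <- rnorm(p$n_subjects)
    score <- p$behavior_mean + p$behavior_sd *
      (p$effect_size * z + sqrt(1 - p$effect_size^2) * eta)
  })
  if (qr(mixing)$rank < p$n_sources) {
    stop_degenerate("drawn mixing matrix is column-rank deficient; use another seed.")
  }
  ids <- sprintf("S%04d", seq_len(p$n_subjects))
  labels <- synthetic_feature_labels(p$n_features)
  colnames(conn) <- labels
  connectivity <- dplyr::bind_cols(
    tibble::tibble(subject_id = ids),
    tibble::as_tibble(conn)
  )
  behavior <- tibble::tibble(subject_id = ids, score = score)
  structure(
    list(
      connectivity = connectivity,
      behavior = behavior,
      truth = list(
        mixing = mixing, sources = sources,
        linked_source = p$linked_source, effect_size = p$effect_size,
        params = p
      )
    ),
    class = "covica_cohort"
  )
}

#' @export
print.covica_cohort <- function(x, ...) {
  p <- x$truth$params
  cat(sprintf(
    "<covica_cohort> %d subjects, %d features, %d sources (linked #%d, effect size %.2f)\n",
    p$n_subjects, p$n_features, p$n_sources, p$linked_source, p$effect_size
  ))
  invisible(x)
}
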