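#' Infomax ICA configuration
#'
#' Tuning parameters for the natural-gradient Infomax optimizer used by
#' [fit_method1()] and [fit_method2()]. Defaults follow common EEG practice:
#' identity initialization, an initial learning rate of `0.01 / log(k)` for
#' `k` channels, learning-rate annealing on direction reversals and
#' blow-ups, and a stopping rule on the Frobenius norm of the weight
#' change.
#'
#' @param learning_rate Initial learning rate. `NULL` (default) resolves to
#'   `0.01 / log(k)` at fit time, where `k` is the number of channels.
#' @param tol Convergence tolerance on the per-sweep weight change
#'   (Frobenius norm of `W_new - W_old`).
#' @param max_iter Maximum number of full sweeps through the data.
#' @param batch_size Mini-batch size; batches are reshuffled every sweep
#'   using the fit seed. Capped at the number of subjects.
#' @param anneal_factor Multiplier applied to the learning rate when the
#'   direction of successive sweep updates turns by more than 60 degrees
#'   (the iterate is orbiting a fixed point). A non-finite or exploding
#'   update is rolled back with a harsher cut (rate times 0.9).
#' @param extended Logical; use the extended (sub+super-Gaussian) Infomax
#'   nonlinearity with a kurtosis-based sign switch. Default `FALSE`:
#'   connectivity features are expected super-Gaussian-dominated.
#' @return A list of class `covica_ica_config`.
#' @examples
#' ica_config(max_iter = 256)
#' @export
ica_config <- function(learning_rate = NULL, tol = 1e-7, max_iter = 512L,
                       batch_size = 64L, anneal_factor = 0.98,
                       extended = FALSE) {
  if (!is.null(learning_rate) &&
    (!is_scalar_number(learning_rate) || learning_rate <= 0)) {
    stop_parameter("`learning_rate` must be NULL or a positive number.")
  }
  if (!is_scalar_number(tol) || tol <= 0) stop_parameter("`tol` must be positive.")
  max_iter <- check_scalar_int(max_iter, "max_iter", min = 1L)
  batch_size <- check_scalar_int(batch_size, "batch_size", min = 1L)
  if (!is_scalar_number(anneal_factor) || anneal_factor <= 0 || anneal_factor >= 1) {
    stop_parameter("`anneal_factor` must be in (0, 1).")
  }
  structure(
    list(
      learning_rate = learning_rate, tol = tol, max_iter = max_iter,
      batch_size = batch_size, anneal_factor = anneal_factor,
      extended = isTRUE(extended)
    ),
    class = "covica_ica_config"
  )
}

#' Pipeline run configuration
#'
#' Bundles every option of the jackknife comparison pipeline so that a
#' complete, serializable record of the run travels with its report.
#'
#' @param ica An [ica_config()] object.
#' @param projection Held-out projection rule for augmented models:
#'   `"connectivity_only"` (default; the covariate channel of a held-out
#'   subject is fixed at the training mean, so held-out behavior is never
#'   consulted) or `"full"` (the literal augmented linear map, which leaks
#'   the held-out score into its own predictor; emitted with a warning,
#'   available for comparison only).
#' @param evaluation_set Which subjects each jackknife iteration correlates:
#'   `"train"` (default) computes the per-iteration association on that
#'   iteration's n-1 training subjects, yielding a length-n distribution of
#'   the statistic; `"pooled_oos"` correlates the n pooled left-out source
#'   values against behavior once per method.
#' @param n_permutations Random sign-flip draws for the permutation test
#'   when exhaustive enumeration (n <= 20) is not feasible.
#' @param alternative `"one_sided"` (default; tests whether the augmented
#'   method's p-values are systematically smaller) or `"two_sided"`.
#' @param histogram_bins Number of bins for the difference histograms.
#' @return A list of class `covica_run_config`.
#' @examples
#' run_config(n_permutations = 2000)
#' @export
run_config <- function(ica = ica_config(),
                       projection = c("connectivity_only", "full"),
                       evaluation_set = c("train", "pooled_oos"),
                       n_permutations = 10000L,
                       alternative = c("one_sided", "two_sided"),
                       histogram_bins = 30L) {
  if (!inherits(ica, "covica_ica_config")) {
    stop_parameter("`ica` must be an ica_config() object.")
  }
  projection <- match.arg(projection)
  evaluation_set <- match.arg(evaluation_set)
  alternative <- match.arg(alternative)
  structure(
    list(
      ica = ica,
      projection = projection,
      evaluation_set = evaluation_set,
      n_permutations = check_scalar_int(n_permutations, "n_permutations", 10L),
      alternative = alternative,
      histogram_bins = check_scalar_int(histogram_bins, "histogram_bins", 2L)
    ),
    class = "covica_run_config"
  )
}
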