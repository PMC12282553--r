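# Small cohort builders shared across test files. Everything is generated
# in code from fixed seeds; nothing is read from disk.

tiny_cohort <- function(n_subjects = 40, n_features = 5, n_sources = 3,
                        effect_size = 0.6, noise_sd = 0.5, seed = 42) {
  generate_cohort(synthetic_params(
    n_subjects = n_subjects, n_features = n_features, n_sources = n_sources,
    effect_size = effect_size, connectivity_noise_sd = noise_sd, seed = seed
  ))
}

# hand-built connectivity tibble from a matrix
conn_tbl <- function(X, ids = sprintf("S%02d", seq_len(nrow(X)))) {
  colnames(X) <- colnames(X) %||% sprintf("f%d", seq_len(ncol(X)))
  dplyr::bind_cols(tibble::tibble(subject_id = ids), tibble::as_tibble(X))
}

beh_tbl <- function(scores, ids = sprintf("S%02d", seq_along(scores))) {
  tibble::tibble(subject_id = ids, score = scores)
}

# jackknife record tibble with the class/attributes compare_methods expects
fake_records <- function(df, config = run_config(), seed = 1L) {
  structure(
    tibble::as_tibble(df),
    class = c("covica_jackknife", class(tibble::tibble())),
    config = config, seed = seed
  )
}

`%||%` <- rlang::`%||%`
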