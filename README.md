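# covica

Covariate-augmented independent component analysis (ICA) for linking
brain-connectivity features to a behavioral score.

## What it does

EEG connectivity studies summarize each subject by a vector of region-pair
coupling values (e.g. 30 upper-alpha lagged-coherence values among
default-mode-network regions) and ask whether a latent pattern in those
values tracks a standardized cognitive score (standard-score units: mean
100, SD 15). Modeling the subjects-by-features table `C` as a linear
mixture `X = A S` of independent non-Gaussian sources, `covica` fits the
unmixing `S = W X` by Infomax and compares two strategies:

* **Method 1 — plain ICA**: decompose `C` into `m` components, correlate
  each with the behavior vector `J`, keep the best:
  `rho_max = max_i |rho(S_i, J)|`, with exact Pearson p-values.
* **Method 2 — covariate-augmented ICA**: decompose `C' = [C J]`
  (behavior z-scored, appended as column `m + 1`) into `m + 1`
  components. Evaluation uses **only the connectivity weights**: held-out
  subjects are projected with the covariate channel fixed at its training
  mean, so a held-out score can never leak into its own prediction.

The two methods are compared by a leave-one-out jackknife: per iteration,
both are refitted on `n - 1` subjects and their best in-sample `(R^2, p)`
recorded, the left-out subject projected and pooled into an out-of-sample
correlation per method. The per-iteration differences (augmented − plain)
are tested with a paired t-test, a Monte-Carlo Lilliefors Gaussianity
check, and a sign-flip permutation test (exhaustive for `n <= 20`).

A synthetic-cohort generator (Laplace sources, Gaussian mixing, a
behavioral score with exact population correlation `r` to one planted
source) provides ground truth for every stage, including an Amari-index
recovery benchmark of the unmixing itself.

## Worked example

```r
library(covica)

cohort <- generate_cohort(synthetic_params(
  n_subjects = 80, n_features = 10, n_sources = 4,
  effect_size = 0.5, seed = 1
))

records <- jackknife_compare(
  cohort$connectivity, cohort$behavior,
  config = run_config(n_permutations = 2000), seed = 1
)
report <- compare_methods(records)
report
#> <covica_comparison> 80 jackknife iterations (0 excluded)
#>   delta_p  (augmented - plain): mean -0.004317 | t(79) = -28.930, p = 8.574e-44 | KS p = 0.0002 | sign-flip p = 0.0004998 (less)
#>   delta_r2 (augmented - plain): mean +0.2221 | sign-flip p = 0.0004998 (greater)
#>   pooled out-of-sample r: plain 0.175 (p = 0.12), augmented 0.418 (p = 0.000115)
```

Reading this: across the 80 leave-one-out refits the augmented method's
selected component explained on average 0.22 more variance in the score
(`delta_r2`) and produced systematically smaller p-values (`delta_p`
negative; sign-flip p = 5e-4 one-sided). The difference distribution is
non-Gaussian (small Lilliefors p), which is why the
permutation test, not the t-test, is the headline. On the pooled left-out
subjects — data the models never saw — the augmented component correlates
0.42 with behavior versus 0.18 for plain ICA. `tidy(report)` returns the
per-iteration tibble, `glance(report)` the one-row summary, and
`autoplot(report)` the pair of difference histograms.

Fitted models are first-class: `fit_method1()` / `fit_method2()` return
unmixing models with `tidy()`/`glance()` methods, `project_heldout()`
projects new subjects, and `write_unmixing_model()` serializes the full
transform to JSON. Delimited tables are read and written with
`read_connectivity_table()`, `read_behavior_table()`, `write_table()`
(tab- or comma-delimited, `subject_id` first column, complete cases only).
A thin command-line wrapper with `simulate` and `compare` subcommands is
installed at `inst/cli/covica.R`.

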