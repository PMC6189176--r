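# sustainr

Subtype and Stage Inference for cross-sectional biomarker data.

Progressive diseases confound two kinds of heterogeneity: *which*
progression pattern a person follows (subtype) and *how far along* it they
are (stage). `sustainr` disentangles the two from a single cross-sectional
measurement per subject, for researchers working with cohort biomarker
tables (e.g. regional brain volumes in neurodegenerative disease).

## The model

Each biomarker `i` is a control-referenced z-score that accumulates along a
piecewise-linear trajectory `g_i(t)` over an arbitrary disease time
`t ∈ [0, 1]`, passing its thresholds `z = 1, 2, 3` at times determined by
the position of those *z-score events* in an ordering `S`, and ending at a
terminal value `z_max,i`. The event in position `k` of the `N`-event
ordering completes at `t = k/(N+1)`. With Gaussian noise `σ_i` and a
uniform stage prior, one subtype's data likelihood is

    P(X|S) = Π_j Σ_{k=0..N} ∫_{k/(N+1)}^{(k+1)/(N+1)} Π_i N(x_ij; g_i(t), σ_i) dt

and a cohort is a mixture over `C` subtypes, `P(X|M) = Σ_c f_c P(X|S_c)`.
Fitting is greedy E-M over event orderings with multi-restart and
hierarchical cluster splitting; uncertainty comes from MCMC over
orderings; the number of subtypes is chosen by a cross-validation
information criterion (`CVIC = −2 ×` out-of-sample log likelihood) with a
6-unit parsimony rule; subjects are assigned a subtype, a stage and a
strength of assignment by averaging over the MCMC posterior.

## Worked example

Simulate the package's canonical validation cohort (5 biomarkers, 15
z-score events, two subtypes sweeping the biomarkers in opposite orders,
500 subjects, unit noise), then run the full pipeline:

```r
library(sustainr)

cfg  <- canonical_scenario(n_subjects = 500, seed = 42)
sim  <- simulate_cohort(cfg)
fits <- fit_hierarchical(sim$data, cfg$event_set, C_max = 3,
                         n_restarts = 8, seed = 43)
cv   <- cross_validate(sim$data, cfg$event_set, C_max = 3,
                       n_folds = 10, seed = 45, n_restarts = 2)
mc   <- mcmc_sample(sim$data, fits[[2]]$model, n_samples = 1e5, seed = 44)
asg  <- assign_subjects(sim$data, mc)
recovery_report(sim, fits[[2]], samples = mc, assignments = asg,
                cv = cv, t_min = 0.2)
```

Output from this run:

```
$assignment_accuracy
[1] 0.9696203

$permutation
[1] 2 1

$fraction_error
[1] 0.02872582

$positional_similarity
[1] 0.9194776 0.9012490

$stage_spearman
[1] 0.9660141

$selected_C
[1] 2

$selected_C_correct
[1] TRUE
```

Reading the numbers: cross-validation selects the true two subtypes
(`selected_C`); 97% of subjects past disease onset (`t > 0.2`) are assigned
to their generating subtype after the best label permutation; the estimated
mixture fractions are within 0.03 of the true (0.5, 0.5); the MCMC
positional distributions overlap the true orderings with Bhattacharyya
similarity ≥ 0.90 per subtype; and assigned stages track true disease time
with Spearman ρ = 0.97.

For real data the pipeline starts from a raw CSV instead:
`fit_control_adjustment()` + `to_zscores()` (covariate-adjusted,
control-referenced z-scores, declining biomarkers sign-flipped),
`select_events()` (keep thresholds at least 10 patients exceed), then the
calls above — or use `run_config()` + `pipeline_fit()` /
`pipeline_crossval()`, or the CLI at `inst/cli/sustainr-cli.R`
(`fit | crossval | assign | simulate`).

## Layout

- `R/` — event sets and datasets, likelihood wrappers, fitting, MCMC,
  model selection, assignment, preprocessing, baselines, simulator,
  pipeline/CLI plumbing
- `src/likelihood.cpp` — quadrature likelihood, greedy optimiser and MCMC
  kernel (Rcpp)
- `tests/testthat/` — unit, property and end-to-end acceptance tests with
  independent oracles (trapezoid integration, exhaustive enumeration)
- `vignettes/subtype-stage-inference.Rmd` — the methods vignette: model,
  assumptions, numerical choices, design decisions, limitations
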