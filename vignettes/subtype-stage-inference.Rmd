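---
title: "Subtype and stage inference from cross-sectional biomarker data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtype and stage inference from cross-sectional biomarker data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sustainr)
```

## The problem

Neurodegenerative diseases are heterogeneous in two confounded ways: people
differ in *which* progression pattern their disease follows (phenotypic
subtype) and in *how far along* that pattern they are (stage). A clustering
of raw biomarker profiles mixes the two — an early severe-subtype patient can
resemble a late mild-subtype patient — while a single progression model
averages over genuinely distinct patterns. `sustainr` implements subtype and
stage inference (SuStaIn): an unsupervised mixture of event-based progression
models that disentangles the two using only one cross-sectional measurement
per subject.

## The generative model

The data are control-referenced z-scores $x_{ij}$ for biomarkers
$i = 1 \dots I$ and subjects $j = 1 \dots J$ (unitless standard deviations;
abnormality increases positively by convention). Each biomarker carries a
small set of *z-score events* — the times at which it reaches thresholds
$z_{i1} < z_{i2} < \dots$ (1, 2 and 3 by default) — giving $N$ events in
total, plus a terminal value $z_{\max,i}$ reached at the end of progression.

A subtype is an ordering $S$ of all $N$ events. Disease time $t$ runs over
$[0,1]$ (the scale is arbitrary — no calendar-time calibration is attempted);
the event in position $k$ (1-based) completes at $t = k/(N+1)$, and stage $k$
denotes the interval in which exactly $k$ events have completed. Between its
events each biomarker follows the piecewise-linear trajectory $g_i(t)$
through $(0, 0)$, its event points, and $(1, z_{\max,i})$. Measurements are
the trajectory plus Gaussian noise, so

$$P(X \mid S) \;=\; \prod_{j=1}^J \sum_{k=0}^{N}
  \int_{k/(N+1)}^{(k+1)/(N+1)} \prod_{i=1}^I
  \mathcal N\!\left(x_{ij};\, g_i(t),\, \sigma_i\right)\, dt ,$$

with a uniform prior over disease time. A cohort is modelled as a mixture of
$C$ subtypes with proportions $f_c$:
$P(X \mid M) = \sum_c f_c\, P(X \mid S_c)$.

Orderings that would reach a biomarker's higher threshold before a lower one
are excluded from the model space: $g_i$ is non-decreasing, so such
sequences are impossible under the model and likelihood-dominated besides.

### Assumptions worth stating

* Noise is Gaussian, independent across biomarkers given $t$, with constant
  level over the timeframe. After control-referenced z-scoring the natural
  default is $\sigma_i = 1$ (the control SD); pass `sigma` everywhere to
  override, e.g. re-estimated from a control subset.
* The stage prior is uniform: a priori a subject is equally likely to sit
  anywhere along the progression. Cohorts heavily enriched for one stage
  violate this mildly; the likelihood usually dominates.
* Missing measurements are flagged `NA` and marginalised out — they
  contribute a factor of one, preserving the product structure.

## Numerical treatment

The per-stage integral has no closed form. It is approximated by a
composite midpoint rule with `K` points per stage (default `K = 10`, i.e.
`10 * (N + 1)` trajectory evaluations per sequence). Midpoint quadrature is
deterministic and converges at $O(K^{-2})$; the suite checks it against a
$10^5$-point trapezoid oracle (relative error well under $10^{-3}$ at the
default order; increase `K` when terminal segments are very steep, since the
local error scales with the squared trajectory slope). All likelihood
accumulation happens in log space with log-sum-exp; terms more than 40 nats
below the row maximum are dropped (relative mass $< 10^{-17}$).

## Fitting

`fit_single_cluster()` runs greedy coordinate ascent: each event in turn is
tried at every admissible position with the others' order fixed, keeping the
best; passes repeat until nothing moves. Exact ties keep the incumbent
position, making the ascent strictly monotone, terminating and
deterministic given its start. Starts are drawn uniformly over admissible
orderings (random keys, then a stable within-biomarker reorder); 25 restarts
by default guard against local optima. On 5-event problems the suite checks
the restart strategy against exhaustive enumeration of all 120 admissible
sequences.

`fit_hierarchical()` grows the number of subtypes one at a time. Each
$C$-subtype model is seeded from the best $(C-1)$-model by
`split_cluster_em()`: the subjects hard-assigned (maximum posterior) to one
cluster are randomly bipartitioned, each half fitted separately, the pair
refined by two-cluster E-M on those subjects, and the full model then
refined by alternating greedy sequence updates (each maximises the *full
mixture* likelihood with the other subtypes held fixed) and fraction
updates ($f_c$ set to mean posterior membership — the exact M-step). The
split is restarted from `n_restarts` random bipartitions per cluster. E-M
stops when the log likelihood improves by less than `tol` ($10^{-6}$) or
after `max_iter` (100) outer iterations. Restarts happen inside every
split at every level; split candidates can in principle end below the
$(C-1)$ likelihood, in which case the largest cluster is duplicated with
its fraction halved so the in-sample likelihood is never decreasing in $C$.

## Uncertainty

`mcmc_sample()` runs Metropolis-Hastings over the admissible orderings with
a flat prior, initialised at the maximum-likelihood fit (hence no burn-in by
default; both burn-in and thinning are available). One step relocates one
random event of one random subtype to a uniformly random admissible slot — a
symmetric proposal, because the slot count depends only on the order of the
*other* events. With $C > 1$ the fractions are jointly perturbed by a
clipped, renormalised Gaussian step (SD 0.01); set
`sample_fractions = FALSE` to freeze them at the ML estimate. The default
chain length is $10^6$; the validation suite uses $10^5$, where the sampled
posterior on 3-event problems matches exact enumeration to total variation
below 0.05 and the lag-100 autocorrelation of the likelihood trace stays
below 0.5.

`positional_distribution()` reduces the chain to each subtype's event ×
position probability matrix (the positional variance diagram), and
`cumulative_severity_encoding()` gives, per biomarker and stage, the
cumulative probability of having reached z = 1, 2, 3 — the three stacked
colour channels (white→red→magenta→blue) of the progression diagrams.

## How many subtypes?

`cross_validate()` refits the hierarchy on each of 10 folds and evaluates
every candidate $C$ on the held-out subjects. The criterion is
$\mathrm{CVIC}(C) = -2 \sum_{\text{folds}} \log P(X_{\text{test}} \mid M)$,
and `select_n_subtypes()` picks the *smallest* $C$ within 6 CVIC units of
the minimum — a more complex model must earn at least 3 log-likelihood units
out of sample. Folds are seeded random partitions, optionally stratified by
a supplied label (the stratification scheme is this package's choice).
Consistency of the patterns themselves is summarised by the
cross-validation similarity (CVS): each full-data subtype is paired with its
most similar fold subtype by greedy maximum-similarity matching (pairing
method again our choice) and scored with the Bhattacharyya coefficient of
event positions, averaged over events and folds — 1 for identical
positional distributions, 0 for disjoint ones.

## Subjects: subtype, stage, strength

`assign_subjects()` computes each subject's joint subtype × stage posterior
averaged over the MCMC samples (a thinned subset, default 200, rather than
the ML point estimate), so model uncertainty reaches the per-subject level.
The subtype call is the argmax of the stage-marginalised probabilities; the
stage posterior under that subtype is reported as both its argmax and its
mean, since an individual's stage is effectively an average over the
posterior on the ordering. The *strength* of an assignment compares the
pooled probability of stage ≤ 2 (too little abnormality to carry subtype
information — pooled across subtypes, which is our reading of that rule)
with each subtype's mass over stages 3+; assignments are "strong" when the
best subtype's late-stage mass strictly exceeds one half.

`threshold_classify()` turns subtype probabilities into a label classifier:
per-subtype probability thresholds (absorbing unequal within-subtype
heterogeneity) are optimised on training folds by coordinate ascent over a
0.05-step grid maximising balanced accuracy, and accuracy is reported out
of sample over 10 folds. The subtype-to-class correspondence is the
accuracy-maximising permutation chosen on training data.

## Preprocessing

`fit_control_adjustment()` / `to_zscores()` implement control-referenced
z-scoring: per biomarker, covariate effects (age, sex, education, genotype
dose — numeric codes) are estimated on controls by linear regression,
retained only when significant at $\alpha = 0.05$ (per-covariate t-test, no
multiplicity correction — the screening test itself is not dictated by
convention, so ours is documented rather than assumed), and removed; the
control residual mean and SD define the scaling, so controls come out mean
0, SD 1. For biomarkers where disease lowers the raw value (regional
volumes), the sign is flipped so abnormality increases. The transform tags
its output and refuses to run twice. `hemispheric_asymmetry()` provides the
log-transformed left/right asymmetry index as a derived feature computed
before z-scoring.

`select_events()` applies the event-selection rules: candidate thresholds
z = 1, 2, 3 are kept when at least 10 patients exceed them (exceedance sets
are nested, so retained sets are always prefixes), and the terminal
z-score is 2, 3 or 5 according to whether the largest retained threshold is
1, 2 or 3.

## Comparators

`fit_subtypes_only()` is the stage-blind ablation: a Gaussian mixture over
raw profiles with per-cluster means and diagonal covariance (per-dimension
variances — our reading of "unknown mean and variance"; full covariance sits
behind `diagonal = FALSE`), fitted with mclust and selected by the same
CVIC-plus-6 rule. `fit_stages_only()` is the subtype-blind ablation — the
$C = 1$ special case of the main model. On two-subtype synthetic cohorts
the suite checks that stage-aware subtyping beats the Gaussian mixture on
subtype accuracy and that the two-subtype model beats stages-only out of
sample.

## The simulator, and what passing its tests does not show

`simulate_cohort()` draws each subject a subtype from the mixture
fractions, a disease time from the stage distribution (uniform by default,
matching the model prior; truncated-normal and point-mass options emulate
diagnostic-group structure), and observes the trajectories plus Gaussian
noise, optionally equicorrelated across biomarkers through a single shared
factor. Outlier subjects (a configurable fraction) follow no progression
pattern: standard noise around zero with independent standard-normal
per-biomarker shifts. Ground truth (subtype, time, stage) is returned for
scoring by `recovery_report()`, which maximises subject-level accuracy over
subtype permutations (identities are arbitrary) and reuses that permutation
for fractions and positional similarity.

The canonical validation scenario (`canonical_scenario()`) uses 5
biomarkers with events at z = 1, 2, 3 ($N = 15$, terminal z 5), two equal
subtypes, 500 subjects, unit noise and uniform stages. The two true
orderings sweep the biomarkers in opposite orders, each biomarker passing
through its thresholds in turn before the next begins. This emulates
subtypes distinguished by *where* disease starts — the situation the method
targets. It is deliberately favourable: during design we also examined
sequences interleaved threshold-level by threshold-level (both subtypes
mildly abnormal everywhere early on), where even the true generating model
separates subjects poorly — heavily overlapping progression patterns are a
genuine limitation, not a fitting failure. Passing the synthetic suite
therefore shows correct inference under well-separated patterns, Gaussian
noise and the model's own trajectory family; it does not certify behaviour
under model mismatch (non-linear accumulation, heavy-tailed noise,
informative missingness) or subtle real-cohort structure.

Validation problem sizes (the package's choices for a thorough but
desk-scale suite): $J = 500$ for the canonical scenario with hierarchical
fits to $C_{\max} = 3$ at 8 restarts, 10-fold cross-validation at 2
restarts per fold, $10^5$ MCMC samples; 20 seeded trials at $J = 200$ for
the enumeration benchmark; 20 random instances for the quadrature oracle.
`scripts/acceptance.R` reruns all of this from scratch at a user-supplied
seed.

## Worked example

```{r example}
library(sustainr)

cfg <- canonical_scenario(n_subjects = 500, seed = 42)
sim <- simulate_cohort(cfg)

fits <- fit_hierarchical(sim$data, cfg$event_set, C_max = 3,
                         n_restarts = 8, seed = 43)
cv <- cross_validate(sim$data, cfg$event_set, C_max = 3, n_folds = 10,
                     seed = 45, n_restarts = 2)
cv$selected_C

mc <- mcmc_sample(sim$data, fits[[cv$selected_C]]$model,
                  n_samples = 1e5, seed = 44)
plot(positional_distribution(mc), subtype = 1)

asg <- assign_subjects(sim$data, mc)
head(asg$table)

recovery_report(sim, fits[[2]], samples = mc, assignments = asg,
                cv = cv, t_min = 0.2)
```

## Known limitations

* Subtypes are single fixed orderings; a continuous spectrum of orderings
  within a subtype is out of scope.
* The time axis is relative — staging is ordinal, not a calendar forecast.
* Runtime grows roughly with $J \times N^3$ per E-M pass, so very large
  event sets call for fewer candidate thresholds per biomarker.
* The subtypes-only comparator requires complete data; the main model
  tolerates `NA`s but many all-missing subjects dilute staging.
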