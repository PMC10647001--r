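---
title: "Methods: longitudinal CSF proteomics and the OU state-transition model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal CSF proteomics and the OU state-transition model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteostate)
```

This vignette documents the models, the numerical choices, and the
design decisions behind `proteostate`, in the order the pipeline runs.

## The problem

ALS progression speed varies widely between patients. Clinically it is
summarized by the monthly decline of the ALSFRS-R score: fast
progressors (FP) lose ≥ 1 unit/month, slow progressors (SP) < 0.5
(`progression_label()`; intermediate patients are excluded from all
group analyses). The scientific question the package operationalizes is
whether the longitudinal CSF proteome — a protein × sample matrix of
label-free quantitation (LFQ) log-intensities over 3–5 clinic visits per
patient — separates FP from SP, both through individual candidate
markers and through the *variance* of the proteome state over time.

## Synthetic cohorts: what they emulate and what they do not

All tests run on cohorts from `generate_cohort()`. An abundance entry
for protein *p*, patient *i*, visit *v* is built additively on the log2
scale:

> baseline(p) + group shift(p) + patient effect(p, i) +
> batch effect(p, batch(i, v)) + noise(p, i, v)

with the following default calibration (every default is a
`cohort_spec()` argument; units are log2 intensities unless noted):

| parameter | default | why |
|---|---|---|
| `n_fast`, `n_slow` | 6, 5 | the discovery-cohort design |
| `visits_per_patient` | 3–5 | observed visit counts |
| `visit_spacing_months` | 6 | gives 12–24 month spans, matching observed follow-up |
| `n_proteins` | 1150 | scale of an LFQ CSF proteome |
| `n_signal_proteins` | 50 | scale of a cross-sectional candidate panel |
| `group_effect_log2` | 1.5 | clear markers (fold change ≈ 2.8); signs alternate so both up- and down-in-FP markers exist |
| `within_patient_sd_fast` / `_slow` | 0.9 / 0.3 | the elevated visit-to-visit proteome variance of fast progressors (3:1) |
| `patient_random_effect_sd` | 0.4 | between-patient biology |
| `batch_count`, `batch_effect_sd` | 3, 0.3 | additive processing batches |
| `missing_rate`, `missing_mnar_weight` | 0, 0.5 | missingness off by default; see below |

Group shifts are constant over time (slopes ≈ 0): the candidate markers
this design emulates separate the groups at every visit but do not trend
within patients. ALSFRS-R slopes are drawn uniformly from [1.0, 2.7]
(fast) and [0.0, 0.48] (slow), ranges bracketing both observed cohorts,
so relabelling by threshold reproduces the requested group sizes
exactly.

The effect size and patient-effect SD were calibrated jointly so that
the generated cohorts reproduce the two qualitative findings the
downstream stages assume: PC1 of the abundance matrix separates FP from
SP (near-perfect separation at the defaults), and the FP/SP PC1
variance-rate ratio exceeds 1 in roughly 90% of cohorts at the 6/5
cohort size. That 90% is worth dwelling on: the per-cohort ratio is a
median over only 5–6 patients per group, each contributing 2–4 visit
increments, so individual cohorts can invert even under a 3:1 noise
ratio. Tests and the acceptance script therefore aggregate over seeds
rather than asserting on single cohorts.

**Missingness.** LFQ missingness is intensity-dependent. The generator
removes an entry with probability `(1 − w)·r + w·r·2·u`, where `r` is
the target rate, `w` the missing-not-at-random weight and `u` the
(0, 1)-scaled rank of the entry's intensity from the top (low-abundance
entries get `u` near 1). At `w = 0` the realized missing fraction equals
`r` to within ±0.02; at `w = 1` missingness concentrates on faint
proteins. No published missingness mechanism exists for this design, so
it is exposed as a parameter rather than fixed as truth, and downstream
tests drop missing values pairwise — there is no imputation anywhere
except PC1 extraction (protein-mean imputation, flagged).

What the generator does *not* emulate: peptide-level structure,
retention-time drift, correlated protein modules, nonlinear trends, or
dropout of whole visits. Passing tests show the pipeline recovers planted
structure of the kind described above; they do not certify behaviour on
correlated real proteomes.

## Preprocessing

`vst_normalize()` applies `log2(x + 1)` to raw intensities and then a
per-sample affine shift equalizing sample medians. This is a transparent
stand-in for a full variance-stabilizing transform: after log transform,
the dominant between-sample artifact (a multiplicative loading factor)
is an additive offset, which median calibration removes exactly. The
arcsinh-based generalized-log fit is out of scope, and results that
depend on its variance weighting will differ. The operation preserves
within-sample ranks and is idempotent.

`batch_adjust()` removes per-protein batch means and restores the
protein grand mean — the additive special case of standard batch
regression, and exactly the generator's batch model. Singleton batches
are statistically unidentifiable and pass through with a warning.

## Differential abundance and the four-way panel

Each protein is tested FP vs SP by a two-sided Mann–Whitney test with
mid-ranks. At cohort scale (total n ≤ 12 by default) the p-value is
computed by full enumeration of group assignments over the rank vector —
C(11, 5) = 462 assignments for 6-vs-5 — with the two-sided p being twice
the smaller tail, capped at 1. Beyond that, a tie-corrected,
continuity-corrected normal approximation is used. Benjamini–Hochberg
correction runs over all testable proteins (≥ 2 observed values per
group; others are excluded from the family). Significance additionally
requires |log2 FC| ≥ log2(1.5), with the fold change defined as the
difference of group means on the log2 scale.

The candidate panel intersects the significant sets of the four
cross-sectional comparisons — FP/SP at first visits, at last visits, and
both crossings — and by default also requires a consistent fold-change
direction across all four (`require_direction = FALSE` disables this;
observed candidate panels form coherent up/down blocks, which motivates
the default).

**A power boundary worth knowing.** With 6 vs 5 patients the smallest
exact two-sided p is 2/462 ≈ 0.0043, so with ~1,150 tests the smallest
attainable BH-adjusted p for a 50-protein signal set is ≈ 0.10 — the
0.0125 threshold is *unreachable* at that size no matter how large the
effect. Published panels at such thresholds imply a different testing
granularity than the per-protein exact rank test. The package's
power/calibration studies (tests and acceptance script) therefore use
12 + 12 patients, where the normal-approximation regime applies and the
planted 50-marker panel is recovered with median sensitivity ≈ 1 and
false discovery proportion 0.

## rdCV random-forest selection

`rdcv_select()` implements repeated double cross-validation around
`ranger` probability forests. Folds are stratified by *patient* by
default — all visits of a patient stay in one fold — because visits of
one patient are not independent; sample-level folds would leak identity
and overstate accuracy. Within each outer training set, inner folds
drive recursive elimination: permutation importance (averaged over inner
folds; non-finite values from tiny out-of-bag sets are treated as zero)
ranks variables, the lowest `drop_fraction` is removed, and the inner
misclassification count is recorded per panel size. The minimum model —
the smallest size at minimal inner error — is refit on the outer
training set and applied to the held-out fold, giving unbiased
per-sample probabilities of the sample's own class (a sample is
misclassified when its average probability is below 0.5).

Consensus: a repetition selects a protein when any of its outer-fold
minimum models contains it, and the reported panel consists of proteins
selected by at least half the repetitions. The per-fold minimum model is
deliberately parsimonious, so when several markers are individually
sufficient, different folds pick different ones; the per-repetition
union is what stabilizes into the full marker set, and both frequency
tables (`selection_frequency` per repetition, `fold_frequency` per run)
are returned. Defaults (30 repetitions, 6 outer / 5 inner folds, drop
20%, minimum model) follow common rdCV practice; none are published for
this design, so they are package choices.

`swim_lane_table()` reshapes the per-sample probabilities into the
per-patient lane summary (per-visit call, > 0.9 high-confidence flag,
majority patient-level call).

## Panel evaluation

Logistic regression (`glm`, binomial) turns a marker set into per-sample
FP probabilities; under complete separation the score is rebuilt from
capped coefficients and flagged (ranking is preserved, which is all ROC
analysis needs). AUC is the rank statistic (ties half-counted), equal to
the Mann–Whitney U divided by n₁n₀. Confidence intervals are stratified
bootstrap percentile intervals (default 1,000 resamples, 95%); resamples
are drawn within class so no resample is degenerate. The reported
criterion maximizes the Youden index J = sensitivity + specificity − 1,
with ties broken toward higher specificity — the selection rule behind
printed criterion/sensitivity/specificity tables is not standardized,
and Youden is the convention adopted here.

The demographic operations are exact by construction:
`fisher_exact_2x2()` sums hypergeometric probabilities of tables no more
probable than the observed one, and `exact_mann_whitney()` enumerates
all assignments with mid-ranks. On the bundled patient table these
reproduce the published discovery-cohort values (sex p = 0.57,
age-at-onset p = 0.14 = 64/462 at two decimals).

## Marker trajectories

`fit_random_slope_model()` fits, by maximum likelihood,
`value ~ group + group:time + age + (1 + time | patient)` with
group-specific slopes in units/month. Slope significance uses a
likelihood-ratio test of the model with that group's slope removed
rather than Satterthwaite degrees of freedom; the two are asymptotically
equivalent and the package's validation surface is simulation-based
(type-I behaviour of the LRT at this design is mildly anticonservative,
which the tests band accordingly). Singular random-effect covariances
trigger a diagonal-covariance refit, flagged. The age covariate enters
as a main effect only; a group × age interaction is not identifiable at
cohort scale. Degenerate constant inputs short-circuit to a zero fit
rather than entering the optimizer.

## Mutual information

`mutual_information_cd()` is a nearest-neighbour estimator for a
continuous marker against a discrete label: for each sample, the
distance to its k-th (default 3) nearest neighbour within its own class
defines a radius, the number of samples of any class strictly inside
that radius enters a digamma formula, and the result is clipped at zero.
Units are nats; the estimate is bounded by the label entropy (ln 2 ≈
0.693 for balanced classes, ≈ 0.689 for a 6/5 split). The estimator is
exactly invariant to affine maps and approximately invariant to
monotone transforms. Two calibration facts shape the tests: the
clip-at-zero introduces a positive bias that decays with sample size
(null mean < 0.02 nats needs n ≳ 100; calibration suites use n = 400),
and at n ≈ 40 samples the null spread is wide enough that top-20 null
scores around 0.3 nats are normal. Ranking ties are broken by protein ID
for determinism.

## The OU state-transition model

The proteome state is X_t, the projection of each sample onto PC1 of
the protein-centred abundance matrix, oriented so the FP group mean is
≥ the SP mean (the raw PC sign is arbitrary; the convention makes
"higher = further into the FP-like state" stable across runs). Its
dynamics are modelled as an Ornstein–Uhlenbeck process

dX_t = θ(μ − X_t) dt + √(2β⁻¹) dB_t,

mean-reverting toward the attractor μ with rate θ (1/month) and
Brownian fluctuation scale β⁻¹. Stationary variance is β⁻¹/θ and lag-Δ
autocorrelation e^{−θΔ}. The package treats the group contrast
θ_SP < θ_FP, β⁻¹_SP < β⁻¹_FP as the modelled hypothesis: fast
progressors both transition faster and fluctuate more.

Numerical choices:

- **Exact transition sampling.** Simulation draws
  X_{t+Δ} ~ N(μ + (X_t − μ)e^{−θΔ}, (β⁻¹/θ)(1 − e^{−2θΔ})) — no
  Euler–Maruyama step-size bias at any grid spacing, which matters
  because clinic visits are months apart.
- **Likelihood conditions on the first observation** by default: the
  first CSF draw is not the start of the disease process, so the
  stationary density of the first point is optional
  (`condition_first = FALSE`).
- **Fitting** maximizes the summed transition log-likelihood over all
  patients of a group jointly (shared θ, μ, β⁻¹; per-patient paths),
  with positivity enforced by optimizing log θ and log β⁻¹
  (Nelder–Mead, then BFGS polish; initial values from the pooled lag
  correlation and increment variance). μ is shared within a group;
  whether it should be shared *across* groups ("one state of ALS")
  depends on whether PC1 is group-centred — with the package's PC1
  convention the groups sit at different PC1 levels, so per-group μ is
  the default and the correct reading of the attractor.
- **Backcasting** runs the process on [−T, 0] from a pre-symptomatic
  reference state (x = 0 by convention) and, in the default bridge mode,
  conditions on the observed baseline value at t = 0 via the exact OU
  diffusion bridge (each step samples the Gaussian law of the next point
  given the current point and the endpoint). An unconditioned forward
  mode is also available; the bridge is the default because the
  observed baseline is a datum, not a free outcome. Bridge marginals
  were validated against rejection-conditioned forward simulations.
- **`variance_biomarker()`** is the model-free counterpart: per patient,
  the mean squared PC1 increment per month (an estimate of the local
  fluctuation rate 2β⁻¹), summarized by group medians and their FP/SP
  ratio.

Because no fitted parameter values are published for this design, the
model's validation is property-based: closed-form stationary moments,
hand-computed transition densities, parameter recovery (20 patients × 13
visits recovers θ, μ, β⁻¹ within ~35%), and ordering recovery — with
groups simulated at θ 1.0 vs 0.25 and β⁻¹ 2.0 vs 0.5 (8 patients × 6
visits each), both orderings are recovered in ≥ 96% of 50 replicates.

## Pipeline orchestration

`run_pipeline()` chains synth → preprocess → differential → select →
evaluate → trajectories → MI → state transition from one configuration
(R list or YAML), with per-stage sub-seeds derived deterministically from
the global seed, per-stage output files, and a manifest of MD5 hashes; a
stage failure is recorded and downstream stages are skipped. Reruns with
the same configuration are bit-identical. The package deliberately
exposes this as R functions rather than a shell tool: the analysis is
interactive by nature and the functions are the interface.

## Problem sizes used in the validation suites

The shipped tests and `scripts/acceptance.R` use: 1,150-protein cohorts
with 12 + 12 patients for differential power (20 and 5 seeds
respectively), a 303-protein cohort with 3 planted markers for rdCV
(12 repetitions, 6 outer / 4 inner folds, 100 trees), 2,000 paths for OU
stationary checks, 50 replicates for ordering recovery, and n = 400
samples for MI calibration. These sizes were chosen so each property is
measured with comfortable Monte-Carlo margin while the whole suite stays
quick on a laptop.

## Known limitations

- The normalization is a median calibration, not a variance-stabilizing
  fit; heteroscedasticity across the intensity range is not modelled.
- No imputation: proteins missing in a comparison are dropped pairwise,
  and PC1 uses protein-mean imputation, which shrinks variance.
- The OU model is one-dimensional; multi-component state dynamics and
  onset-time (hazard) modelling are out of scope.
- rdCV on 11 patients is inherently unstable; selection frequencies,
  not single panels, are the trustworthy output at that size.
- Synthetic cohorts have independent proteins; correlated protein
  modules would reduce the effective dimensionality of every multivariate
  step and are not emulated.
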