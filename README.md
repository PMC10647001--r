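# proteostate

Longitudinal cerebrospinal-fluid (CSF) proteomics tools for separating
fast-progressing (FP) from slow-progressing (SP) amyotrophic lateral
sclerosis (ALS), built around a stochastic state-transition model of the
proteome.

ALS progression rate is defined clinically from the monthly decline of
the revised ALS Functional Rating Scale (ALSFRS-R): FP patients lose at
least 1 unit/month, SP patients less than 0.5. Given a protein-by-sample
log-intensity matrix (label-free quantitation, missing values allowed)
and per-sample metadata (patient, visit, months from baseline, batch,
clinical covariates), the package provides the full discovery pipeline:

- **Preprocessing** — log2 + per-sample median calibration, additive
  per-batch adjustment, missingness filtering.
- **Differential abundance** — per-protein two-sided Mann–Whitney tests
  (exact mid-rank enumeration at cohort scale), Benjamini–Hochberg
  correction, significance at fold change > 1.5 and adjusted p ≤ 0.0125;
  a candidate panel is the direction-consistent intersection of the four
  cross-sectional FP-vs-SP comparisons (first/last visit crossed).
- **Panel selection** — repeated double cross-validation (rdCV) random
  forests: outer folds estimate error on held-out patients, inner folds
  drive recursive elimination by permutation importance; swim-lane
  summaries of per-visit class probabilities.
- **Panel evaluation** — logistic panel scores, rank-based ROC AUC with
  stratified bootstrap percentile CIs, Youden-optimal criterion, and the
  exact demographic tests (Fisher's exact and exact Mann–Whitney tests
  used for cohort tables).
- **Trajectories** — random-slope, random-intercept linear mixed models
  of marker abundance over months with an age covariate (`lme4`),
  slope significance by likelihood-ratio test.
- **Mutual information** — nearest-neighbour continuous–discrete MI
  (k = 3, nats) ranking proteins against the FP/SP label.
- **State transition** — the proteome state X_t (PC1 of the abundance
  matrix) is modelled as an Ornstein–Uhlenbeck diffusion

  dX_t = θ(μ − X_t) dt + √(2β⁻¹) dB_t

  with rate constant θ (1/month), attractor μ (the "state of ALS"), and
  fluctuation scale β⁻¹ (proteome entropy rate). Exact-transition
  simulation, joint maximum-likelihood fitting per progression group,
  visit-time downsampling, a per-patient proteome-variance statistic, and
  diffusion-bridge backcasting to pre-symptomatic time are provided. The
  package's working hypothesis, encoded in its generator and tests, is
  θ_SP < θ_FP and β⁻¹_SP < β⁻¹_FP: fast progressors carry more proteome
  variance per month.

A seeded synthetic-cohort generator (`cohort_spec()`, `generate_cohort()`)
emulates the study design end to end — 6 FP / 5 SP patients, 3–5 visits
over months, ~1,150 proteins with a planted signal subset, batch
structure and intensity-dependent missingness — so every stage is
testable without any external download.

## Worked example

```r
library(proteostate)

# published demographics: label the cohorts and run the exact tests
disc <- demographics_tests("discovery")
cat(sprintf("discovery: %d FP / %d SP; sex Fisher p = %.2f; age-at-onset MW p = %.2f\n",
            disc$n_fast, disc$n_slow, disc$sex_fisher_p, disc$age_onset_mw_p))

# synthetic cohort -> differential panel -> OU state-transition model
cohort <- generate_cohort(cohort_spec(
  n_fast = 12, n_slow = 12, n_proteins = 600, n_signal_proteins = 30,
  group_effect_log2 = 2, seed = 42
))
mat <- batch_adjust(vst_normalize(cohort$matrix), cohort$metadata)
panel <- four_way_panel(mat, cohort$metadata)
cat(sprintf("four-way panel: %d proteins, %d of %d planted markers recovered\n",
            length(panel$panel),
            length(intersect(panel$panel, cohort$truth$signal_proteins)), 30))

traj <- pc1_trajectories(mat, cohort$metadata)
fits <- fit_ou(traj)
for (g in names(fits)) {
  p <- fits[[g]]$params
  cat(sprintf("OU fit %s: theta = %.2f /month, mu = %.1f, beta_inv = %.2f\n",
              g, p$theta, p$mu, p$beta_inv))
}
vb <- variance_biomarker(traj)
cat(sprintf("PC1 variance-rate ratio FP/SP = %.1f\n", vb$ratio))
```

This prints:

```
discovery: 6 FP / 5 SP; sex Fisher p = 0.57; age-at-onset MW p = 0.14
four-way panel: 20 proteins, 20 of 30 planted markers recovered
OU fit FP: theta = 0.18 /month, mu = 6.3, beta_inv = 0.36
OU fit SP: theta = 0.31 /month, mu = -5.9, beta_inv = 0.07
PC1 variance-rate ratio FP/SP = 3.4
```

Reading it: the bundled patient table splits into 6 fast and 5 slow
progressors with no significant demographic imbalance (p = 0.57, 0.14).
On the synthetic cohort, the four-way intersection panel recovers 20
planted markers with zero false positives (the default generator's fast
group is deliberately noisy, which costs some sensitivity — see the
vignette). The OU fits put the two groups at well-separated attractors on
the PC1 axis with a five-fold higher fluctuation scale β⁻¹ in FP, and the
model-free variance statistic agrees (ratio 3.4): proteome instability
tracks progression speed.

`run_pipeline()` chains all stages from one configuration (list or YAML)
and writes per-stage outputs plus a seeded, hash-stamped manifest.

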