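---
title: "Modeling Top Cognitive Performance from regional cortical thickness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling Top Cognitive Performance from regional cortical thickness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question and the model

Some elderly individuals maintain unusually good memory and executive
function into their 70s, 80s and 90s. A recurring claim in the
successful-aging literature is that the cingulate cortex is structurally
preserved in such people. `tcpthick` implements a pipeline for the
sharper question behind that claim: *how well can regional cortical
thickness model high cognitive status at all, and is the predictive
value localized (cingulate), distributed as a gradient, or absent?*

The pipeline's components:

1. **TCP labeling.** A subject is a Top Cognitive Performer (TCP) when
   they score at or above the 50th percentile of the analyzed sample on
   *both* a delayed-recall memory test (higher is better) and the Trail
   Making Test part B completion time (lower is better). Percentiles
   are computed within the cohort (or within age decade), self
   included; ties at the median count as passing.
2. **Two logistic models of TCP status.** An a priori model on the six
   bilateral cingulate ROIs (caudal anterior, rostral anterior,
   posterior), and a forward-selection model over all 62
   Desikan-Killiany-Tourville (DKT) cortical ROIs. Both are ordinary
   maximum-likelihood logistic regressions,
   `logit P(TCP) = b0 + sum(b_i * x_i)` with `x_i` the ROI mean
   thicknesses in mm.
3. **Apparent ROC/AUC with a permutation null.** Performance is
   summarized by the in-sample (apparent) AUC — the Mann-Whitney
   pairwise concordance of the fitted probabilities. Because apparent
   AUCs are optimistic (severely so after selecting 7-ish predictors
   from 62), significance comes from an empirical null: shuffle the TCP
   labels K times, *rebuild the entire model each time* (including the
   forward selection), and report
   `alpha = (1 + #[null AUC >= observed AUC]) / (K_ok + 1)`.
4. **A DeLong contrast** between the two models' correlated AUCs
   (placement-value covariance, two-sided normal reference).
5. **Bootstrap selection-frequency analysis.** Stratified bootstrap
   samples (observed TCP / non-TCP counts, drawn with replacement
   within stratum) re-run the forward selection; each ROI's selection
   frequency estimates its predictive reliability across plausible
   samples. A shuffled-label rerun of the identical procedure gives the
   chance baseline, and the sorted frequency curve is classified as
   flat-at-chance / flat-above-chance / step / gradient.

# The synthetic cohort: what it emulates and what it does not

The cohorts this analysis design comes from (NACC; The 90+ Study) are
restricted-access, so the package ships a generative stand-in,
`synthetic_config()` + `generate_cohort()`. Its defaults are the study
conditions: 347 subjects aged 70-89 (decades mixed 244:103), 62 ROI
thicknesses with field-typical means (1.7-3.3 mm) and SD 0.2 mm, ~61%
female, education ~15 (SD 3.4) years, and a TCP base rate near 30%.

Structural choices, made once:

* **Exchangeable ROI correlation** (default rho = 0.3), with an
  optionally stronger correlation between left/right homologous pairs
  (default equal to rho). No empirical DKT covariance is published for
  these samples; exchangeability keeps every downstream property
  analytically checkable. Real thickness covariance is block-structured
  by lobe and network — one reason passing tests here do not certify
  behavior on real data.
* **Planted signal.** Latent cognition is the standardized mean of the
  signal ROIs' thickness deviates, scaled by `signal_effect` (in SD
  units), plus unit noise, then re-standardized. Both cognitive scores
  load on this latent; the memory score linearly, the Trails-B time as
  a decreasing lognormal (completion times are positively skewed).
* **Base-rate calibration.** TCP thresholds both scores at their
  within-sample medians, so on the latent scale the TCP rate is the
  bivariate-normal quadrant probability `1/4 + asin(r) / (2*pi)` in the
  score-score correlation `r`. The generator inverts this:
  `r = sin(2*pi*(target - 1/4))`, giving a realized rate within
  sampling error of the target (default 0.303) at any `signal_effect`,
  because the latent is standardized before the scores are formed.
* **Demographics are independent of cognition by default**; an
  `education_confound` knob (years shifted per SD of latent cognition)
  exists to emulate the education differences real TCP groups show.
* The default *analysis* cohort (see `analysis/01_simulate_cohort.R`)
  plants four signal ROIs spanning limbic and association cortex at
  effect 1.0 SD, so the end-to-end run exercises the distributed-signal
  regime the pipeline is designed to detect.

What the generator does **not** emulate: scanner/site effects,
age-related thinning gradients, spatially structured atrophy, missing
data mechanisms, or volunteer bias. Tests passing on synthetic cohorts
validate the *machinery*, not claims about any real population.

# Numerical and procedural choices

* **Logistic fits** use IRLS (`stats::glm.fit`) with log-likelihood
  tolerance 1e-8 and at most 100 iterations. Complete or quasi-complete
  separation is flagged (`separation = TRUE`, coefficients capped at
  +/-1000) rather than thrown: resampling loops need fits that fail
  soft.
* **Forward-selection entry test.** Classic stepwise software frames
  the entry criterion as an "F test"; for a logistic model the natural
  equivalent is the likelihood-ratio chi-square for adding one
  predictor, which is the default here (`method = "lrt"`, warm-started
  from the current fit). The Rao score test — the other classic
  stepwise criterion, ~30x faster since it needs no refit per candidate
  — is available as `method = "score"`. Entry cutoff p <= 0.25,
  smallest p enters, ties break by canonical ROI order, nothing is ever
  removed. With 62 correlated candidates and no signal this enters
  roughly 8-12 ROIs before stopping — selection on noise is exactly the
  optimism the permutation null absorbs.
* **Covariate-augmented models** refit the *already selected* ROI set
  with age / sex / education forced in; covariates do not participate
  in selection. Education enters as years when numeric, as two dummy
  columns for the 3-level category.
* **Permutation / bootstrap stream discipline.** Each iteration gets an
  independent child seed drawn once from the run seed, so results are
  reproducible and iterations are order-independent. Failed iterations
  (fit error, or a selection path ending in separation) are excluded
  from the denominator and counted, never retried.
* **The add-one alpha** `(1+r)/(K+1)` is never exactly zero; with
  K = 10,000 the smallest reportable alpha is ~1e-4.
* **Shape classifier.** The four hypothesis shapes are fit to the
  descending-sorted frequencies by least squares (constant-at-chance: 0
  parameters; free constant: 1; two-level step with scanned breakpoint:
  3; linear ramp: 2) and compared by AIC. *Limitation:* sorting is not
  noise-neutral — the sorted curve of a truly flat profile with
  finite-B binomial noise acquires a monotone trend, which the ramp
  model fits well. The flat labels are therefore reliable only for
  profiles whose level is (near-)constant before sorting, i.e. at large
  B; with B in the hundreds, flat-but-noisy profiles lean "gradient".
* **Degenerate inputs.** One-class labels error everywhere; a DeLong
  contrast of identical (or both-constant) score sets returns p = 1,
  while zero placement variance with unequal AUCs errors; an ROI whose
  voxels all fall below the 1 mm clip errors (it signals a mask or
  registration failure, not a thin cortex).

# Problem sizes

The shipped analysis scripts default to desk-scale resampling depths —
K = 200 permutations and B = 100 bootstrap iterations at n = 347 — and
expose `--full` for the publication-scale K = 10,000 / B = 1,000 (the
`run_config()` defaults). The whole-brain permutation and both
selection-frequency stages re-run the complete forward selection per
iteration, which is the honest but expensive null: roughly one second
per 62-ROI selection path at n = 347. Calibration-style tests
(permutation uniformity, type-I error of the DeLong contrast, parameter
recovery at n = 50,000) use the sizes at which their tolerances were
derived.

# Known limitations

* Apparent AUC is reported by design (matching the analysis this
  pipeline reimplements); no cross-validated or shrunken performance
  estimate is offered.
* The forward-selection path is greedy; with strongly collinear ROIs
  the entered set is sample-dependent — that instability is not a bug
  but the very phenomenon the bootstrap stage quantifies.
* The synthetic generator's exchangeable covariance makes all null ROIs
  statistically interchangeable; real selection-frequency profiles will
  ride on anatomical correlation structure the generator does not
  model. For the same reason a planted regional effect leaks into the
  volume-weighted global thickness (TCP groups differ globally on
  synthetic cohorts), whereas real cohorts can show regional
  discrimination with no global difference.
* Percentile norms are internal to the analyzed sample. TCP status is
  relative to the (self-selected, healthy, educated) cohort, not to
  population norms.
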