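# tcpthick

Can regional cortical thickness model who stays cognitively sharp in old
age — and if so, is the predictive value concentrated in a few regions
(the cingulate cortex, per the successful-aging literature), spread as a
gradient across the cortex, or absent? `tcpthick` implements the full
analysis pipeline for this question as a tested R package plus a set of
numbered analysis scripts.

It is written for biostatisticians and aging researchers working with
cohort-style tabular data: one row per subject with demographics, two
cognitive scores, and mean thickness (mm) for the 62 cortical regions of
the Desikan–Killiany–Tourville (DKT) atlas. The cohorts this design
targets (NACC, available by request from naccdata.org; The 90+ Study,
not public) are restricted, so the package includes a synthetic cohort
generator with planted thickness–cognition effects that reproduces the
statistical structure the pipeline assumes — every stage is testable
without restricted data.

## The method

* **TCP labeling.** A subject is a *Top Cognitive Performer* when they
  perform at or above the 50th percentile of the analyzed sample on
  **both** a delayed-recall memory score (higher better) and Trails-B
  completion time (lower better). Multi-visit cohorts can use the
  median of up to four visits closest to the MRI scan date.
* **Two logistic models of TCP status.**
  `Logit(TCP) = β₀ + Σ βᵢ·x_ROIᵢ`, with (1) the six bilateral a priori
  cingulate ROIs, and (2) forward selection over all 62 ROIs
  (likelihood-ratio entry test, cutoff p ≤ 0.25).
* **Apparent AUC with a permutation null.** Model accuracy is the
  in-sample Mann–Whitney AUC of the fitted probabilities. Its
  significance is an empirical alpha: shuffle the labels K times,
  rebuild the *entire* model per shuffle (including the forward
  selection), and report `α = (1 + #{null AUC ≥ observed}) / (K + 1)`.
* **DeLong contrast** between the two models' correlated AUCs.
* **Bootstrap selection frequencies.** Stratified bootstrap resamples
  re-run the forward selection; each ROI's selection frequency, against
  a shuffled-label chance baseline, maps where predictive value lives.
  The sorted frequency curve is classified (least-squares + AIC) as
  flat-at-chance / flat-above-chance / step / gradient.
* **Group statistics.** Pooled two-sample t (raw data or published
  summary statistics), Fisher's exact test, Pearson chi-square — the
  standard cohort demographics table.

## Worked example

```r
library(tcpthick)

signal <- c("L_entorhinal", "L_caudal_middle_frontal",
            "L_medial_orbitofrontal", "R_superior_frontal")
cfg <- synthetic_config(n_subjects = 347, signal_rois = signal,
                        signal_effect = 1.0, seed = 42)
cohort <- label_cohort(generate_cohort(cfg))
cohort
#> <tcp_cohort> 347 subjects, 62 ROIs; 111 TCP (32%)

X <- thickness_matrix(cohort)
y <- as.integer(cohort$subjects$is_tcp)

cing <- fit_logistic(X[, cingulate_roi_set()], y)
auc(cing$fitted, y)
#> 0.673

wb <- forward_select(X, y, entry_p = 0.25)
head(wb$trace, 3)
#>   step       chosen      p_value n_candidates
#> 1    1    L_lingual 6.038632e-08           62
#> 2    2 L_entorhinal 6.090915e-05           61
#> 3    3  L_precuneus 1.707384e-03           60

delong_contrast(wb$model$fitted, cing$fitted, y)
#> <auc_contrast> 0.8561 vs 0.6729, z = 5.943, p = 2.796e-09

permutation_alpha(X, y, function(Xm, yy)
  fit_logistic(Xm[, cingulate_roi_set()], yy)$fitted, K = 199, seed = 1)
#> <perm_result> observed AUC = 0.6729, alpha = 0.005 (K = 199)
```

Reading: on a cohort with four planted signal ROIs, the localist
cingulate model reaches an apparent AUC of 0.67 (none of its six ROIs
carry planted signal; they borrow it through inter-ROI correlation),
while the whole-brain forward-selected model reaches 0.86 — a reliable
difference by the DeLong contrast. The cingulate model's 0.67 is itself
better than chance (permutation α = 0.005): the permutation null — not
0.5 — is the right reference for apparent AUCs.

## The analysis workflow

Numbered scripts under `analysis/` run the full study end-to-end and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R        # synthetic study cohort
Rscript analysis/02_label_tcp.R              # exclusions, TCP labels, demographics
Rscript analysis/03_fit_models.R             # cingulate + whole-brain models, ROC, DeLong
Rscript analysis/04_permutation_null.R       # permutation alphas (--full for K = 10,000)
Rscript analysis/05_bootstrap_selection.R    # selection frequencies + chance baseline (--full for B = 1,000)
Rscript analysis/06_group_tables.R           # published-table group comparisons
```

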