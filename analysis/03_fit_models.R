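#!/usr/bin/env Rscript
# Stage 3: the two logistic models of TCP status and their ROC contrast.
#
# Model 1: the a priori six-ROI bilateral cingulate model. Model 2:
# forward selection over all 62 DKT ROIs (likelihood-ratio entry test,
# cutoff p = 0.25). Apparent AUCs are compared with the DeLong
# correlated-AUC contrast; their significance is deferred to the
# permutation stage, which rebuilds each model per label shuffle.

suppressPackageStartupMessages(library(tcpthick))

cohort <- read_cohort(file.path("results", "cohort", "cohort.csv"))
cohort <- label_cohort(apply_exclusions(cohort))
X <- thickness_matrix(cohort)
y <- as.integer(cohort$subjects$is_tcp)
dir.create(file.path("results", "models"), showWarnings = FALSE,
           recursive = TRUE)

cing <- fit_logistic(X[, cingulate_roi_set()], y)
cing_roc <- roc_curve(cing$fitted, y)
cat("A priori cingulate model:\n  ", model_equation(cing), "\n")
utils::write.csv(coefficient_tests(cing),
                 file.path("results", "models", "cingulate_tests.csv"),
                 row.names = FALSE)

wb <- forward_select(X, y, entry_p = 0.25)
wb_roc <- roc_curve(wb$model$fitted, y)
cat("Whole-brain forward selection entered", length(wb$selected),
    "ROIs:\n  ", model_equation(wb$model), "\n")
utils::write.csv(wb$trace,
                 file.path("results", "models", "selection_trace.csv"),
                 row.names = FALSE)

ct <- delong_contrast(wb$model$fitted, cing$fitted, y)
cat(sprintf("Apparent AUC: cingulate %.3f, whole-brain %.3f (DeLong p = %.4g)\n",
            cing_roc$auc, wb_roc$auc, ct$p))

cov_tab <- covariate_auc_table(cohort, wb$selected, y)
utils::write.csv(cov_tab,
                 file.path("results", "models", "covariate_aucs.csv"),
                 row.names = FALSE)
cat("Covariate-augmented AUCs (age/sex/education add little beyond ROIs):\n")
print(cov_tab)

for (nm in c("cingulate", "whole_brain")) {
  r <- if (nm == "cingulate") cing_roc else wb_roc
  utils::write.csv(data.frame(fpr = r$fpr, tpr = r$tpr),
                   file.path("results", "models", paste0("roc_", nm, ".csv")),
                   row.names = FALSE)
}
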