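#!/usr/bin/env Rscript
# Stage 2: exclusions, TCP labeling and demographic comparisons.
#
# Subjects at or above the within-cohort median on both the memory score
# and Trails-B completion time are Top Cognitive Performers. The
# demographic table then mirrors the standard cohort report: age, sex,
# education and volume-weighted global thickness compared across groups.

suppressPackageStartupMessages(library(tcpthick))

cohort <- read_cohort(file.path("results", "cohort", "cohort.csv"),
                      visits_path = file.path("results", "cohort",
                                              "visits.csv"))
cohort <- apply_exclusions(cohort)
cohort <- label_cohort(cohort, tcp_criteria())

dir.create(file.path("results", "labels"), recursive = TRUE,
           showWarnings = FALSE)
utils::write.csv(cohort$tcp_labels,
                 file.path("results", "labels", "tcp_labels.csv"),
                 row.names = FALSE)
demog <- demographics_table(cohort)
utils::write.csv(demog, file.path("results", "labels", "demographics.csv"),
                 row.names = FALSE)

cat(sprintf("Labeled %d of %d subjects TCP (%.1f%%).\n",
            sum(cohort$subjects$is_tcp), nrow(cohort$subjects),
            100 * mean(cohort$subjects$is_tcp)))
cat("Volume-weighted global-thickness group difference: t =",
    round(demog$statistic[demog$variable == "global_thickness"], 2),
    "\n(note: the generator's exchangeable ROI correlation propagates a",
    "planted\nregional signal into the global mean; real cohorts showed no",
    "global difference).\n")
print(demog)
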