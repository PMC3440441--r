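#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Generates a seeded synthetic Cold/Heat rheumatoid-arthritis cohort with
# the published study design: 20 Cold + 19 Heat subjects, a 57-item symptom
# questionnaire (1-7 severity scales, 15 items without variation), 40
# clinical-chemistry variables (monotone and nonmonotone class relations),
# and urine (14+14) / plasma (11+14) LC-MS feature tables with 1000
# features each, planted 2log fold changes taken from the published
# discriminator tables, detection-limit zeros and pooled-QC drift.
# Writes the cohort and its ground truth under results/cohort/.
#
# Usage: Rscript analysis/01_simulate.R [seed]

library(coldheat)
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

cfg <- cohort_config(seed = seed)
co <- generate_cohort(cfg)
paths <- write_cohort(co, "results/cohort")

message(sprintf("cohort: %d Cold + %d Heat subjects", cfg$n_cold, cfg$n_heat))
message(sprintf("questionnaire: %d items (%d constant, %d sparse, %d informative)",
                cfg$n_items, cfg$n_constant_items, cfg$n_sparse_items,
                cfg$n_informative_items))
message(sprintf("urine: %d x %d; plasma: %d x %d (plus %d QC injections each)",
                nrow(co$urine$table$intensities), cfg$n_features_urine,
                nrow(co$plasma$table$intensities), cfg$n_features_plasma,
                cfg$n_qc))
message("wrote: ", paste(basename(paths), collapse = ", "))
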