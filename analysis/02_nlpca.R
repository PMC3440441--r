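#!/usr/bin/env Rscript
# Stage 2 — questionnaire + clinical chemistry analysis.
#
# The forced-classification nonlinear PCA protocol: merge sparse scoring
# categories (<7 observations), drop single-category items, bin clinical
# values into 19 uniform categories, compare analysis levels for the
# clinical variables (numeric vs spline-ordinal vs spline-nominal; 1 vs 2
# interior knots), fit the forced model with class weight 1000, select
# variables with VAF > 0.20, estimate the classification error by
# stratified leave-two-out CV, and test significance by label permutation.
# Writes loadings (Table-2 shape), transformation tables (per-category
# quantifications), the CV log and the permutation null under results/.
#
# Usage: Rscript analysis/02_nlpca.R [seed] [n_permutations]

library(coldheat)
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
n_perm <- if (length(args) >= 2) as.integer(args[2]) else 100L
cfg <- run_config(seed = seed, n_permutations = n_perm)

co <- load_cohort("results/cohort")
labels <- factor(co$labels, levels = c("Cold", "Heat"))

## questionnaire preprocessing -------------------------------------------------
ds_q <- cat_dataset(co$questionnaire, scaling_spec("ordinal"))
merged <- merge_sparse_categories(ds_q, cfg$min_category_count)
dropped <- drop_single_category_variables(merged$dataset)
message(sprintf("items: %d -> %d after merging and removing %d constant items",
                ncol(co$questionnaire), ncol(dropped$dataset$data),
                length(dropped$removed)))

## clinical binning ------------------------------------------------------------
bins <- apply(co$clinical, 2, bin_clinical, n_bins = cfg$n_bins)
rownames(bins) <- rownames(co$clinical)

## analysis-level comparison for the clinical variables ------------------------
ds_num <- cat_dataset(bins, scaling_spec("numeric"))
specs_of <- function(spec) setNames(rep(list(spec), ncol(bins)), colnames(bins))
cmp <- compare_analysis_levels(
  ds_num, labels,
  list(numeric = specs_of(scaling_spec("numeric")),
       spline_ordinal_1k = specs_of(scaling_spec("spline-ordinal", 2, 1)),
       spline_nominal_1k = specs_of(scaling_spec("spline-nominal", 2, 1)),
       spline_nominal_2k = specs_of(scaling_spec("spline-nominal", 2, 2))),
  class_weight = cfg$class_weight, seed = cfg$seed)
print(transform(cmp$summary,
                total_vaf_substantive = vapply(cmp$models, function(m)
                  m$total_vaf_substantive, 0)))
message("largest per-variable gain between consecutive levels:")
print(cmp$top_gain)
write.csv(cmp$summary, "results/nlpca_level_comparison.csv", row.names = FALSE)

## full protocol: fit, select VAF > 0.20, leave-two-out CV ---------------------
ds <- cat_dataset(cbind(dropped$dataset$data, bins),
                  c(dropped$dataset$specs,
                    specs_of(scaling_spec("spline-nominal", 2, 1))))
prot <- nlpca_protocol(ds, labels, vaf_threshold = cfg$vaf_threshold,
                       class_weight = cfg$class_weight, seed = cfg$seed)
message(sprintf("final model: %d selected variables, total VAF %.1f%%, CV error %.1f%%",
                nrow(prot$selected), 100 * prot$model$total_vaf_substantive,
                100 * prot$cv$error))
write.csv(prot$selected, "results/nlpca_loadings.csv", row.names = FALSE)

trans <- do.call(rbind, lapply(names(prot$model$quantifications), function(v)
  cbind(variable = v, prot$model$quantifications[[v]])))
write.csv(trans, "results/nlpca_transformations.csv", row.names = FALSE)
write.csv(prot$cv$predictions, "results/nlpca_cv_log.csv", row.names = FALSE)

## permutation test ------------------------------------------------------------
pt <- permutation_test_nlpca(ds, labels, n_permutations = cfg$n_permutations,
                             seed = cfg$seed)
message(sprintf("permutation test: observed error %.1f%%, null mean %.1f%%, p = %.4f",
                100 * pt$observed, 100 * mean(pt$null), pt$p_value))
write.csv(data.frame(null_error = pt$null), "results/nlpca_permutation_null.csv",
          row.names = FALSE)
write_report(list(
  n_items_retained = ncol(dropped$dataset$data),
  removed_items = dropped$removed,
  level_comparison = cmp$summary,
  selected = prot$selected,
  total_vaf = prot$model$total_vaf_substantive,
  cv_error = prot$cv$error,
  permutation_p = pt$p_value), "results/nlpca_report.json", config = cfg)
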