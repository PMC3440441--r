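# compact cohort configurations used across tests (small for speed)

small_config <- function(seed = 1L, ...) {
  args <- list(n_cold = 13L, n_heat = 13L,
               n_items = 20L, n_constant_items = 3L, n_sparse_items = 3L,
               n_informative_items = 8L,
               n_clinical = 10L, n_monotone_clinical = 3L,
               n_quadratic_clinical = 1L,
               n_features_urine = 120L, n_features_plasma = 120L,
               n_informative_features = 10L,
               log2_effects = c(-0.73, -0.70, -0.89, -0.75, -2.40,
                                -0.98, -0.92, -0.55, -1.21, 0.42),
               missing_rate = 0.1, n_qc = 5L,
               urine_n = c(cold = 8L, heat = 8L),
               plasma_n = c(cold = 8L, heat = 8L),
               seed = seed)
  do.call(cohort_config, utils::modifyList(args, list(...)))
}

# questionnaire -> merged, recoded, single-category-free cat_dataset
prep_questionnaire <- function(cohort, min_count = 7L) {
  ds <- cat_dataset(cohort$questionnaire$data, scaling_spec("ordinal"))
  ds <- merge_sparse_categories(ds, min_count)$dataset
  drop_single_category_variables(ds)$dataset
}

# study-sample intensity matrix of a preprocessed compartment table
prep_compartment <- function(gen, min_fraction = 0.8) {
  tab <- replace_zeros(filter_presence(gen$table, min_fraction)$table)
  list(X = tab$intensities[which(!tab$samples$is_qc), , drop = FALSE],
       y = gen$labels, table = tab)
}

# brute-force weighted monotone LS fit: enumerate all partitions of 1..k
# into consecutive blocks, fit block-wise weighted means, keep feasible
# (nondecreasing) fits, return the minimum-SSE one
brute_monotone <- function(values, weights) {
  k <- length(values)
  best <- NULL; best_sse <- Inf
  # each of 2^(k-1) cut patterns defines a partition into consecutive blocks
  for (mask in 0:(2^(k - 1L) - 1L)) {
    cuts <- which(bitwAnd(mask, 2^(seq_len(k - 1L) - 1L)) > 0)
    bounds <- c(0L, cuts, k)
    fit <- numeric(k)
    for (b in seq_len(length(bounds) - 1L)) {
      i <- (bounds[b] + 1L):bounds[b + 1L]
      fit[i] <- sum(values[i] * weights[i]) / sum(weights[i])
    }
    if (is.unsorted(fit)) next
    sse <- sum(weights * (values - fit)^2)
    if (sse < best_sse - 1e-12) { best_sse <- sse; best <- fit }
  }
  best
}

# brute-force Mann-Whitney U statistic (pairwise count, ties count 1/2)
brute_u <- function(g1, g2) {
  sum(outer(g1, g2, ">")) + 0.5 * sum(outer(g1, g2, "=="))
}
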