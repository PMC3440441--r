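test_that("cohort configuration enforces its invariants", {
  expect_error(cohort_config(n_cold = 3, n_heat = 3), "n_cold \\+ n_heat")
  expect_error(cohort_config(missing_rate = 1), "missing_rate")
  expect_error(cohort_config(n_informative_features = 3,
                             log2_effects = c(-1, 1)), "length")
  expect_error(cohort_config(n_items = 10, n_constant_items = 8,
                             n_sparse_items = 8), "exceed")
})

test_that("generation is deterministic given the seed", {
  a <- generate_cohort(small_config(seed = 7))
  b <- generate_cohort(small_config(seed = 7))
  expect_identical(a$questionnaire$data, b$questionnaire$data)
  expect_identical(a$clinical$data, b$clinical$data)
  expect_identical(a$urine$table$intensities, b$urine$table$intensities)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(small_config(seed = 8))
  expect_false(identical(a$questionnaire$data, c$questionnaire$data))
})

test_that("questionnaire matches the designed item structure", {
  cfg <- cohort_config(seed = 2)
  q <- generate_questionnaire(cfg)
  expect_equal(dim(q$data), c(39L, 57L))
  expect_true(all(q$data >= 1 & q$data <= 7))
  ncat <- apply(q$data, 2, function(y) length(unique(y)))
  expect_equal(sum(ncat == 1L), 15L)             # constant items
  expect_equal(sum(ncat > 1L), 42L)
  # designated sparse items carry a category with < 7 observations;
  # all other variable items are fully supported
  sparse_flag <- apply(q$data, 2, function(y) any(table(y) < 7))
  expect_true(all(sparse_flag[q$truth$sparse_item_ids]))
  variable_items <- setdiff(colnames(q$data)[ncat > 1L],
                            q$truth$sparse_item_ids)
  expect_false(any(sparse_flag[variable_items]))
})

test_that("null questionnaire shows no class association", {
  pvals <- unlist(lapply(1:3, function(s) {
    cfg <- cohort_config(seed = 50 + s, n_informative_items = 0L)
    q <- generate_questionnaire(cfg)
    ncat <- apply(q$data, 2, function(y) length(unique(y)))
    apply(q$data[, ncat > 1L], 2, function(y)
      suppressWarnings(wilcox.test(y ~ q$labels, exact = FALSE))$p.value)
  }))
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("quadratic clinical variables enrich the extreme bins in Heat", {
  cfg <- cohort_config(seed = 3, n_cold = 200, n_heat = 200)
  cl <- generate_clinical(cfg)
  qvar <- cl$truth$id[cl$truth$relation == "quadratic"][1]
  bins <- bin_clinical(cl$data[, qvar], 19L)
  extreme <- bins <= 4 | bins >= 16
  p_heat <- mean(extreme[cl$labels == "Heat"])
  p_cold <- mean(extreme[cl$labels == "Cold"])
  expect_gt(p_heat, p_cold + 0.1)
  # and the class means barely differ (the relation is nonmonotone)
  expect_lt(abs(mean(cl$data[cl$labels == "Heat", qvar]) -
                mean(cl$data[cl$labels == "Cold", qvar])), 0.3)
})

test_that("null clinical variables reject at the nominal t-test rate", {
  cfg <- cohort_config(seed = 9, n_clinical = 1000,
                       n_monotone_clinical = 0L, n_quadratic_clinical = 0L)
  cl <- generate_clinical(cfg)
  p <- apply(cl$data, 2, function(v) t.test(v ~ cl$labels)$p.value)
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.09)
})

test_that("planted feature effects are recovered at large n", {
  # acetylcarnitine-like effect of -0.75 recovered within +-0.1 at
  # n = 500/class, and the estimator is unbiased across seeds
  devs <- vapply(1:6, function(s) {
    cfg <- cohort_config(seed = s, n_cold = 500, n_heat = 500,
                         urine_n = c(cold = 500, heat = 500),
                         n_features_urine = 20, n_informative_features = 2,
                         log2_effects = c(-0.75, -0.5), missing_rate = 0)
    ur <- generate_feature_table(cfg, "urine")
    si <- which(!ur$table$samples$is_qc)
    acetyl <- names(ur$truth$effects)[ur$truth$effects == -0.75]
    log2_ratio(ur$table$intensities[si, acetyl], ur$labels) + 0.75
  }, 0)
  expect_lt(max(abs(devs)), 0.1)
  expect_lt(abs(mean(devs)), 0.05)
})

test_that("acylcarnitine family is constructed exactly", {
  ur <- generate_feature_table(small_config(seed = 12), "urine")
  fam <- ur$truth$acylcarnitine_ids
  meta <- ur$table$features
  idx <- match(fam, meta$feature)
  loss <- meta$mz[idx] - as.numeric(meta$fragments[idx])
  expect_equal(loss, rep(59.0747, length(fam)), tolerance = 1e-10)
  expect_true(all(diff(meta$rt[idx][order(meta$mz[idx])]) > 0))
  expect_true(all(meta$ion_mode[idx] == "pos"))
})

test_that("overall zero rate tracks the configured missing rate", {
  ur <- generate_feature_table(cohort_config(seed = 6, missing_rate = 0.25),
                               "urine")
  si <- which(!ur$table$samples$is_qc)
  expect_equal(mean(ur$table$intensities[si, ] == 0), 0.25, tolerance = 0.03)
})
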