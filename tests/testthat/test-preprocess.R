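test_that("ordinal category merging pools sparse categories into neighbours", {
  y <- rep(1:3, c(20, 3, 16))
  ds <- cat_dataset(cbind(v = y, pad = rep(1:2, c(20, 19))),
                    scaling_spec("ordinal"))
  out <- merge_sparse_categories(ds, min_count = 7L)
  counts <- table(out$dataset$data[, "v"])
  expect_equal(unname(c(counts)), c(23, 16))
  expect_equal(length(counts), 2L)
})

test_that("merging leaves fully supported variables unchanged", {
  y <- rep(1:3, c(10, 9, 20))
  ds <- cat_dataset(cbind(v = y), scaling_spec("ordinal"))
  ds$data <- cbind(ds$data, w = rep(1:2, c(19, 20)))
  ds$specs <- rep(list(scaling_spec("ordinal")), 2)
  out <- merge_sparse_categories(ds, 7L)
  expect_equal(out$dataset$data[, "v"], y, ignore_attr = TRUE)
  expect_equal(nrow(out$log), 0L)
})

test_that("hopelessly sparse variables collapse and are dropped", {
  y <- rep(1:3, c(2, 3, 1))
  ds <- cat_dataset(cbind(v = y), scaling_spec("ordinal"))
  out <- merge_sparse_categories(ds, 7L)
  expect_equal(length(unique(out$dataset$data[, "v"])), 1L)
  # the merge trace records the collapse
  expect_true(all(out$log$variable == "v"))
  dropped <- drop_single_category_variables(out$dataset)
  expect_identical(dropped$removed, "v")
  expect_equal(ncol(dropped$dataset$data), 0L)  # degenerate: nothing left
})

test_that("nominal sparse categories pool into one 'other' category", {
  y <- rep(c(1L, 2L, 3L, 4L), c(15, 12, 4, 5))
  ds <- cat_dataset(cbind(v = y, pad = rep(1:2, 18)),
                    list(scaling_spec("nominal"), scaling_spec("ordinal")))
  out <- merge_sparse_categories(ds, 7L)
  counts <- table(out$dataset$data[, "v"])
  expect_equal(sort(unname(c(counts))), c(9, 12, 15))  # 4+5 pooled
})

test_that("merge then drop reproduces the 57 -> 42 item reduction and is idempotent", {
  co <- generate_cohort(cohort_config(seed = 4))
  ds <- cat_dataset(co$questionnaire$data, scaling_spec("ordinal"))
  m1 <- merge_sparse_categories(ds, 7L)
  d1 <- drop_single_category_variables(m1$dataset)
  expect_equal(ncol(ds$data), 57L)
  expect_equal(length(d1$removed), 15L)
  expect_equal(ncol(d1$dataset$data), 42L)
  # applying the pair again changes nothing
  m2 <- merge_sparse_categories(d1$dataset, 7L)
  d2 <- drop_single_category_variables(m2$dataset)
  expect_identical(d2$dataset$data, d1$dataset$data)
  expect_length(d2$removed, 0L)
})

test_that("uniform binning follows the closed-form edges", {
  expect_equal(bin_clinical(0:18, 19L), 1:19)
  expect_equal(bin_clinical(rep(3.2, 5)), rep(1L, 5))
  # interior edge belongs to the right bin (half-open convention)
  expect_equal(bin_clinical(c(0, 5, 10), 2L), c(1L, 2L, 2L))
  expect_error(bin_clinical(c(1, NA, 3)), "non-finite")
})

test_that("binning preserves within-variable rank order", {
  set.seed(12)
  for (rep in 1:10) {
    v <- rnorm(50)
    b <- bin_clinical(v, 19L)
    expect_true(all(b >= 1L & b <= 19L))
    o <- order(v)
    expect_true(all(diff(b[o]) >= 0L))
  }
})

test_that("presence filter keeps features supported by at least one class", {
  set.seed(5)
  mk <- function(frac_cold, frac_heat, n = 100) {
    c(rbinom(n, 1, frac_cold), rbinom(n, 1, frac_heat)) * runif(2 * n, 1, 2)
  }
  nz_cold <- rep(1, 100); nz_cold[1:10] <- 0          # 90% in Cold
  f1 <- c(nz_cold, rep(0, 90), runif(10))             # 10% in Heat
  f2 <- c(rep(c(1, 1, 1, 1, 0), 20), rep(c(1, 1, 1, 1, 0), 20)) # 80/80
  f3 <- c(rep(c(1, 1, 1, 0, 0), 20), rep(c(1, 1, 1, 0, 0), 20)) # 60/60
  intens <- cbind(keep_onesided = f1, keep_both = f2, drop_both = f3)
  samples <- data.frame(sample = sprintf("s%03d", 1:200),
                        class = rep(c("Cold", "Heat"), each = 100),
                        is_qc = FALSE, injection_order = 1:200)
  features <- data.frame(feature = colnames(intens), mz = 1:3, rt = 1:3,
                         ion_mode = "pos", fragments = NA)
  tab <- feature_table(intens, samples, features)
  out <- filter_presence(tab, 0.8)
  expect_setequal(colnames(out$table$intensities),
                  c("keep_onesided", "keep_both"))
  expect_equal(out$removed, 1L)
  strict <- filter_presence(tab, 0.8, rule = "all-classes")
  expect_identical(colnames(strict$table$intensities), "keep_both")
})

test_that("zero replacement halves the per-feature minimum", {
  intens <- cbind(a = c(0, 4, 6), b = c(1, 2, 3), c = c(0, 0, 10))
  samples <- data.frame(sample = c("s1", "s2", "s3"),
                        class = c("Cold", "Cold", "Heat"),
                        is_qc = FALSE, injection_order = 1:3)
  features <- data.frame(feature = c("a", "b", "c"), mz = 1:3, rt = 1:3,
                         ion_mode = "pos", fragments = NA)
  tab <- feature_table(intens, samples, features)
  out <- replace_zeros(tab)
  expect_equal(unname(out$intensities[, "a"]), c(2, 4, 6))
  expect_equal(unname(out$intensities[, "b"]), c(1, 2, 3))
  expect_equal(unname(out$intensities[, "c"]), c(5, 5, 10))
  expect_true(all(out$intensities > 0))
  allzero <- tab; allzero$intensities[, "a"] <- 0
  expect_error(replace_zeros(allzero), "all-zero")
  glob <- replace_zeros(tab, per_feature = FALSE)
  expect_equal(unname(glob$intensities[1, "a"]), 0.5)  # global min 1 / 2
})

test_that("presence filter plus zero replacement leaves no zeros", {
  co <- generate_cohort(small_config(seed = 30))
  out <- replace_zeros(filter_presence(co$urine$table)$table)
  expect_true(all(out$intensities > 0))
})

test_that("scaling computes parameters on study samples and applies them to QC", {
  co <- generate_cohort(small_config(seed = 31))
  tab <- replace_zeros(filter_presence(co$urine$table)$table)
  si <- which(!tab$samples$is_qc)
  sc <- scale_features(tab, "autoscale")
  expect_equal(unname(colMeans(sc$intensities[si, ])),
               rep(0, ncol(sc$intensities)), tolerance = 1e-12)
  expect_equal(unname(apply(sc$intensities[si, ], 2, sd)),
               rep(1, ncol(sc$intensities)), tolerance = 1e-12)
  # QC row transformed with the study-derived parameters
  qi <- which(tab$samples$is_qc)[1]
  j <- 3L
  mu <- mean(tab$intensities[si, j]); s <- sd(tab$intensities[si, j])
  expect_equal(sc$intensities[qi, j], (tab$intensities[qi, j] - mu) / s)
  # centering is idempotent
  ce1 <- scale_features(tab, "center")
  ce2 <- scale_features(ce1, "center")
  expect_equal(ce1$intensities, ce2$intensities, tolerance = 1e-9)
})

test_that("QC screening detects injection-order drift and planted outliers", {
  co_drift <- generate_feature_table(
    cohort_config(seed = 44, drift_slope = 0.02, n_qc = 10L,
                  missing_rate = 0), "urine")
  tab <- scale_features(co_drift$table, "center")
  scr <- qc_screen(tab)
  expect_lt(scr$trend$p.value, 0.05)

  co_flat <- generate_feature_table(
    cohort_config(seed = 44, drift_slope = 0, n_qc = 10L,
                  missing_rate = 0), "urine")
  scr0 <- qc_screen(scale_features(co_flat$table, "center"))
  expect_gt(scr0$trend$p.value, 0.05)
  expect_lt(scr0$qc_dispersion_ratio, 0.5)

  # one sample shifted +10 SD on 50 features gets flagged
  tab2 <- scale_features(replace_zeros(filter_presence(
    generate_feature_table(small_config(seed = 45), "urine")$table)$table),
    "autoscale")
  tab2$intensities[2, 1:50] <- tab2$intensities[2, 1:50] + 10
  scr2 <- qc_screen(tab2)
  expect_true(tab2$samples$sample[2] %in% scr2$outliers)
})
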