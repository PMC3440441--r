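test_that("a noiseless single-column signal is fit with one component", {
  set.seed(1)
  X <- matrix(rnorm(20 * 5), 20, 5)
  y <- factor(ifelse(X[, 3] > median(X[, 3]), "Heat", "Cold"),
              levels = c("Cold", "Heat"))
  X[, 3] <- ifelse(y == "Heat", 1, -1)
  fit <- fit_pls(X, y, 1)
  expect_equal(fit$n_components, 1L)
  expect_equal(as.character(predict(fit, X, type = "class")),
               as.character(y))
})

test_that("full-rank PLS reproduces least squares", {
  set.seed(4)
  X <- matrix(rnorm(10 * 8), 10, 8)
  y <- ifelse(rnorm(10) > 0, 1, -1)
  fit <- fit_pls(X, y, 8)
  ols <- coef(lm(y ~ X))
  expect_equal(unname(fit$coef[, 8]), unname(ols[-1]), tolerance = 1e-8)
  expect_equal(unname(fit$intercepts[8]), unname(ols[1]), tolerance = 1e-8)
})

test_that("PLS matches an independent implementation on small data", {
  skip_if_not_installed("mixOmics")
  set.seed(6)
  X <- matrix(rnorm(30 * 12), 30, 12,
              dimnames = list(NULL, paste0("f", 1:12)))
  y <- rnorm(30) + X[, 1] - X[, 5]
  fit <- fit_pls(X, sign(y), 3)
  ref <- mixOmics::pls(X, sign(y), ncomp = 3, mode = "regression",
                       scale = FALSE)
  ours <- predict(fit, X, ncomp = 3)
  theirs <- predict(ref, X)$predict[, 1, 3]
  expect_equal(unname(drop(ours)), unname(theirs), tolerance = 1e-6)
})

test_that("duplicating a feature splits its weight but keeps predictions", {
  set.seed(8)
  X <- matrix(rnorm(24 * 6), 24, 6)
  colnames(X) <- paste0("f", 1:6)
  y <- factor(rep(c("Cold", "Heat"), 12))
  f1 <- fit_pls(X, y, 2)
  Xd <- cbind(X, f1dup = X[, 1])
  f2 <- fit_pls(Xd, y, 2)
  # the two copies share the weight symmetrically at any component count
  expect_equal(unname(f2$coef["f1", 2]), unname(f2$coef["f1dup", 2]),
               tolerance = 1e-10)
  # at full rank both models reproduce the least-squares fit, so the copies
  # halve the original coefficient and predictions coincide
  f1f <- fit_pls(X, y, 6)
  f2f <- fit_pls(Xd, y, 7)
  expect_equal(f2f$n_components, 6L)        # the duplicate adds no rank
  a <- f2f$n_components
  expect_equal(unname(2 * f2f$coef["f1", a]), unname(f1f$coef["f1", 6]),
               tolerance = 1e-6)
  expect_equal(unname(predict(f2f, Xd, ncomp = a)),
               unname(predict(f1f, X, ncomp = 6)), tolerance = 1e-6)
})

test_that("component count past the data rank is rejected", {
  X <- matrix(rnorm(12), 4, 3)
  expect_error(fit_pls(X, c(-1, 1, -1, 1), 4), "n_components")
})

test_that("double CV picks one component on rank-1 class structure", {
  set.seed(3)
  y <- factor(rep(c("Cold", "Heat"), each = 10))
  signal <- ifelse(y == "Heat", 1, -1)
  X <- outer(signal, rnorm(15)) + matrix(rnorm(20 * 15, sd = 0.01), 20, 15)
  cv <- double_cv(X, y, a_max = 4, seed = 2)
  expect_equal(cv$error, 0)
  expect_true(all(cv$chosen_a == 1L))
})

test_that("double CV is deterministic given the seed", {
  co <- generate_cohort(small_config(seed = 19))
  pc <- prep_compartment(co$urine)
  c1 <- double_cv(pc$X, pc$y, a_max = 3, scale_mode = "center", seed = 5)
  c2 <- double_cv(pc$X, pc$y, a_max = 3, scale_mode = "center", seed = 5)
  expect_identical(c1$error, c2$error)
  expect_identical(c1$folds, c2$folds)
})

test_that("jack-knife trace is nonincreasing in size and picks the minimum", {
  co <- generate_cohort(small_config(seed = 23))
  pc <- prep_compartment(co$urine)
  jk <- jackknife_select(pc$X, pc$y, a_max = 3, scale_mode = "autoscale",
                         seed = 4)
  expect_true(all(diff(jk$trace$n_retained) <= 0))
  expect_equal(jk$trace$error[jk$chosen], min(jk$trace$error))
  expect_equal(jk$chosen, which.min(jk$trace$error))  # first minimum
  expect_true(all(jk$selected %in% colnames(pc$X)))
  # threshold above the maximum SE removes nothing
  jk2 <- jackknife_select(pc$X, pc$y, threshold_schedule = max(jk$se) * 2,
                          a_max = 3, scale_mode = "autoscale", seed = 4)
  expect_equal(jk2$trace$n_retained, ncol(pc$X))
})

test_that("permutation p-value carries the add-one correction", {
  co <- generate_cohort(small_config(seed = 29))
  pc <- prep_compartment(co$urine)
  pt <- permutation_test_plsda(pc$X, pc$y, n_permutations = 19,
                               a_max = 3, scale_mode = "autoscale", seed = 3)
  expect_equal(pt$p_value,
               (1 + sum(pt$null <= pt$observed)) / 20)
  if (all(pt$null > pt$observed)) expect_equal(pt$p_value, 1 / 20)
  expect_true(pt$p_value > 0 && pt$p_value <= 1)
})

test_that("feature ranking orders by |coefficient| and annotates ratios", {
  co <- generate_cohort(small_config(seed = 31))
  pc <- prep_compartment(co$urine)
  Xs <- scale(pc$X)
  fit <- fit_pls(Xs, pc$y, 2)
  rk <- rank_features(fit, pc$table, k = 30)
  expect_equal(rk$importance, 1:30)
  b <- abs(fit$coef[, fit$n_components])
  expect_equal(rk$feature[1], names(which.max(b)))
  expect_true(all(diff(abs(rk$coefficient)) <= 1e-12))
  # informative features rank better than noise on average
  inf <- intersect(co$truth$urine$informative_feature_ids, colnames(pc$X))
  allrk <- rank_features(fit, pc$table, k = ncol(pc$X))
  pos <- match(inf, allrk$feature)
  expect_lt(mean(pos), mean(seq_len(ncol(pc$X))))
})
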