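test_that("numeric analysis level reproduces classical PCA", {
  set.seed(20)
  codes <- apply(matrix(rnorm(20 * 10), 20, 10), 2, rank)
  fit <- fit_nlpca(cat_dataset(codes, scaling_spec("numeric")),
                   tol = 1e-12, seed = 2)
  ev <- eigen(cor(codes), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(fit$total_vaf, ev[1] / ncol(codes), tolerance = 1e-8)
})

test_that("total VAF is nondecreasing over ALS iterations at every level", {
  set.seed(8)
  co <- generate_cohort(small_config(seed = 8))
  bins <- apply(co$clinical$data, 2, bin_clinical)
  for (lvl in list(scaling_spec("nominal"), scaling_spec("ordinal"),
                   scaling_spec("spline-nominal", 2, 1),
                   scaling_spec("spline-ordinal", 2, 1))) {
    fit <- fit_nlpca(cat_dataset(bins, lvl), seed = 4)
    expect_true(all(diff(fit$vaf_history) >= -1e-9))
  }
})

test_that("quantifications stay normalised: mean 0, sum of squares n", {
  set.seed(15)
  co <- generate_cohort(small_config(seed = 15))
  ds <- prep_questionnaire(co)
  fit <- fit_nlpca(ds, seed = 3)
  n <- nrow(ds$data)
  for (j in seq_along(fit$quantifications)) {
    tab <- fit$quantifications[[j]]
    q <- tab$quantification[match(ds$data[, j],
                                  tab$category)]
    expect_equal(mean(q), 0, tolerance = 1e-8)
    expect_equal(sum(q^2), n, tolerance = 1e-6)
  }
  expect_equal(unname(fit$vaf), unname(fit$loadings[, 1]^2), tolerance = 1e-12)
})

test_that("two identical variables obtain equal loadings and VAF", {
  set.seed(9)
  v <- sample(1:4, 30, replace = TRUE)
  other <- matrix(sample(1:5, 30 * 3, replace = TRUE), 30, 3)
  codes <- cbind(a = v, b = v, other)
  fit <- fit_nlpca(cat_dataset(codes, scaling_spec("ordinal")),
                   tol = 1e-10, seed = 1)
  expect_equal(fit$loadings["a", 1], fit$loadings["b", 1], tolerance = 1e-5)
  expect_equal(fit$vaf[["a"]], fit$vaf[["b"]], tolerance = 1e-5)
})

test_that("ordinal equals nominal when unconstrained quantifications are monotone", {
  # a variable perfectly aligned with a strong gradient has monotone
  # category means, so PAVA is a no-op
  set.seed(33)
  grad <- rep(1:6, each = 6)
  noisy <- pmin(6, pmax(1, grad + sample(c(-1, 0, 1), 36, TRUE)))
  codes <- cbind(g = grad, h = noisy)
  f_nom <- fit_nlpca(cat_dataset(codes, scaling_spec("nominal")),
                     tol = 1e-12, seed = 2)
  f_ord <- fit_nlpca(cat_dataset(codes, scaling_spec("ordinal")),
                     tol = 1e-12, seed = 2)
  qn <- f_nom$quantifications$g$quantification
  expect_true(all(diff(qn) >= -1e-8) || all(diff(qn) <= 1e-8))
  expect_equal(f_ord$total_vaf, f_nom$total_vaf, tolerance = 1e-6)
})

test_that("forced classification separates classes and pins the sign", {
  co <- generate_cohort(small_config(seed = 21))
  ds <- prep_questionnaire(co)
  fit <- forced_classification_fit(ds, co$labels, seed = 5)
  x <- drop(fit$object_scores)
  expect_true(fit$separated)
  expect_gt(min(x[co$labels == "Heat"]), max(x[co$labels == "Cold"]))
  expect_gt(mean(x[co$labels == "Heat"]), 0)
})

test_that("class variable dominates pure-noise predictors", {
  set.seed(2)
  noise <- matrix(sample(1:4, 24 * 6, replace = TRUE), 24, 6)
  y <- factor(rep(c("Cold", "Heat"), each = 12))
  fit <- forced_classification_fit(cat_dataset(noise, scaling_spec("nominal")),
                                   y, seed = 1)
  expect_true(fit$separated)
  expect_true(all(fit$vaf[setdiff(names(fit$vaf), ".class")] < 0.5))
  expect_gt(fit$vaf[[".class"]], 0.99)
})

test_that("flipping the class coding flips only the loading signs", {
  co <- generate_cohort(small_config(seed = 6))
  ds <- prep_questionnaire(co)
  f1 <- forced_classification_fit(ds, co$labels, seed = 9)
  flipped <- factor(ifelse(co$labels == "Cold", "Heat", "Cold"),
                    levels = c("Cold", "Heat"))
  f2 <- forced_classification_fit(ds, flipped, seed = 9)
  subst <- setdiff(f1$var_names, ".class")
  expect_equal(unname(f1$loadings[subst, 1]), -unname(f2$loadings[subst, 1]),
               tolerance = 1e-4)
  # the class indicator itself stays aligned with the component (+1) under
  # the Heat-positive sign convention
  expect_gt(f2$loadings[".class", 1], 0.99)
  expect_equal(f1$vaf, f2$vaf, tolerance = 1e-6)
})

test_that("training subjects are re-predicted into their own class", {
  co <- generate_cohort(small_config(seed = 13))
  ds <- prep_questionnaire(co)
  fit <- forced_classification_fit(ds, co$labels, seed = 2)
  expect_true(fit$separated)
  p <- predict_class(fit, ds$data)
  expect_equal(as.character(p$label), as.character(co$labels))
})

test_that("prediction handles unseen categories and refuses sparse subjects", {
  co <- generate_cohort(small_config(seed = 17))
  ds <- prep_questionnaire(co)
  fit <- forced_classification_fit(ds, co$labels, seed = 2)
  new <- ds$data[1:2, , drop = FALSE]
  new[1, 1] <- max(ds$data[, 1]) + 5L   # unseen high code: extrapolation
  expect_no_error(p <- predict_class(fit, new))
  expect_false(anyNA(p$score))
  mostly_na <- ds$data[1, , drop = FALSE]
  mostly_na[1, seq_len(ceiling(ncol(ds$data) * 0.7))] <- NA
  p2 <- predict_class(fit, mostly_na)
  expect_true(is.na(p2$label))
})

test_that("a midway score ties toward Cold", {
  model <- structure(list(
    var_names = c("v1", ".class"), class_var = ".class",
    labels = factor(c("Cold", "Heat")),
    weights = c(1, 1000), loadings = matrix(c(1, 1), 2,
                                            dimnames = list(c("v1", ".class"))),
    specs = list(v1 = scaling_spec("ordinal"),
                 .class = scaling_spec("nominal")),
    quantifications = list(
      v1 = data.frame(category = 1:2, quantification = c(0, 0), count = c(1, 1)),
      .class = data.frame(category = 1:2, quantification = c(-1, 1),
                          count = c(1, 1))),
    class_centroids = c(Cold = -1, Heat = 1)), class = "nlpca")
  p <- predict_class(model, matrix(1L, 1, 1, dimnames = list(NULL, "v1")))
  expect_equal(p$score, 0)
  expect_equal(as.character(p$label), "Cold")
})

test_that("prediction error falls as planted effects grow", {
  err_at <- function(effect) {
    errs <- vapply(1:3, function(s) {
      co <- generate_cohort(small_config(seed = 40 + s,
                                         item_effect = effect))
      ds <- prep_questionnaire(co)
      leave_two_out_cv(ds, co$labels, seed = s)$error
    }, 0)
    mean(errs)
  }
  expect_lte(err_at(3), err_at(0.3))
})
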