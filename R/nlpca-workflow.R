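#' Compare analysis levels by total VAF
#'
#' Fits a forced-classification model under each candidate set of scaling
#' specifications (e.g. numeric vs spline-ordinal vs spline-nominal for the
#' clinical variables) and tabulates the total VAF. Because the feasible
#' sets are nested, a substantial VAF gain for a freer level indicates a
#' nonmonotone relationship. For each consecutive pair of sets the variable
#' contributing the largest per-variable VAF gain is flagged.
#'
#' @param dataset a [cat_dataset()] of predictors.
#' @param labels two-level factor of subject classes.
#' @param level_sets named list; each element is itself a named list mapping
#'   variable names to a [scaling_spec()] override (variables not named keep
#'   the dataset's spec).
#' @param class_weight forced-classification weight.
#' @param seed passed to each fit.
#' @return list with `summary` (data.frame set/total_vaf), `vaf` (variables
#'   x sets matrix of per-variable VAF), `top_gain` (data.frame comparing
#'   consecutive sets), `models` (the fits).
#' @export
compare_analysis_levels <- function(dataset, labels, level_sets,
                                    class_weight = 1000, seed = NULL) {
  stopifnot(is.list(level_sets), length(level_sets) >= 1L)
  if (is.null(names(level_sets)))
    names(level_sets) <- paste0("set", seq_along(level_sets))
  models <- lapply(level_sets, function(ovr) {
    ds <- dataset
    for (v in names(ovr)) ds <- set_specs(ds, v, ovr[[v]])
    forced_classification_fit(ds, labels, class_weight = class_weight,
                              seed = seed)
  })
  vaf <- vapply(models, function(m) m$vaf[setdiff(m$var_names, ".class")],
                numeric(ncol(dataset$data)))
  rownames(vaf) <- setdiff(models[[1L]]$var_names, ".class")
  summary <- data.frame(set = names(level_sets),
                        total_vaf = vapply(models, `[[`, 0, "total_vaf"))
  top_gain <- NULL
  if (length(models) > 1L) {
    top_gain <- do.call(rbind, lapply(seq_len(length(models) - 1L), function(i) {
      delta <- vaf[, i + 1L] - vaf[, i]
      k <- which.max(delta)
      data.frame(from = names(level_sets)[i], to = names(level_sets)[i + 1L],
                 variable = rownames(vaf)[k], delta = delta[k])
    }))
  }
  list(summary = summary, vaf = vaf, top_gain = top_gain, models = models)
}

#' Select variables by per-variable VAF
#'
#' Retains variables whose VAF (squared loading on the forced component) is
#' strictly greater than the threshold; the class indicator is always
#' retained by the fitting routine and is not part of the returned
#' predictor list.
#'
#' @param model an `nlpca` fit.
#' @param vaf_threshold strict lower bound (default 0.20).
#' @return data.frame `variable`, `loading`, `vaf`, ordered by decreasing
#'   absolute loading.
#' @export
select_variables <- function(model, vaf_threshold = 0.20) {
  stopifnot(inherits(model, "nlpca"))
  vars <- setdiff(model$var_names, model$class_var)
  loading <- model$loadings[vars, 1L]
  vaf <- loading^2
  keep <- vaf > vaf_threshold
  if (!any(keep))
    stop("no variable exceeds the VAF threshold; consider lowering it")
  out <- data.frame(variable = vars[keep], loading = loading[keep],
                    vaf = vaf[keep], row.names = NULL)
  out[order(-abs(out$loading)), , drop = FALSE]
}

# stratified leave-two-out folds: one subject of each class per pair where
# possible; the larger class's leftovers are paired among themselves; an odd
# leftover forms a final singleton fold
lto_folds <- function(labels, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  i1 <- sample(which(labels == levels(labels)[1L]))
  i2 <- sample(which(labels == levels(labels)[2L]))
  k <- min(length(i1), length(i2))
  folds <- mapply(function(a, b) c(a, b), i1[seq_len(k)], i2[seq_len(k)],
                  SIMPLIFY = FALSE)
  rest <- c(i1[-seq_len(k)], i2[-seq_len(k)])
  while (length(rest) >= 2L) {
    folds[[length(folds) + 1L]] <- rest[1:2]
    rest <- rest[-(1:2)]
  }
  if (length(rest)) folds[[length(folds) + 1L]] <- rest
  folds
}

#' Leave-two-out cross-validation of the forced-classification model
#'
#' Subjects are partitioned into stratified pairs (one per class where
#' possible; odd leftovers form a final fold). For each fold the model is
#' refit on the remaining subjects and the held-out pair's classes are
#' predicted; the overall error is the misclassified fraction. Variables
#' that collapse to a single category inside a training fold are dropped
#' for that fold.
#'
#' @param dataset a [cat_dataset()] of predictors.
#' @param labels two-level factor.
#' @param class_weight forced-classification weight.
#' @param seed controls fold assignment and fit initialisation.
#' @param ... passed to [forced_classification_fit()].
#' @return list of class `cv_result`: `error`, `predictions` (data.frame),
#'   `folds`.
#' @export
leave_two_out_cv <- function(dataset, labels, class_weight = 1000,
                             seed = NULL, ...) {
  labels <- as.factor(labels)
  n <- nrow(dataset$data)
  stopifnot(n >= 4L, length(labels) == n)
  folds <- lto_folds(labels, seed)
  pred <- factor(rep(NA_character_, n), levels = levels(labels))
  score <- rep(NA_real_, n)
  for (f in folds) {
    tr <- setdiff(seq_len(n), f)
    ds_tr <- subset_rows(dataset, tr)
    ncat <- apply(ds_tr$data, 2L, function(y) length(unique(y[!is.na(y)])))
    if (any(ncat <= 1L)) {
      keep <- ncat > 1L
      ds_tr$data <- ds_tr$data[, keep, drop = FALSE]
      ds_tr$specs <- ds_tr$specs[keep]
    }
    m <- forced_classification_fit(ds_tr, labels[tr],
                                   class_weight = class_weight,
                                   seed = seed, ...)
    p <- predict_class(m, dataset$data[f, , drop = FALSE])
    pred[f] <- p$label
    score[f] <- p$score
  }
  err <- mean(pred != labels, na.rm = FALSE)
  structure(list(error = err,
                 predictions = data.frame(subject = rownames(dataset$data),
                                          truth = labels, predicted = pred,
                                          score = score),
                 folds = folds),
            class = "cv_result")
}

#' Full questionnaire/clinical protocol
#'
#' The published analysis sequence: fit the forced-classification model on
#' all subjects, select variables with VAF above the threshold, refit on the
#' selected variables, and estimate the classification error by stratified
#' leave-two-out cross-validation. Selection is performed once on the full
#' data before CV (the protocol the study describes; optimistically biased).
#' Set `select_in_cv = TRUE` to redo selection inside every training fold
#' instead.
#'
#' @param dataset a [cat_dataset()] of predictors.
#' @param labels two-level factor.
#' @param vaf_threshold strict VAF selection threshold.
#' @param class_weight forced-classification weight.
#' @param seed seed for fits and fold assignment.
#' @param on_empty what to do when no variable passes the threshold: keep
#'   all variables (`"all"`, default) or raise an error (`"error"`).
#' @param select_in_cv logical; selection inside each CV training fold.
#' @return list with `model` (final refit), `selected` (selection table or
#'   NULL when selection fell back to all variables), `cv` (a `cv_result`).
#' @export
nlpca_protocol <- function(dataset, labels, vaf_threshold = 0.20,
                           class_weight = 1000, seed = NULL,
                           on_empty = c("all", "error"),
                           select_in_cv = FALSE) {
  on_empty <- match.arg(on_empty)
  full <- forced_classification_fit(dataset, labels,
                                    class_weight = class_weight, seed = seed)
  sel <- tryCatch(select_variables(full, vaf_threshold),
                  error = function(e) if (on_empty == "all") NULL else stop(e))
  ds_sel <- if (is.null(sel)) dataset
            else {
              keep <- match(sel$variable, colnames(dataset$data))
              structure(list(data = dataset$data[, keep, drop = FALSE],
                             specs = dataset$specs[keep]),
                        class = "cat_dataset")
            }
  if (select_in_cv) {
    # selection redone inside each fold: wrap CV manually
    n <- nrow(dataset$data)
    folds <- lto_folds(labels, seed)
    pred <- factor(rep(NA_character_, n), levels = levels(labels))
    for (f in folds) {
      tr <- setdiff(seq_len(n), f)
      sub <- subset_rows(dataset, tr)
      ncat <- apply(sub$data, 2L, function(y) length(unique(y)))
      sub$data <- sub$data[, ncat > 1L, drop = FALSE]
      sub$specs <- sub$specs[ncat > 1L]
      m0 <- forced_classification_fit(sub, labels[tr],
                                      class_weight = class_weight, seed = seed)
      s0 <- tryCatch(select_variables(m0, vaf_threshold),
                     error = function(e) NULL)
      ds0 <- if (is.null(s0)) sub else {
        k0 <- match(s0$variable, colnames(sub$data))
        structure(list(data = sub$data[, k0, drop = FALSE],
                       specs = sub$specs[k0]), class = "cat_dataset")
      }
      m1 <- forced_classification_fit(ds0, labels[tr],
                                      class_weight = class_weight, seed = seed)
      pred[f] <- predict_class(m1, dataset$data[f, , drop = FALSE])$label
    }
    cv <- structure(list(error = mean(pred != labels),
                         predictions = data.frame(truth = labels,
                                                  predicted = pred),
                         folds = folds), class = "cv_result")
  } else {
    cv <- leave_two_out_cv(ds_sel, labels, class_weight = class_weight,
                           seed = seed)
  }
  model <- forced_classification_fit(ds_sel, labels,
                                     class_weight = class_weight, seed = seed)
  list(model = model, selected = sel, cv = cv)
}

#' Permutation test of the questionnaire/clinical protocol
#'
#' Permutes the class labels (preserving class sizes), re-runs the full
#' protocol (fit, variable selection, cross-validation) per permutation, and
#' compares the observed CV error with the null distribution. The p-value
#' uses the add-one correction \eqn{p = (1 + \#\{null \le obs\}) / (B + 1)}.
#' Labels are permuted before selection, so the null accounts for the
#' selection step.
#'
#' @param dataset a [cat_dataset()] of predictors.
#' @param labels two-level factor.
#' @param n_permutations number of label permutations (the published
#'   analyses used 250; fewer than 19 floors p above 0.05, which triggers a
#'   warning).
#' @param seed master seed (permutation draws and all fits).
#' @param ... passed to [nlpca_protocol()].
#' @return list of class `permutation_result`: `observed`, `null`,
#'   `p_value`, `n_permutations`.
#' @export
permutation_test_nlpca <- function(dataset, labels, n_permutations = 100L,
                                   seed = 1L, ...) {
  labels <- as.factor(labels)
  if (n_permutations < 19L)
    warning("fewer than 19 permutations: p-value floor exceeds 0.05")
  obs <- nlpca_protocol(dataset, labels, seed = seed, ...)$cv$error
  null <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    set.seed(child_seed(seed, 100L + b))
    perm <- sample(labels)
    null[b] <- nlpca_protocol(dataset, perm, seed = child_seed(seed, b),
                              ...)$cv$error
  }
  p <- (1 + sum(null <= obs)) / (n_permutations + 1)
  structure(list(observed = obs, null = null, p_value = p,
                 n_permutations = n_permutations),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test: observed %.3f, null median %.3f, p = %.4f (%d permutations)\n",
              x$observed, stats::median(x$null), x$p_value, x$n_permutations))
  invisible(x)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cross-validation: error %.3f over %d folds\n",
              x$error, length(x$folds)))
  invisible(x)
}
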