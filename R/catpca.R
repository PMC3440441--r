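#' Nonlinear principal component analysis with optimal scaling
#'
#' Fits a categorical PCA by alternating least squares over object scores,
#' category quantifications and loadings. Each variable's quantification is
#' constrained by its analysis level: free (nominal), monotone (ordinal, via
#' weighted pool-adjacent-violators), smooth (spline-nominal), smooth and
#' monotone (spline-ordinal, nonnegative coefficients on a cumulated
#' B-spline basis), or linear (numeric). The solution maximises the variance
#' of the transformed variables accounted for by the components (VAF).
#'
#' The loss minimised is \eqn{\sum_j w_j \|X - q_j a_j^\top\|^2} over
#' centered, orthonormal object scores \eqn{X} (\eqn{X^\top X = n I}),
#' normalised quantified variables \eqn{q_j} (mean 0, sum of squares
#' \eqn{n}) and loadings \eqn{a_j}; per-variable VAF is \eqn{\|a_j\|^2} and
#' total VAF the \eqn{w_j}-weighted mean. The loss decreases (VAF
#' increases) monotonically across iterations.
#'
#' @param dataset a [cat_dataset()].
#' @param ndim number of components (the forced-classification analyses use
#'   1).
#' @param maxit maximum ALS iterations.
#' @param tol convergence tolerance on the total-VAF gain per iteration.
#' @param seed optional integer seed for the random initialisation of the
#'   object scores.
#' @return object of class `nlpca`: `object_scores` (n x ndim),
#'   `loadings` (J x ndim), `vaf` (per variable), `total_vaf`,
#'   `quantifications` (per variable, data.frame of observed category code
#'   and its scaled quantification), `vaf_history`, `iterations`,
#'   `converged`, plus the specs and weights used.
#' @export
fit_nlpca <- function(dataset, ndim = 1L, maxit = 500L, tol = 1e-8,
                      seed = NULL) {
  stopifnot(inherits(dataset, "cat_dataset"))
  dat <- dataset$data
  n <- nrow(dat); J <- ncol(dat)
  if (J < 2L) stop("need at least 2 variables")
  if (n < 3L) stop("need at least 3 subjects")
  specs <- dataset$specs
  w <- vapply(specs, `[[`, 0, "weight")

  # per-variable index structures on observed categories
  vinfo <- vector("list", J)
  for (j in seq_len(J)) {
    codes <- dat[, j]
    obs <- sort(unique(codes[!is.na(codes)]))
    if (length(obs) < 2L)
      stop(sprintf("variable '%s' has a single observed category; remove it first",
                   colnames(dat)[j]))
    idx <- match(codes, obs)
    d <- tabulate(idx, nbins = length(obs))
    sp <- specs[[j]]
    sb <- NULL
    if (sp$level %in% c("spline-nominal", "spline-ordinal")) {
      sb <- spline_basis(as.numeric(obs), degree = sp$degree,
                         interior_knots = sp$knots,
                         monotone = sp$level == "spline-ordinal",
                         weights = d)
    }
    vinfo[[j]] <- list(obs = obs, idx = idx, d = d, sb = sb,
                       level = sp$level)
  }

  # initial object scores: seeded random normal, centered, orthonormalised
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(stats::rnorm(n * ndim), n, ndim)
  X <- scale(X, center = TRUE, scale = FALSE)
  X <- qr.Q(qr(X)) * sqrt(n)

  # initial quantifications: standardized observed codes (numeric start)
  Q <- matrix(0, n, J)
  A <- matrix(0, J, ndim)
  for (j in seq_len(J)) {
    q <- as.numeric(vinfo[[j]]$obs)[vinfo[[j]]$idx]
    q <- q - mean(q)
    ss <- sum(q^2)
    Q[, j] <- if (ss > 1e-12) q * sqrt(n / ss) else 0
    A[j, ] <- crossprod(X, Q[, j]) / n
  }

  wss <- function(r, d) sum(d * r^2)
  vaf_hist <- numeric(0)
  vaf_total <- sum(w * rowSums(A^2)) / sum(w)
  converged <- FALSE
  iter <- 0L
  while (iter < maxit) {
    iter <- iter + 1L
    for (j in seq_len(J)) {
      vi <- vinfo[[j]]
      if (vi$level == "numeric") {        # q_j fixed; only the loading moves
        A[j, ] <- crossprod(X, Q[, j]) / n
        next
      }
      aj <- A[j, ]
      t_target <- drop(X %*% aj)
      if (sum(aj^2) < 1e-12) {
        # restart a dead variable from its own standardized codes
        t_target <- Q[, j]
        if (all(t_target == 0))
          t_target <- as.numeric(vi$obs)[vi$idx] - mean(as.numeric(vi$obs)[vi$idx])
      }
      m <- drop(rowsum(t_target, vi$idx, reorder = TRUE)) / vi$d
      v <- switch(vi$level,
        "nominal" = m,
        "ordinal" = {
          up <- monotone_regression(m, vi$d)
          dn <- -monotone_regression(-m, vi$d)
          if (wss(m - dn, vi$d) < wss(m - up, vi$d)) -dn else up
          # note: when the decreasing fit wins we store its mirror (an
          # increasing vector); the loading sign recomputed below flips to
          # compensate, keeping quantifications nondecreasing.
        },
        "spline-nominal" = spline_project(m, vi$d, vi$sb),
        "spline-ordinal" = {
          up <- spline_project(m, vi$d, vi$sb)
          dn <- spline_project(-m, vi$d, vi$sb)
          if (wss(m + dn, vi$d) < wss(m - up, vi$d)) dn else up
        })
      q <- v[vi$idx]
      q <- q - mean(q)
      ss <- sum(q^2)
      if (ss < 1e-12) { Q[, j] <- 0; A[j, ] <- 0; next }
      Q[, j] <- q * sqrt(n / ss)
      A[j, ] <- crossprod(X, Q[, j]) / n
    }
    # object-score update: weighted sum of fitted variables, re-orthonormalised
    Z <- Q %*% (w * A)
    Z <- scale(Z, center = TRUE, scale = FALSE)
    if (ndim == 1L) {
      nz <- sqrt(sum(Z^2))
      if (nz < 1e-300) stop("degenerate solution: all loadings vanished")
      X <- Z * (sqrt(n) / nz)
    } else {
      sv <- svd(Z)
      X <- sv$u %*% t(sv$v) * sqrt(n)
    }
    for (j in seq_len(J)) A[j, ] <- crossprod(X, Q[, j]) / n

    vaf_new <- sum(w * rowSums(A^2)) / sum(w)
    vaf_hist <- c(vaf_hist, vaf_new)
    if (vaf_new < vaf_total - 1e-9)
      warning(sprintf("total VAF decreased at iteration %d (%.3e -> %.3e)",
                      iter, vaf_total, vaf_new))
    if (vaf_new - vaf_total < tol) { vaf_total <- vaf_new; converged <- TRUE; break }
    vaf_total <- vaf_new
  }

  quant <- vector("list", J)
  for (j in seq_len(J)) {
    vi <- vinfo[[j]]
    # scaled quantification per observed category, consistent with Q[, j]
    vq <- drop(rowsum(Q[, j], vi$idx, reorder = TRUE)) / vi$d
    quant[[j]] <- data.frame(category = vi$obs, quantification = vq,
                             count = vi$d)
  }
  names(quant) <- colnames(dat)
  dimnames(A) <- list(colnames(dat), paste0("D", seq_len(ndim)))
  structure(list(
    object_scores = X, loadings = A, vaf = rowSums(A^2),
    total_vaf = vaf_total, quantifications = quant,
    vaf_history = vaf_hist, iterations = iter, converged = converged,
    weights = w, specs = specs, n = n,
    var_names = colnames(dat)), class = "nlpca")
}

#' @export
print.nlpca <- function(x, ...) {
  cat(sprintf("nlpca: %d subjects, %d variables, %d component(s)\n",
              x$n, length(x$vaf), ncol(x$loadings)))
  cat(sprintf("total VAF %.4f after %d iterations (converged: %s)\n",
              x$total_vaf, x$iterations, x$converged))
  invisible(x)
}

#' Forced-classification NLPCA fit
#'
#' Appends the binary class indicator as an extra (nominal) variable with a
#' very large weight and fits a one-component optimal-scaling PCA, so the
#' component is forced to align with the class split and objects cluster
#' into per-class subclouds. The weight is escalated (doubled, up to a cap)
#' until the two classes' object-score intervals separate completely; the
#' sign is fixed so the second factor level (Heat by convention) has
#' positive scores.
#'
#' @param dataset a [cat_dataset()] of predictor variables (the class must
#'   not be among them).
#' @param labels factor with two levels, one value per subject. The first
#'   level plays the "Cold" role (negative scores), the second "Heat"
#'   (positive).
#' @param class_weight starting weight for the class variable.
#' @param weight_cap maximum weight tried during escalation.
#' @param ... passed to [fit_nlpca()] (`maxit`, `tol`, `seed`).
#' @return an `nlpca` object with extra fields: `class_var` (name),
#'   `labels`, `separated`, `class_weight_used`, `class_centroids`
#'   (per-class component value of the class quantification).
#' @export
forced_classification_fit <- function(dataset, labels, class_weight = 1000,
                                      weight_cap = 64000, ...) {
  stopifnot(inherits(dataset, "cat_dataset"))
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
  if (length(labels) != nrow(dataset$data)) stop("one label per subject")
  cls <- as.integer(labels)

  wgt <- class_weight
  repeat {
    aug <- cbind(dataset$data, .class = cls)
    specs <- c(dataset$specs, list(.class = scaling_spec("nominal", weight = wgt)))
    ds <- structure(list(data = aug, specs = specs), class = "cat_dataset")
    fit <- fit_nlpca(ds, ndim = 1L, ...)
    x <- drop(fit$object_scores)
    r1 <- range(x[cls == 1L]); r2 <- range(x[cls == 2L])
    separated <- r1[2] < r2[1] || r2[2] < r1[1]
    if (separated || wgt >= weight_cap) break
    wgt <- wgt * 2
  }
  # sign convention: second level (Heat) positive
  if (mean(x[cls == 2L]) < 0) {
    fit$object_scores <- -fit$object_scores
    fit$loadings <- -fit$loadings
  }
  qc <- fit$quantifications$.class
  a_cls <- fit$loadings[".class", 1L]
  centroids <- stats::setNames(a_cls * qc$quantification[match(1:2, qc$category)],
                               levels(labels))
  fit$class_var <- ".class"
  # the headline "total VAF" of a forced-classification analysis summarises
  # the substantive variables: unweighted mean VAF excluding the class
  # indicator (whose VAF is ~1 by construction)
  fit$total_vaf_substantive <-
    mean(fit$vaf[setdiff(fit$var_names, ".class")])
  fit$labels <- labels
  fit$separated <- separated
  fit$class_weight_used <- wgt
  fit$class_centroids <- centroids
  if (!separated)
    warning("complete class separation not achieved at the weight cap")
  fit
}

#' Predict class for new subjects from a forced-classification model
#'
#' Each new subject's variables are transformed with the trained category
#' quantifications (unseen categories: linear interpolation over neighbouring
#' observed categories for ordered levels, the modal category's
#' quantification for nominal), the object score is estimated by weighted
#' least squares over the non-class variables,
#' \eqn{\hat x = \sum_j w_j a_j q_j / \sum_j w_j a_j^2}, and the predicted
#' label is the class whose trained class-quantification is nearer on the
#' forced component (ties go to the first level, Cold).
#'
#' @param model an `nlpca` fit from [forced_classification_fit()].
#' @param newdata integer matrix/data.frame with the model's predictor
#'   columns.
#' @param max_missing maximum tolerated fraction of missing variables per
#'   subject before prediction is refused (`NA` returned).
#' @return list with `label` (factor) and `score` (numeric component score).
#' @export
predict_class <- function(model, newdata, max_missing = 0.5) {
  stopifnot(inherits(model, "nlpca"), !is.null(model$class_var))
  newdata <- as.matrix(newdata)
  vars <- setdiff(model$var_names, model$class_var)
  if (!all(vars %in% colnames(newdata)))
    stop("newdata lacks model variables: ",
         paste(setdiff(vars, colnames(newdata)), collapse = ", "))
  jw <- match(vars, model$var_names)
  w <- model$weights[jw]
  a <- model$loadings[jw, 1L]
  lv <- vapply(model$specs[jw], `[[`, "", "level")

  scores <- apply(newdata[, vars, drop = FALSE], 1L, function(row) {
    qv <- numeric(length(vars)); ok <- logical(length(vars))
    for (k in seq_along(vars)) {
      code <- row[k]
      if (is.na(code)) next
      tab <- model$quantifications[[vars[k]]]
      hit <- match(code, tab$category)
      if (!is.na(hit)) {
        qv[k] <- tab$quantification[hit]
      } else if (lv[k] == "nominal") {
        # unseen nominal code: use the modal training category's value
        qv[k] <- tab$quantification[which.max(tab$count)]
      } else {
        qv[k] <- stats::approx(tab$category, tab$quantification, xout = code,
                               rule = 2)$y
      }
      ok[k] <- TRUE
    }
    if (mean(!ok) > max_missing) return(NA_real_)
    denom <- sum(w[ok] * a[ok]^2)
    if (denom < 1e-12) return(NA_real_)
    sum(w[ok] * a[ok] * qv[ok]) / denom
  })

  cen <- model$class_centroids
  lab <- ifelse(is.na(scores), NA_integer_,
                ifelse(abs(scores - cen[1L]) <= abs(scores - cen[2L]), 1L, 2L))
  list(label = factor(levels(model$labels)[lab], levels = levels(model$labels)),
       score = scores)
}
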