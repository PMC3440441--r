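#' Partial least squares for a binary response
#'
#' Deterministic single-response PLS (NIPALS with X deflation). The class
#' is coded -1 (first level, Cold) / +1 (second level, Heat); prediction is
#' the sign of the fitted response, with 0 assigned to the first level.
#'
#' @param X numeric samples x features matrix, already scaled per the
#'   compartment contract (centering/autoscaling handled by the caller or
#'   the CV wrapper).
#' @param y two-level factor, or numeric vector in \{-1, +1\}.
#' @param n_components number of latent variables; must not exceed
#'   `min(n - 1, n_features)`. Fewer components are returned if the
#'   residual X or covariance collapses first.
#' @return object of class `pls`: `coef` (features x A matrix, column a =
#'   regression vector using the first a components, on the scale of the X
#'   given), `intercepts`, `n_components` (effective), `scores`, `weights`,
#'   `x_loadings`, `levels`.
#' @export
fit_pls <- function(X, y, n_components) {
  X <- as.matrix(X)
  lev <- NULL
  if (is.factor(y) || is.character(y)) {
    y <- as.factor(y)
    if (nlevels(y) != 2L) stop("y must have exactly two levels")
    lev <- levels(y)
    y <- ifelse(as.integer(y) == 1L, -1, 1)
  }
  n <- nrow(X); p <- ncol(X)
  if (n_components > min(n - 1L, p))
    stop("n_components exceeds min(n - 1, n_features)")
  x_mu <- colMeans(X)
  y_mu <- mean(y)
  E <- sweep(X, 2L, x_mu)
  f <- y - y_mu
  A <- as.integer(n_components)
  W <- matrix(0, p, A); P <- matrix(0, p, A); qv <- numeric(A)
  Tm <- matrix(0, n, A)
  a_eff <- 0L
  for (a in seq_len(A)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_ <- drop(E %*% w)
    tt <- sum(t_^2)
    if (tt < 1e-12) break
    pv <- drop(crossprod(E, t_)) / tt
    qa <- sum(f * t_) / tt
    E <- E - tcrossprod(t_, pv)
    W[, a] <- w; P[, a] <- pv; qv[a] <- qa; Tm[, a] <- t_
    a_eff <- a
  }
  if (a_eff == 0L) stop("X carries no covariance with y")
  W <- W[, seq_len(a_eff), drop = FALSE]
  P <- P[, seq_len(a_eff), drop = FALSE]
  qv <- qv[seq_len(a_eff)]
  Tm <- Tm[, seq_len(a_eff), drop = FALSE]
  # regression vectors for every truncation a = 1..A: b_a = W_a (P_a'W_a)^-1 q_a
  B <- matrix(0, p, a_eff)
  PW <- crossprod(P, W)
  for (a in seq_len(a_eff)) {
    Ra <- solve(PW[seq_len(a), seq_len(a), drop = FALSE], qv[seq_len(a)])
    B[, a] <- W[, seq_len(a), drop = FALSE] %*% Ra
  }
  rownames(B) <- colnames(X)
  structure(list(coef = B, intercepts = y_mu - drop(crossprod(B, x_mu)),
                 n_components = a_eff, scores = Tm, weights = W,
                 x_loadings = P, y_loadings = qv, x_center = x_mu,
                 y_center = y_mu, levels = lev), class = "pls")
}

#' @export
predict.pls <- function(object, newdata, ncomp = object$n_components,
                        type = c("response", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  yhat <- sweep(newdata %*% object$coef[, ncomp, drop = FALSE], 2L,
                object$intercepts[ncomp], "+")
  if (type == "response") return(yhat)
  cls <- ifelse(yhat > 0, 1L, -1L)      # 0 goes to the first level (Cold)
  if (!is.null(object$levels))
    cls <- array(object$levels[(cls + 3L) / 2L], dim = dim(cls))
  cls
}

#' Double cross-validation of a PLS-DA model
#'
#' Nested stratified leave-two-out loops: the inner loop (on each outer
#' training set) picks the number of latent variables minimising the inner
#' misclassification count (ties to the smaller number); the outer loop
#' refits at the chosen complexity and predicts the held-out pair, giving an
#' error estimate untouched by the complexity choice. Optionally, column
#' scaling is recomputed inside every training fold and applied to the
#' held-out samples (no information leak).
#'
#' @param X samples x features matrix (raw or pre-scaled, see `scale_mode`).
#' @param y two-level factor.
#' @param a_max maximum number of latent variables examined.
#' @param scale_mode `"none"` (X used as given), `"center"`, or
#'   `"autoscale"` (parameters from each training fold).
#' @param seed controls fold assignment (the only randomness).
#' @param collect_coefs logical; also return each outer fold's regression
#'   vector (used by the jack-knife).
#' @return list of class `double_cv`: `error`, `chosen_a` (per outer fold),
#'   `predictions`, `folds`, and optionally `fold_coefs` (outer folds x
#'   features).
#' @export
double_cv <- function(X, y, a_max = 10L, scale_mode = c("none", "center",
                                                        "autoscale"),
                      seed = NULL, collect_coefs = FALSE) {
  scale_mode <- match.arg(scale_mode)
  X <- as.matrix(X)
  y <- as.factor(y)
  stopifnot(nlevels(y) == 2L, nrow(X) == length(y), nrow(X) >= 8L)
  n <- nrow(X)
  folds <- lto_folds(y, seed)
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  chosen <- integer(length(folds))
  coefs <- if (collect_coefs) matrix(0, length(folds), ncol(X)) else NULL
  rescale <- function(M, mu, sd_) {
    M <- sweep(M, 2L, mu)
    if (!is.null(sd_)) M <- sweep(M, 2L, sd_, "/")
    M
  }
  for (k in seq_along(folds)) {
    te <- folds[[k]]; tr <- setdiff(seq_len(n), te)
    if (nlevels(droplevels(y[tr])) < 2L)
      stop("a training fold lost a class; cohort too small or unbalanced")
    # inner loop on the training remainder
    inner <- lto_folds(y[tr], if (is.null(seed)) NULL else child_seed(seed, k))
    amax_k <- min(a_max, length(tr) - 3L, ncol(X))
    miss <- numeric(amax_k)
    for (f in inner) {
      itr <- setdiff(seq_along(tr), f)
      Xi <- X[tr[itr], , drop = FALSE]; Xo <- X[tr[f], , drop = FALSE]
      if (scale_mode != "none") {
        mu <- colMeans(Xi)
        sd_ <- if (scale_mode == "autoscale") {
          s <- apply(Xi, 2L, stats::sd); s[s == 0] <- 1; s
        } else NULL
        Xi <- rescale(Xi, mu, sd_); Xo <- rescale(Xo, mu, sd_)
      }
      ai <- min(amax_k, length(itr) - 1L)
      fit <- fit_pls(Xi, y[tr[itr]], ai)
      ph <- predict(fit, Xo, ncomp = seq_len(min(ai, fit$n_components)),
                    type = "class")
      truth <- as.character(y[tr[f]])
      m <- colSums(ph != truth)
      miss[seq_along(m)] <- miss[seq_along(m)] + m
      if (length(m) < amax_k)   # components unavailable count as misses
        miss[(length(m) + 1L):amax_k] <- miss[(length(m) + 1L):amax_k] +
          m[length(m)]
    }
    a_star <- which.min(miss)           # first minimum = smallest A on ties
    chosen[k] <- a_star
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (scale_mode != "none") {
      mu <- colMeans(Xtr)
      sd_ <- if (scale_mode == "autoscale") {
        s <- apply(Xtr, 2L, stats::sd); s[s == 0] <- 1; s
      } else NULL
      Xtr <- rescale(Xtr, mu, sd_); Xte <- rescale(Xte, mu, sd_)
    }
    fit <- fit_pls(Xtr, y[tr], a_star)
    pred[te] <- predict(fit, Xte, ncomp = fit$n_components, type = "class")
    if (collect_coefs) coefs[k, ] <- fit$coef[, fit$n_components]
  }
  out <- list(error = mean(pred != y), chosen_a = chosen,
              predictions = data.frame(truth = y, predicted = pred),
              folds = folds)
  if (collect_coefs) out$fold_coefs <- coefs
  structure(out, class = "double_cv")
}

#' @export
print.double_cv <- function(x, ...) {
  cat(sprintf("double CV: error %.3f; chosen components: %s\n", x$error,
              paste(sort(unique(x$chosen_a)), collapse = ",")))
  invisible(x)
}

#' Jack-knife variable elimination for PLS-DA
#'
#' Regression vectors are collected across the outer cross-validation
#' segments; each feature's standard error is the standard deviation of its
#' coefficient over segments. Features whose standard error exceeds a
#' threshold are removed and the double CV is re-run; the threshold walks
#' down a schedule (by default the descending quantiles 1.00, 0.95, ...,
#' 0.50 of the criterion's distribution). By default the SE is taken
#' relative to the mean coefficient (`criterion = "relative"`): a feature
#' is unstable when its coefficient cannot be told from zero across
#' segments, which is the jack-knife criterion used with PLS in practice —
#' thresholding the raw SE (`criterion = "absolute"`) preferentially
#' removes the largest, most discriminating coefficients, whose absolute
#' fold-to-fold variation is biggest. The elimination stops being useful
#' once the error starts to increase; the full trace is recorded regardless
#' and the step with the minimum error (first on ties) is chosen. The final
#' model is refit on all samples with the chosen feature set.
#'
#' @param X samples x features matrix.
#' @param y two-level factor.
#' @param threshold_schedule optional numeric vector of thresholds
#'   (descending); default as above.
#' @param criterion `"relative"` (SE / |mean coefficient|, default) or
#'   `"absolute"` (raw SE).
#' @param a_max,scale_mode,seed as in [double_cv()].
#' @return list of class `jackknife_trace`: `trace` (data.frame threshold /
#'   n_retained / error), `chosen` (row index), `selected` (feature names),
#'   `se` (per-feature criterion values), `final_model` (a `pls` fit on all
#'   samples), `final_a`.
#' @export
jackknife_select <- function(X, y, threshold_schedule = NULL, a_max = 10L,
                             scale_mode = "none", seed = NULL,
                             criterion = c("relative", "absolute")) {
  criterion <- match.arg(criterion)
  X <- as.matrix(X)
  y <- as.factor(y)
  base <- double_cv(X, y, a_max = a_max, scale_mode = scale_mode,
                    seed = seed, collect_coefs = TRUE)
  se <- apply(base$fold_coefs, 2L, stats::sd)
  if (criterion == "relative")
    se <- se / pmax(abs(colMeans(base$fold_coefs)), .Machine$double.eps)
  if (is.null(threshold_schedule))
    threshold_schedule <- stats::quantile(se, probs = seq(1, 0.5, by = -0.05),
                                          names = FALSE)
  keep_sets <- lapply(threshold_schedule, function(th) which(se <= th))
  rows <- list()
  for (i in seq_along(threshold_schedule)) {
    keep <- keep_sets[[i]]
    if (!length(keep)) {
      message(sprintf("threshold %.3g empties the feature set; step skipped",
                      threshold_schedule[i]))
      next
    }
    cv <- if (length(keep) == ncol(X)) base
          else double_cv(X[, keep, drop = FALSE], y, a_max = a_max,
                         scale_mode = scale_mode, seed = seed)
    rows[[length(rows) + 1L]] <- data.frame(
      step = i, threshold = threshold_schedule[i],
      n_retained = length(keep), error = cv$error,
      a_mode = as.integer(names(which.max(table(cv$chosen_a)))))
  }
  trace <- do.call(rbind, rows)
  chosen <- which.min(trace$error)      # first minimum on ties
  sel_idx <- keep_sets[[trace$step[chosen]]]
  selected <- colnames(X)[sel_idx]
  Xs <- X[, sel_idx, drop = FALSE]
  if (scale_mode != "none") {
    mu <- colMeans(Xs)
    sd_ <- if (scale_mode == "autoscale") {
      s <- apply(Xs, 2L, stats::sd); s[s == 0] <- 1; s
    } else NULL
    Xs <- sweep(Xs, 2L, mu)
    if (!is.null(sd_)) Xs <- sweep(Xs, 2L, sd_, "/")
  }
  a_final <- min(trace$a_mode[chosen], nrow(Xs) - 1L, ncol(Xs))
  final <- fit_pls(Xs, y, a_final)
  structure(list(trace = trace, chosen = chosen, selected = selected,
                 se = se, final_model = final, final_a = a_final),
            class = "jackknife_trace")
}

#' Permutation test of the PLS-DA pipeline
#'
#' Shuffles the class labels and recomputes the double-CV classification
#' error per permutation (with jack-knife selection inside each permutation
#' when `jackknife = TRUE`). Significance at the 5% level is declared when
#' the observed error beats the 5th percentile of the null errors; the
#' p-value carries the add-one correction.
#'
#' @param X samples x features matrix.
#' @param y two-level factor.
#' @param n_permutations default 250, as in the published analyses.
#' @param jackknife logical; run variable elimination inside each
#'   permutation (slow) or test the fixed pipeline (default).
#' @param a_max,scale_mode as in [double_cv()].
#' @param seed master seed.
#' @return `permutation_result` with the extra field `significant`.
#' @export
permutation_test_plsda <- function(X, y, n_permutations = 250L,
                                   jackknife = FALSE, a_max = 10L,
                                   scale_mode = "none", seed = 1L) {
  y <- as.factor(y)
  run <- function(yy, s) {
    if (jackknife)
      jackknife_select(X, yy, a_max = a_max, scale_mode = scale_mode,
                       seed = s)$trace$error |> min()
    else double_cv(X, yy, a_max = a_max, scale_mode = scale_mode,
                   seed = s)$error
  }
  obs <- run(y, seed)
  null <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    set.seed(child_seed(seed, 500L + b))
    null[b] <- run(sample(y), child_seed(seed, b))
  }
  p <- (1 + sum(null <= obs)) / (n_permutations + 1)
  structure(list(observed = obs, null = null, p_value = p,
                 n_permutations = n_permutations,
                 significant = obs < stats::quantile(null, 0.05,
                                                     names = FALSE)),
            class = "permutation_result")
}

#' Rank features of a final PLS-DA model
#'
#' Orders features by the absolute regression coefficient (importance rank 1
#' = largest) and annotates each with its 2log Cold/Heat ratio computed from
#' the supplied raw (zero-replaced) intensities.
#'
#' @param model a `pls` fit whose features are a subset of `table`'s.
#' @param table a [feature_table()] on the raw intensity scale (after zero
#'   replacement) providing values for the ratio.
#' @param k report size (default 50, the "top 50" convention).
#' @return data.frame `importance`, `feature`, `coefficient`,
#'   `log2_cold_heat`.
#' @export
rank_features <- function(model, table, k = 50L) {
  stopifnot(inherits(model, "pls"), inherits(table, "feature_table"))
  b <- model$coef[, model$n_components]
  ord <- order(-abs(b))
  feats <- rownames(model$coef)[ord]
  k <- min(k, length(feats))
  feats <- feats[seq_len(k)]
  si <- study_idx(table)
  cls <- study_classes(table)
  lr <- vapply(feats, function(f) {
    log2_ratio(table$intensities[si, f], cls)
  }, 0)
  data.frame(importance = seq_len(k), feature = feats,
             coefficient = b[ord][seq_len(k)], log2_cold_heat = lr,
             row.names = NULL)
}
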