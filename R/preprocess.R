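#' Merge sparse questionnaire categories
#'
#' Every retained category of every variable must be supported by at least
#' `min_count` observations (default 7), or the variable collapses to a
#' single category and is flagged for removal. Ordinal variables merge a
#' sparse category into the adjacent category with the nearer code (ties
#' toward the lower code), preserving order; nominal variables pool all
#' sparse categories into one "other" category. Codes are re-indexed to
#' consecutive integers afterwards.
#'
#' @param dataset a [cat_dataset()].
#' @param min_count minimum per-category support.
#' @return list with `dataset` (recoded) and `log` (data.frame of variable,
#'   action messages).
#' @export
merge_sparse_categories <- function(dataset, min_count = 7L) {
  stopifnot(inherits(dataset, "cat_dataset"))
  dat <- dataset$data
  logs <- list()
  for (j in seq_len(ncol(dat))) {
    lvl <- dataset$specs[[j]]$level
    y <- dat[, j]
    if (lvl %in% c("nominal")) {
      tab <- table(y)
      bad <- as.integer(names(tab)[tab < min_count])
      if (length(bad) && length(bad) < length(tab)) {
        other <- max(y, na.rm = TRUE) + 1L
        y[y %in% bad] <- other
        # pooled "other" may itself still be sparse; if so merge it into the
        # modal category
        if (sum(y == other, na.rm = TRUE) < min_count) {
          tab2 <- table(y[y != other])
          y[y == other] <- as.integer(names(tab2)[which.max(tab2)])
        }
        logs[[length(logs) + 1L]] <- data.frame(
          variable = colnames(dat)[j],
          action = sprintf("pooled nominal categories %s",
                           paste(bad, collapse = ",")))
      } else if (length(bad)) {
        y[] <- 1L   # everything sparse: collapses to a single category
        logs[[length(logs) + 1L]] <- data.frame(
          variable = colnames(dat)[j], action = "collapsed to one category")
      }
    } else {
      repeat {
        tab <- table(y)
        cats <- as.integer(names(tab))
        if (length(cats) <= 1L) break
        bad <- cats[tab < min_count]
        if (!length(bad)) break
        b <- bad[1L]
        nb <- cats[cats != b]
        # adjacent category with the nearer code; ties toward the lower code
        dist <- abs(nb - b)
        cand <- nb[dist == min(dist)]
        tgt <- min(cand)
        y[y == b] <- tgt
        logs[[length(logs) + 1L]] <- data.frame(
          variable = colnames(dat)[j],
          action = sprintf("merged category %d into %d", b, tgt))
      }
    }
    # re-index to consecutive codes
    obs <- sort(unique(y[!is.na(y)]))
    dat[, j] <- match(y, obs)
  }
  dataset$data <- dat
  list(dataset = dataset,
       log = if (length(logs)) do.call(rbind, logs)
             else data.frame(variable = character(), action = character()))
}

#' Drop variables left with a single category
#'
#' After merging, variables with no variation carry no information and are
#' removed; their names are returned for the analysis report.
#'
#' @param dataset a [cat_dataset()].
#' @return list with `dataset` and `removed` (character vector of names).
#' @export
drop_single_category_variables <- function(dataset) {
  stopifnot(inherits(dataset, "cat_dataset"))
  ncat <- apply(dataset$data, 2L, function(y) length(unique(y[!is.na(y)])))
  removed <- colnames(dataset$data)[ncat <= 1L]
  keep <- ncat > 1L
  dataset$data <- dataset$data[, keep, drop = FALSE]
  dataset$specs <- dataset$specs[keep]
  list(dataset = dataset, removed = removed)
}

#' Uniformly bin a continuous clinical variable
#'
#' Equal-width bins spanning the observed range, codes 1..`n_bins`. Interior
#' edges are half-open (a value exactly on an edge goes to the right bin);
#' the rightmost bin is closed. A constant vector maps to code 1.
#'
#' @param values finite numeric vector.
#' @param n_bins number of bins (default 19).
#' @return integer codes of the same length.
#' @export
bin_clinical <- function(values, n_bins = 19L) {
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(is.na(values) | !is.finite(values))
    stop("non-finite values at positions: ", paste(bad, collapse = ", "))
  }
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(1L, length(values)))
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  codes <- findInterval(values, edges, rightmost.closed = TRUE,
                        left.open = FALSE)
  pmin.int(codes, n_bins)
}

#' Presence filter for LC-MS features
#'
#' A feature is retained iff its nonzero fraction reaches `min_fraction` in
#' at least one class, QC samples excluded from the count.
#'
#' @param table a [feature_table()] with class labels on study samples.
#' @param min_fraction required nonzero fraction (default 0.8).
#' @param rule `"any-class"` (default, a feature passes if either class
#'   supports it) or `"all-classes"`.
#' @return list with `table` (filtered) and `removed` (count).
#' @export
filter_presence <- function(table, min_fraction = 0.8,
                            rule = c("any-class", "all-classes")) {
  rule <- match.arg(rule)
  si <- study_idx(table)
  cls <- study_classes(table)
  if (any(table(cls) < 2L)) stop("each class needs at least 2 samples")
  X <- table$intensities[si, , drop = FALSE]
  frac <- vapply(levels(cls), function(cl) {
    colMeans(X[cls == cl, , drop = FALSE] > 0)
  }, numeric(ncol(X)))                       # features x classes
  pass <- if (rule == "any-class") apply(frac >= min_fraction, 1L, any)
          else apply(frac >= min_fraction, 1L, all)
  list(table = subset_features(table, pass), removed = sum(!pass))
}

#' Replace zeros by half the feature minimum
#'
#' Each zero intensity is replaced by the smallest nonzero value of that
#' feature divided by 2 (a standard non-detect convention). Set
#' `per_feature = FALSE` to use the global smallest measured value instead.
#'
#' @param table a presence-filtered [feature_table()].
#' @param per_feature logical; per-feature (default) or global minimum.
#' @return the table with no remaining zeros.
#' @export
replace_zeros <- function(table, per_feature = TRUE) {
  X <- table$intensities
  if (per_feature) {
    for (j in seq_len(ncol(X))) {
      z <- X[, j] == 0
      if (!any(z)) next
      nz <- X[!z, j]
      if (!length(nz))
        stop(sprintf("feature '%s' is all-zero; run filter_presence first",
                     colnames(X)[j]))
      X[z, j] <- min(nz) / 2
    }
  } else {
    nz <- X[X > 0]
    if (!length(nz)) stop("table is all-zero")
    X[X == 0] <- min(nz) / 2
  }
  table$intensities <- X
  table
}

#' Column scaling of a feature table
#'
#' Mean centering or autoscaling (mean 0, SD 1). Parameters are computed on
#' the study (non-QC) samples and applied to all samples, so QC replicates
#' are expressed on the study scale. Zero-variance features cannot be
#' autoscaled and are removed with a warning.
#'
#' @param table a [feature_table()].
#' @param mode `"center"` (urine convention) or `"autoscale"` (plasma
#'   convention).
#' @return scaled `feature_table`.
#' @export
scale_features <- function(table, mode = c("center", "autoscale")) {
  mode <- match.arg(mode)
  si <- study_idx(table)
  X <- table$intensities
  mu <- colMeans(X[si, , drop = FALSE])
  if (mode == "center") {
    table$intensities <- sweep(X, 2L, mu)
    table$scaling <- "centered"
    return(table)
  }
  sd_ <- apply(X[si, , drop = FALSE], 2L, stats::sd)
  dead <- sd_ == 0
  if (any(dead)) {
    warning(sprintf("removed %d zero-variance feature(s) before autoscaling",
                    sum(dead)))
    table <- subset_features(table, !dead)
    X <- table$intensities; mu <- mu[!dead]; sd_ <- sd_[!dead]
  }
  table$intensities <- sweep(sweep(X, 2L, mu), 2L, sd_, "/")
  table$scaling <- "autoscaled"
  table
}

#' Pooled-QC and outlier screening by PCA
#'
#' PCA on the scaled table; reports (i) outliers — samples whose score on
#' either of the first two components deviates from the component median by
#' more than `mad_threshold` MADs; (ii) analysis stability — the ratio of QC
#' to study-sample score dispersion on PC1-2 (near 0 for tight QC
#' replicates); (iii) time trend — Spearman correlation of PC1 scores with
#' injection order (computed on QC samples when at least 3 are present,
#' otherwise on all samples).
#'
#' @param table a scaled [feature_table()].
#' @param mad_threshold MAD multiple for the outlier call (default 4).
#' @return list with `outliers`, `qc_dispersion_ratio` (NA when not
#'   assessable), `trend` (rho, p.value, basis), and `scores`.
#' @export
qc_screen <- function(table, mad_threshold = 4) {
  X <- table$intensities
  pc <- stats::prcomp(X, center = table$scaling == "raw", scale. = FALSE,
                      rank. = 2L)
  S <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  out <- rep(FALSE, nrow(S))
  for (k in seq_len(ncol(S))) {
    med <- stats::median(S[, k]); md <- stats::mad(S[, k])
    if (md > 0) out <- out | abs(S[, k] - med) > mad_threshold * md
  }
  qc <- table$samples$is_qc
  disp <- function(M) mean(apply(M, 2L, stats::sd))
  ratio <- if (sum(qc) >= 3L)
    disp(S[qc, , drop = FALSE]) / disp(S[!qc, , drop = FALSE])
  else NA_real_
  basis <- if (sum(qc) >= 3L) "qc" else "all"
  ti <- if (basis == "qc") which(qc) else seq_len(nrow(S))
  ct <- suppressWarnings(
    stats::cor.test(S[ti, 1L], table$samples$injection_order[ti],
                    method = "spearman"))
  list(outliers = table$samples$sample[out],
       qc_dispersion_ratio = ratio,
       trend = list(rho = unname(ct$estimate), p.value = ct$p.value,
                    basis = basis),
       scores = S)
}
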