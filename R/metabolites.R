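#' 2log Cold/Heat ratio of class means
#'
#' Base-2 logarithm of the ratio of class-mean intensities, Cold over Heat.
#' Arithmetic class means by default ("average levels"); geometric means
#' behind a flag.
#'
#' @param values strictly positive intensities (after zero replacement).
#' @param labels two-level factor; the first level is the numerator class
#'   (Cold).
#' @param geometric logical; use geometric means.
#' @return scalar 2log ratio.
#' @export
log2_ratio <- function(values, labels, geometric = FALSE) {
  labels <- as.factor(labels)
  stopifnot(nlevels(labels) == 2L, length(values) == length(labels))
  if (any(table(labels) == 0L)) stop("both classes must be non-empty")
  avg <- if (geometric) function(v) exp(mean(log(v))) else mean
  m1 <- avg(values[labels == levels(labels)[1L]])
  m2 <- avg(values[labels == levels(labels)[2L]])
  if (m1 <= 0 || m2 <= 0) stop("non-positive class mean; replace zeros first")
  log2(m1 / m2)
}

#' Flag acylcarnitine-like features by neutral loss
#'
#' A feature is flagged when one of its fragment masses sits within
#' `mass_tolerance` of `precursor - 59.0747` (the trimethylamine +
#' propenoate loss diagnostic for acylcarnitines). As a consistency check,
#' the Spearman correlation between precursor mass and retention time over
#' the flagged set is reported: genuine acylcarnitine series elute later
#' with increasing mass (longer acyl chain, less polar), so the check
#' passes when the correlation is positive and significant.
#'
#' @param features data.frame with columns `feature`, `mz`, `rt`,
#'   `fragments` (semicolon-separated fragment masses, NA if none).
#' @param mass_tolerance Da (default 0.005, high-resolution convention).
#' @param neutral_loss targeted loss in Da.
#' @return list with `flagged` (character vector of feature ids),
#'   `rt_mass_check` (rho, p.value, pass) — NA/pass FALSE when fewer than 3
#'   features are flagged.
#' @export
flag_acylcarnitines <- function(features, mass_tolerance = 0.005,
                                neutral_loss = 59.0747) {
  stopifnot(all(c("feature", "mz", "rt", "fragments") %in% names(features)))
  hit <- vapply(seq_len(nrow(features)), function(i) {
    fr <- features$fragments[i]
    if (is.na(fr) || !nzchar(fr)) return(FALSE)
    fm <- as.numeric(strsplit(fr, ";", fixed = TRUE)[[1L]])
    loss <- features$mz[i] - fm
    any(loss >= 0 & abs(loss - neutral_loss) <= mass_tolerance)
  }, logical(1L))
  flagged <- features$feature[hit]
  check <- list(rho = NA_real_, p.value = NA_real_, pass = FALSE)
  if (sum(hit) >= 3L) {
    ct <- suppressWarnings(stats::cor.test(features$mz[hit], features$rt[hit],
                                           method = "spearman"))
    check <- list(rho = unname(ct$estimate), p.value = ct$p.value,
                  pass = unname(ct$estimate) > 0 && ct$p.value < 0.05)
  }
  list(flagged = flagged, rt_mass_check = check)
}

#' Per-class summary of positive symptom scores
#'
#' For scores 1-7 on a set of symptoms (three joint symptoms in the
#' published table), a score above 1 counts as positive. Reports, per
#' class, the percentage of subjects with exactly 0, at least 1, at least
#' 2, and all 3 positive symptoms, plus a tie-corrected Mann-Whitney U test
#' per symptom. (The "0" row is "exactly zero": within a class the 0 and
#' >=1 rows sum to 100.)
#'
#' @param scores matrix/data.frame of integer scores in 1..7, subjects x
#'   symptoms (3 columns typical).
#' @param labels two-level factor per subject.
#' @return list with `summary` (rows 0 / >=1 / >=2 / =k, one percentage
#'   column per class) and `tests` (data.frame symptom, U, p.value).
#' @export
symptom_positive_summary <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.factor(labels)
  stopifnot(nlevels(labels) == 2L, nrow(scores) == length(labels))
  bad <- which(scores < 1 | scores > 7, arr.ind = TRUE)
  if (nrow(bad))
    stop("scores outside 1..7 for subjects: ",
         paste(unique(rownames(scores)[bad[, 1L]] %||% bad[, 1L]),
               collapse = ", "))
  k <- ncol(scores)
  npos <- rowSums(scores > 1)
  pct <- function(cl, f) 100 * mean(f(npos[labels == cl]))
  rows <- c("0", paste0(">=", seq_len(max(k - 1L, 1L))), paste0("=", k))
  summ <- sapply(levels(labels), function(cl) {
    c(pct(cl, function(x) x == 0),
      vapply(seq_len(max(k - 1L, 1L)), function(j)
        pct(cl, function(x) x >= j), 0),
      pct(cl, function(x) x == k))
  })
  rownames(summ) <- rows
  tests <- do.call(rbind, lapply(seq_len(k), function(j) {
    g1 <- scores[labels == levels(labels)[1L], j]
    g2 <- scores[labels == levels(labels)[2L], j]
    wt <- suppressWarnings(stats::wilcox.test(g1, g2, exact = FALSE,
                                              correct = TRUE))
    data.frame(symptom = colnames(scores)[j] %||% paste0("s", j),
               U = unname(wt$statistic), p.value = wt$p.value)
  }))
  list(summary = summ, tests = tests)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-sample Student t-test from summary statistics
#'
#' Pooled-variance two-tailed t-test computed from group means, standard
#' deviations and sizes, for comparing published group characteristics
#' without raw data.
#'
#' @param mean1,sd1,n1 first group summaries.
#' @param mean2,sd2,n2 second group summaries.
#' @return list with `t`, `df`, `p.value`.
#' @examples
#' ttest_from_summary(51, 13, 20, 54, 11, 19)  # p ~ 0.44
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(sd1 > 0, sd2 > 0, n1 >= 2, n2 >= 2)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t_ <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t_, df = df, p.value = 2 * stats::pt(-abs(t_), df))
}
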