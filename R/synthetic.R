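#' Configuration for a synthetic Cold/Heat cohort
#'
#' Defines the study design the generator emulates: two balanced patient
#' classes, a 57-item symptom questionnaire on a 1-7 scale (some items
#' constant, some with sparse categories), ~40 clinical-chemistry variables
#' with monotone and nonmonotone (quadratic) class relationships, and LC-MS
#' feature tables for urine and plasma with log-normal intensities, planted
#' 2log fold changes, detection-limit zeros, and pooled-QC replicates with
#' injection-order drift.
#'
#' @param n_cold,n_heat subjects per class (defaults 20/19).
#' @param n_items questionnaire items; `n_constant_items` of them are
#'   constant (no variation), `n_sparse_items` carry a category observed
#'   fewer than 7 times, `n_informative_items` discriminate the classes
#'   with latent shift `item_effect` (logit scale).
#' @param n_clinical clinical variables; `n_monotone_clinical` have a class
#'   mean shift of `clinical_effect` SD, `n_quadratic_clinical` have
#'   class-dependent tail enrichment (both tails enriched in Heat, centre in
#'   Cold), the rest are noise.
#' @param n_features_urine,n_features_plasma LC-MS features per table.
#' @param n_informative_features features with a planted class effect;
#'   `log2_effects` gives their 2log Cold/Heat fold changes (length must
#'   match). The default plants the 20 published top urine/plasma
#'   discriminator ratios, each on three features (real discriminating
#'   compounds contribute several correlated features).
#' @param missing_rate fraction of study-sample intensities below the
#'   detection limit (reported as zero).
#' @param n_qc pooled-QC injections per table; `drift_slope` is the
#'   multiplicative intensity drift per injection index.
#' @param urine_n,plasma_n named vectors `c(cold=, heat=)` of study samples
#'   with a collected specimen per compartment (defaults 14/14 and 11/14).
#' @param seed master seed; each table derives an independent child seed.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_cold = 20L, n_heat = 19L,
                          n_items = 57L, n_constant_items = 15L,
                          n_sparse_items = 10L, n_informative_items = 12L,
                          item_effect = 2.2,
                          n_clinical = 40L, n_monotone_clinical = 6L,
                          n_quadratic_clinical = 2L, clinical_effect = 1.2,
                          n_features_urine = 1000L, n_features_plasma = 1000L,
                          n_informative_features = 60L,
                          log2_effects = rep(c(-0.73, -0.70, -0.89, -0.75,
                                               -2.40, -0.98, -0.92, -0.55,
                                               -1.21, -0.53, -1.19, -0.23,
                                               -2.26, -0.66, 0.42, -0.96,
                                               -0.25, -0.44, -0.65, -0.26),
                                             3),
                          missing_rate = 0.2, n_qc = 8L, drift_slope = 0.002,
                          urine_n = c(cold = 14L, heat = 14L),
                          plasma_n = c(cold = 11L, heat = 14L),
                          seed = 1L) {
  cfg <- list(n_cold = as.integer(n_cold), n_heat = as.integer(n_heat),
              n_items = as.integer(n_items),
              n_constant_items = as.integer(n_constant_items),
              n_sparse_items = as.integer(n_sparse_items),
              n_informative_items = as.integer(n_informative_items),
              item_effect = item_effect,
              n_clinical = as.integer(n_clinical),
              n_monotone_clinical = as.integer(n_monotone_clinical),
              n_quadratic_clinical = as.integer(n_quadratic_clinical),
              clinical_effect = clinical_effect,
              n_features_urine = as.integer(n_features_urine),
              n_features_plasma = as.integer(n_features_plasma),
              n_informative_features = as.integer(n_informative_features),
              log2_effects = log2_effects,
              missing_rate = missing_rate, n_qc = as.integer(n_qc),
              drift_slope = drift_slope,
              urine_n = urine_n, plasma_n = plasma_n,
              seed = as.integer(seed))
  counts <- cfg[c("n_cold", "n_heat", "n_items", "n_constant_items",
                  "n_sparse_items", "n_informative_items", "n_clinical",
                  "n_monotone_clinical", "n_quadratic_clinical",
                  "n_features_urine", "n_features_plasma",
                  "n_informative_features", "n_qc")]
  if (any(unlist(counts) < 0L)) stop("all counts must be >= 0")
  if (cfg$n_cold + cfg$n_heat < 8L) stop("need n_cold + n_heat >= 8")
  if (cfg$n_constant_items + cfg$n_sparse_items + cfg$n_informative_items >
      cfg$n_items)
    stop("constant + sparse + informative items exceed n_items")
  if (cfg$n_monotone_clinical + cfg$n_quadratic_clinical > cfg$n_clinical)
    stop("informative clinical variables exceed n_clinical")
  if (cfg$n_informative_features > min(cfg$n_features_urine,
                                       cfg$n_features_plasma))
    stop("n_informative_features exceeds the feature count")
  if (length(log2_effects) != cfg$n_informative_features)
    stop("log2_effects must have length n_informative_features")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (any(urine_n > c(cfg$n_cold, cfg$n_heat)) ||
      any(plasma_n > c(cfg$n_cold, cfg$n_heat)))
    stop("compartment sample counts exceed the cohort size")
  structure(cfg, class = "cohort_config")
}

# independent child seed per table, kept under 2^31
child_seed <- function(seed, k) (seed + k * 1000003L) %% 2147483629L

cohort_labels <- function(config) {
  factor(rep(c("Cold", "Heat"), c(config$n_cold, config$n_heat)),
         levels = c("Cold", "Heat"))
}

cohort_subject_ids <- function(config) {
  c(sprintf("C%02d", seq_len(config$n_cold)),
    sprintf("H%02d", seq_len(config$n_heat)))
}

#' Generate the synthetic symptom questionnaire
#'
#' Integer scores 1-7 per subject and item. Informative items come from an
#' ordered-logit model whose latent mean shifts between classes; constant
#' items show a single value; sparse items are forced to carry a category
#' with fewer than 7 observations; every remaining (non-sparse) item has all
#' observed categories supported by at least 7 subjects.
#'
#' @param config a [cohort_config()].
#' @return list with `data` (subjects x items integer matrix), `labels`,
#'   and `truth` (informative/constant/sparse item names).
#' @export
generate_questionnaire <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(child_seed(config$seed, 1L))
  labels <- cohort_labels(config)
  n <- length(labels)
  z <- ifelse(labels == "Heat", 0.5, -0.5)
  if (abs(config$item_effect) > 8)
    warning("very large item effect: extreme categories clamp the scores")

  kinds <- rep("noise", config$n_items)
  kinds[seq_len(config$n_constant_items)] <- "constant"
  kinds[config$n_constant_items + seq_len(config$n_informative_items)] <- "informative"
  kinds[config$n_constant_items + config$n_informative_items +
          seq_len(config$n_sparse_items)] <- "sparse"

  # wide threshold spacing concentrates mass on few categories so that
  # non-sparse items can satisfy the >=7-per-category support rule at n~39
  thr <- stats::qlogis(c(0.25, 0.55, 0.80, 0.92, 0.97, 0.99)) * 1.1
  draw_item <- function(beta) {
    u <- beta * z + stats::rlogis(n)
    findInterval(u, thr) + 1L
  }
  densify <- function(y) {
    # merge categories observed <7 times into the nearest occupied neighbour
    repeat {
      tab <- table(y)
      bad <- names(tab)[tab < 7L]
      if (!length(bad) || length(tab) == 1L) break
      b <- as.integer(bad[1L])
      others <- as.integer(names(tab)[names(tab) != bad[1L]])
      y[y == b] <- others[which.min(abs(others - b))]
    }
    y
  }

  X <- matrix(1L, n, config$n_items,
              dimnames = list(cohort_subject_ids(config),
                              paste0("v", seq_len(config$n_items))))
  for (j in seq_len(config$n_items)) {
    X[, j] <- switch(kinds[j],
      constant = rep(sample(1:2, 1L), n),
      informative = densify(draw_item(config$item_effect *
                                        sample(c(-1, 1), 1L))),
      sparse = {
        y <- densify(draw_item(0))
        # plant a small category: 3 subjects moved to an unused high code
        free <- setdiff(7:2, unique(y))
        y[sample(n, 3L)] <- if (length(free)) free[1L] else 7L
        y
      },
      noise = densify(draw_item(0)))
  }
  truth <- list(informative_item_ids = colnames(X)[kinds == "informative"],
                constant_item_ids = colnames(X)[kinds == "constant"],
                sparse_item_ids = colnames(X)[kinds == "sparse"])
  list(data = X, labels = labels, truth = truth)
}

#' Generate synthetic clinical-chemistry variables
#'
#' Continuous variables on a standardized scale: monotone-informative
#' variables shift their class means; quadratic-informative variables are
#' tail-enriched in the Heat class (both high and low values) while Cold
#' subjects sit centrally, the nonmonotone pattern an unrestricted spline
#' transformation can pick up but a monotone one cannot; remaining variables
#' are standard-normal noise.
#'
#' @param config a [cohort_config()].
#' @return list with `data` (subjects x variables numeric matrix), `labels`,
#'   `truth` (ids and relation kinds).
#' @export
generate_clinical <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(child_seed(config$seed, 2L))
  labels <- cohort_labels(config)
  n <- length(labels)
  heat <- labels == "Heat"
  z <- ifelse(heat, 0.5, -0.5)

  kinds <- rep("noise", config$n_clinical)
  kinds[seq_len(config$n_monotone_clinical)] <- "monotone"
  kinds[config$n_monotone_clinical + seq_len(config$n_quadratic_clinical)] <- "quadratic"

  X <- matrix(0, n, config$n_clinical,
              dimnames = list(cohort_subject_ids(config),
                              paste0("b", seq_len(config$n_clinical))))
  for (j in seq_len(config$n_clinical)) {
    X[, j] <- switch(kinds[j],
      monotone = sample(c(-1, 1), 1L) * config$clinical_effect * z +
        stats::rnorm(n),
      quadratic = {
        v <- numeric(n)
        v[!heat] <- stats::rnorm(sum(!heat), sd = 0.5)
        v[heat] <- sample(c(-1, 1), sum(heat), replace = TRUE) *
          (0.9 + abs(stats::rnorm(sum(heat), sd = 0.8)))
        v
      },
      noise = stats::rnorm(n))
  }
  truth <- data.frame(
    id = colnames(X)[kinds != "noise"],
    relation = kinds[kinds != "noise"])
  list(data = X, labels = labels, truth = truth)
}

#' Generate a synthetic LC-MS feature table
#'
#' Log-normal base intensities per feature; informative features are
#' multiplied by `2^effect` in the Cold class relative to Heat (so the
#' empirical 2log Cold/Heat ratio of class means converges to the planted
#' effect). Intensities below a detection limit (the `missing_rate` quantile
#' of the drawn study intensities) are reported as zero, so zeros concentrate
#' in low-intensity features. Pooled-QC samples are the cohort mean profile
#' plus small noise, scaled by `(1 + drift_slope * injection_index)`. The
#' first 13 informative features form an acylcarnitine-like family: positive
#' ion mode, a stored fragment at precursor mass minus 59.0747, and
#' retention time strictly increasing with mass.
#'
#' @param config a [cohort_config()].
#' @param compartment `"urine"` or `"plasma"` (selects sample counts and the
#'   child seed).
#' @return list with `table` (a `feature_table`), `labels` (study samples),
#'   `truth` (informative feature ids, effects, acylcarnitine family ids).
#' @export
generate_feature_table <- function(config, compartment = c("urine", "plasma")) {
  stopifnot(inherits(config, "cohort_config"))
  compartment <- match.arg(compartment)
  set.seed(child_seed(config$seed, if (compartment == "urine") 3L else 4L))
  nn <- if (compartment == "urine") config$urine_n else config$plasma_n
  F <- if (compartment == "urine") config$n_features_urine else config$n_features_plasma

  ids <- c(sprintf("C%02d", seq_len(nn[["cold"]])),
           sprintf("H%02d", seq_len(nn[["heat"]])))
  labels <- factor(rep(c("Cold", "Heat"), nn[c("cold", "heat")]),
                   levels = c("Cold", "Heat"))
  ns <- length(ids)

  ninf <- config$n_informative_features
  inf_idx <- sort(sample.int(F, ninf))
  effects <- config$log2_effects
  n_acyl <- min(13L, ninf)
  acyl_idx <- inf_idx[seq_len(n_acyl)]

  # feature metadata
  mz <- round(stats::runif(F, 100, 1000), 4)
  rt <- round(stats::runif(F, 0.5, 30), 3)
  ion <- sample(c("pos", "neg"), F, replace = TRUE)
  fragments <- rep(NA_character_, F)
  # acylcarnitine family: increasing precursor masses, RT strictly
  # increasing with mass, fragment at precursor - 59.0747 exactly
  acyl_mz <- round(204.1230 + sort(sample(0:20, n_acyl)) * 14.0157, 4)
  mz[acyl_idx] <- acyl_mz
  rt[acyl_idx] <- round(2 + 0.05 * (acyl_mz - 200), 3)
  ion[acyl_idx] <- "pos"
  fragments[acyl_idx] <- sprintf("%.4f", acyl_mz - 59.0747)

  base <- stats::rnorm(F, mean = 17, sd = 1.5)     # log2 intensity scale
  # discriminating compounds are confidently detected: their base intensity
  # sits in the upper part of the distribution (as the verified metabolites
  # in the published top-50 lists were)
  base[inf_idx] <- stats::rnorm(ninf, mean = 19, sd = 1)
  eff_col <- numeric(F)
  eff_col[inf_idx] <- effects
  L2 <- matrix(stats::rnorm(ns * F, sd = 0.6), ns, F)
  L2 <- sweep(L2, 2L, base, "+")
  L2[labels == "Cold", ] <- sweep(L2[labels == "Cold", , drop = FALSE],
                                  2L, eff_col, "+")
  intens <- 2^L2

  # QC samples: cohort mean profile + 3% noise, multiplicative drift
  n_qc <- config$n_qc
  qc_prof <- colMeans(intens)
  n_inj <- ns + n_qc
  qc_pos <- unique(round(seq(1, n_inj, length.out = max(n_qc, 1L))))
  if (n_qc > 0L) qc_pos <- qc_pos[seq_len(n_qc)]
  study_pos <- sample(setdiff(seq_len(n_inj), qc_pos))
  QC <- matrix(0, n_qc, F)
  for (i in seq_len(n_qc)) {
    QC[i, ] <- qc_prof * (1 + config$drift_slope * qc_pos[i]) *
      (1 + stats::rnorm(F, sd = 0.03))
  }

  # left-censoring at a detection limit set by the missing-rate quantile
  if (config$missing_rate > 0) {
    lim <- stats::quantile(intens, config$missing_rate, names = FALSE)
    intens[intens < lim] <- 0
    QC[QC < lim] <- 0
  }

  feat_names <- sprintf("F%.4f_%.2f", mz, rt)
  all_int <- rbind(intens, QC)
  rownames(all_int) <- c(ids, sprintf("QC%02d", seq_len(n_qc)))
  colnames(all_int) <- feat_names
  samples <- data.frame(
    sample = rownames(all_int),
    class = c(as.character(labels), rep(NA_character_, n_qc)),
    is_qc = c(rep(FALSE, ns), rep(TRUE, n_qc)),
    injection_order = c(study_pos, qc_pos))
  features <- data.frame(
    feature = feat_names, mz = mz, rt = rt, ion_mode = ion,
    fragments = fragments)
  tab <- feature_table(all_int, samples, features)
  truth <- list(informative_feature_ids = feat_names[inf_idx],
                effects = stats::setNames(effects, feat_names[inf_idx]),
                acylcarnitine_ids = feat_names[acyl_idx])
  list(table = tab, labels = labels, truth = truth)
}

#' Generate a complete synthetic cohort
#'
#' Runs the questionnaire, clinical and both feature-table generators from
#' one master seed and bundles their ground truth.
#'
#' @param config a [cohort_config()].
#' @return list with `questionnaire`, `clinical`, `urine`, `plasma` (each as
#'   returned by its generator), `labels`, `truth`, `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  q <- generate_questionnaire(config)
  cl <- generate_clinical(config)
  ur <- generate_feature_table(config, "urine")
  pl <- generate_feature_table(config, "plasma")
  list(questionnaire = q, clinical = cl, urine = ur, plasma = pl,
       labels = q$labels,
       truth = list(questionnaire = q$truth, clinical = cl$truth,
                    urine = ur$truth, plasma = pl$truth),
       config = config)
}
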