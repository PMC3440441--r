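#' Run configuration with the published thresholds
#'
#' Central place for the pipeline constants: minimum category support 7,
#' 19 uniform clinical bins, VAF selection threshold 0.20, 80% presence
#' fraction, 250 permutations, class weight 1000.
#'
#' @param min_category_count,n_bins,vaf_threshold,presence_fraction,n_permutations,class_weight
#'   pipeline constants; defaults are the published values.
#' @param seed integer seed for all randomized stages.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(min_category_count = 7L, n_bins = 19L,
                       vaf_threshold = 0.20, presence_fraction = 0.8,
                       n_permutations = 250L, class_weight = 1000,
                       seed = 1L) {
  stopifnot(min_category_count >= 1L, n_bins >= 2L,
            vaf_threshold >= 0, vaf_threshold < 1,
            presence_fraction > 0, presence_fraction <= 1,
            n_permutations >= 1L, class_weight > 0)
  structure(list(min_category_count = as.integer(min_category_count),
                 n_bins = as.integer(n_bins),
                 vaf_threshold = vaf_threshold,
                 presence_fraction = presence_fraction,
                 n_permutations = as.integer(n_permutations),
                 class_weight = class_weight,
                 seed = as.integer(seed)), class = "run_config")
}

#' Write a synthetic cohort to CSV/JSON files
#'
#' One CSV per table (subjects x variables; samples x features with the
#' metadata in companion CSVs), a labels CSV, and the ground truth as JSON.
#'
#' @param cohort as returned by [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  wcsv <- function(x, name) {
    p <- file.path(dir, name)
    utils::write.csv(x, p, row.names = FALSE)
    paths[name] <<- p
  }
  wcsv(data.frame(subject = rownames(cohort$questionnaire$data),
                  cohort$questionnaire$data, check.names = FALSE),
       "questionnaire.csv")
  wcsv(data.frame(subject = rownames(cohort$clinical$data),
                  cohort$clinical$data, check.names = FALSE), "clinical.csv")
  wcsv(data.frame(subject = cohort$questionnaire$data |> rownames(),
                  class = as.character(cohort$labels)), "labels.csv")
  for (comp in c("urine", "plasma")) {
    tab <- cohort[[comp]]$table
    wcsv(data.frame(sample = rownames(tab$intensities), tab$intensities,
                    check.names = FALSE),
         sprintf("%s_intensities.csv", comp))
    wcsv(tab$samples, sprintf("%s_samples.csv", comp))
    wcsv(tab$features, sprintf("%s_features.csv", comp))
  }
  p <- file.path(dir, "truth.json")
  jsonlite::write_json(cohort$truth, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths["truth.json"] <- p
  p <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(cohort$config), p, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths["config.json"] <- p
  invisible(paths)
}

read_feature_table_csv <- function(dir, compartment) {
  f <- function(name) file.path(dir, sprintf("%s_%s.csv", compartment, name))
  if (!file.exists(f("intensities"))) return(NULL)
  intens <- utils::read.csv(f("intensities"), check.names = FALSE)
  rn <- intens$sample
  intens <- as.matrix(intens[, -1L, drop = FALSE])
  rownames(intens) <- rn
  samples <- utils::read.csv(f("samples"))
  samples$class[samples$class == ""] <- NA
  features <- utils::read.csv(f("features"),
                              colClasses = c(fragments = "character"))
  features$fragments[features$fragments == ""] <- NA_character_
  feature_table(intens, samples, features)
}

#' Load a cohort from a directory of CSV files
#'
#' Reads the tables written by [write_cohort()] (or hand-prepared files of
#' the same shape), aligns subjects across tables by id, and validates the
#' labels. Missing compartment files are allowed (that stage is skipped
#' with a warning).
#'
#' @param dir directory with `questionnaire.csv`, `clinical.csv`,
#'   `labels.csv` and optional `urine_*` / `plasma_*` CSVs.
#' @return list with `questionnaire` (integer matrix), `clinical` (numeric
#'   matrix), `labels` (factor named by subject), `urine`, `plasma`
#'   (`feature_table` or NULL).
#' @export
load_cohort <- function(dir) {
  lab <- utils::read.csv(file.path(dir, "labels.csv"))
  if (anyDuplicated(lab$subject))
    stop("duplicate subject ids in labels: ",
         paste(unique(lab$subject[duplicated(lab$subject)]), collapse = ", "))
  if (length(unique(lab$class)) != 2L)
    stop("labels must contain exactly two classes, found: ",
         paste(unique(lab$class), collapse = ", "))
  labels <- factor(lab$class)
  names(labels) <- lab$subject

  read_tab <- function(name, mode) {
    p <- file.path(dir, name)
    if (!file.exists(p)) {
      warning(sprintf("%s missing; stage skipped", name))
      return(NULL)
    }
    d <- utils::read.csv(p, check.names = FALSE)
    m <- as.matrix(d[, -1L, drop = FALSE])
    storage.mode(m) <- mode
    rownames(m) <- d$subject
    extra <- setdiff(rownames(m), lab$subject)
    if (length(extra))
      stop(sprintf("subjects in %s but not in labels: %s", name,
                   paste(extra, collapse = ", ")))
    m[lab$subject[lab$subject %in% rownames(m)], , drop = FALSE]
  }
  list(questionnaire = read_tab("questionnaire.csv", "integer"),
       clinical = read_tab("clinical.csv", "double"),
       labels = labels,
       urine = read_feature_table_csv(dir, "urine"),
       plasma = read_feature_table_csv(dir, "plasma"))
}

#' Write an analysis report as JSON
#'
#' Serialises model output (selected variables with loadings, transformation
#' tables, selected features with 2log ratios, CV errors, permutation
#' p-values) with a config echo, in a stable key order.
#'
#' @param report named list of results.
#' @param path output file.
#' @param config optional `run_config` echoed under `$config`.
#' @return invisibly, `path`.
#' @export
write_report <- function(report, path, config = NULL) {
  if (!is.null(config)) report$config <- unclass(config)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
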