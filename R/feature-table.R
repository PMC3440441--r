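#' LC-MS feature table
#'
#' Container for a samples x features intensity matrix with sample metadata
#' (class label, pooled-QC flag, injection order) and feature metadata
#' (m/z, retention time, ion mode, optional fragment masses).
#'
#' @param intensities numeric samples x features matrix, nonnegative before
#'   scaling.
#' @param samples data.frame with columns `sample`, `class` (NA for QC
#'   samples), `is_qc`, `injection_order` (unique).
#' @param features data.frame with columns `feature`, `mz`, `rt`,
#'   `ion_mode`, `fragments` (semicolon-separated masses or NA).
#' @param scaling one of `"raw"`, `"centered"`, `"autoscaled"`.
#' @return object of class `feature_table`.
#' @export
feature_table <- function(intensities, samples, features, scaling = "raw") {
  intensities <- as.matrix(intensities)
  stopifnot(nrow(intensities) == nrow(samples),
            ncol(intensities) == nrow(features))
  if (scaling == "raw" && any(intensities < 0))
    stop("raw intensities must be nonnegative")
  if (anyDuplicated(samples$injection_order))
    stop("injection_order must be unique")
  if (any(!is.na(samples$class[samples$is_qc])))
    stop("QC samples must carry no class label")
  rownames(intensities) <- samples$sample
  colnames(intensities) <- features$feature
  structure(list(intensities = intensities, samples = samples,
                 features = features, scaling = scaling),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples (%d QC) x %d features [%s]\n",
              nrow(x$intensities), sum(x$samples$is_qc),
              ncol(x$intensities), x$scaling))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

# study (non-QC) sample selector
study_idx <- function(table) which(!table$samples$is_qc)

# class factor of the study samples
study_classes <- function(table) {
  factor(table$samples$class[study_idx(table)])
}

# column subset
subset_features <- function(table, keep) {
  feature_table(table$intensities[, keep, drop = FALSE],
                table$samples,
                table$features[keep, , drop = FALSE],
                scaling = table$scaling)
}
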