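#' Scaling specification for one variable
#'
#' Describes how a variable's categories are quantified during optimal
#' scaling: the analysis level (how much freedom the transformation has),
#' the spline shape for spline levels, and the variable weight.
#'
#' @param level one of `"nominal"` (free quantifications), `"ordinal"`
#'   (monotone), `"spline-nominal"` (smooth piecewise polynomial),
#'   `"spline-ordinal"` (smooth and monotone), `"numeric"` (linear in the
#'   category codes).
#' @param degree spline degree; ignored for non-spline levels.
#' @param knots number of interior knots; ignored for non-spline levels.
#' @param weight positive variable weight. The class indicator in forced
#'   classification carries a very large weight (1000 by default) so the
#'   first component aligns with the class split.
#' @return a list of class `scaling_spec`.
#' @export
scaling_spec <- function(level = "ordinal", degree = 2L, knots = 2L,
                         weight = 1) {
  level <- match.arg(level, c("nominal", "ordinal", "spline-nominal",
                              "spline-ordinal", "numeric"))
  stopifnot(degree >= 1L, knots >= 0L, weight > 0)
  if (startsWith(level, "spline") && degree + knots < 1L)
    stop("spline levels require degree + knots >= 1")
  structure(list(level = level, degree = as.integer(degree),
                 knots = as.integer(knots), weight = weight),
            class = "scaling_spec")
}

#' Categorical dataset for optimal-scaling PCA
#'
#' Wraps an integer-coded subjects x variables matrix with per-variable
#' scaling specifications. Category codes are positive integers; they need
#' not be consecutive (observed codes are recoded internally when fitting),
#' but every variable must show at least two observed categories to be
#' usable in a fit.
#'
#' @param data integer matrix or data.frame, subjects in rows. Positive
#'   codes; `NA` allowed (subjects with missing codes are skipped in
#'   category counts).
#' @param specs a single [scaling_spec()] recycled over variables, or a list
#'   of one spec per variable (named or positional).
#' @return object of class `cat_dataset` with elements `data` (integer
#'   matrix) and `specs` (list of `scaling_spec`).
#' @export
cat_dataset <- function(data, specs = scaling_spec("ordinal")) {
  data <- as.matrix(data)
  storage.mode(data) <- "integer"
  if (any(data <= 0L, na.rm = TRUE)) stop("category codes must be positive")
  J <- ncol(data)
  if (is.null(colnames(data))) colnames(data) <- paste0("v", seq_len(J))
  if (inherits(specs, "scaling_spec")) specs <- rep(list(specs), J)
  if (length(specs) != J) stop("need one scaling spec per variable")
  nm <- names(specs)
  if (!is.null(nm) && all(nzchar(nm))) {    # fully named: align to columns
    if (!setequal(nm, colnames(data)))
      stop("spec names do not match the variable names")
    specs <- specs[colnames(data)]
  }
  names(specs) <- colnames(data)
  structure(list(data = data, specs = specs), class = "cat_dataset")
}

#' @export
print.cat_dataset <- function(x, ...) {
  lv <- vapply(x$specs, `[[`, "", "level")
  cat(sprintf("cat_dataset: %d subjects x %d variables\n",
              nrow(x$data), ncol(x$data)))
  print(table(`analysis level` = lv))
  invisible(x)
}

#' @export
dim.cat_dataset <- function(x) dim(x$data)

# row subset (used by cross-validation)
subset_rows <- function(dataset, idx) {
  structure(list(data = dataset$data[idx, , drop = FALSE],
                 specs = dataset$specs), class = "cat_dataset")
}

# replace/override specs for named variables
set_specs <- function(dataset, vars, spec) {
  j <- match(vars, colnames(dataset$data))
  if (anyNA(j)) stop("unknown variables: ", paste(vars[is.na(j)], collapse = ", "))
  for (i in j) dataset$specs[[i]] <- spec
  dataset
}
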