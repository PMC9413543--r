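#' Filtering rules for a feature matrix
#'
#' The three standard matrix filters applied before any modeling: drop
#' CAMERA-style isotope companion rows, drop features eluting before the
#' injection peak, and drop features that are not repeatable across the
#' pooled QC injections.
#'
#' @param min_rt minimum retention time (minutes); features below it are
#'   removed (default 1.0, the injection-peak window)
#' @param max_qc_rsd maximum allowed percent relative standard deviation
#'   across QC injections (default 20)
#' @param drop_isotopes drop features whose isotope flag is non-empty
#'   (default TRUE)
#' @return an object of class `filter_rules`
#' @export
filter_rules <- function(min_rt = 1.0, max_qc_rsd = 20.0,
                         drop_isotopes = TRUE) {
  if (min_rt < 0) stop("min_rt must be >= 0")
  if (max_qc_rsd <= 0) stop("max_qc_rsd must be > 0")
  structure(list(min_rt = min_rt, max_qc_rsd = max_qc_rsd,
                 drop_isotopes = isTRUE(drop_isotopes)),
            class = "filter_rules")
}

#' Percent relative standard deviation across QC injections
#'
#' %RSD = 100 * sd / mean per feature over the QC samples, with the sample
#' standard deviation (n - 1 denominator). Features whose QC mean is zero
#' have no defined %RSD and are returned as `NaN`.
#'
#' @param x a [feature_table()] with at least 2 QC samples
#' @return named numeric vector, one %RSD per feature
#' @export
qc_rsd <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  qc <- x$intensities[, x$samples$class == "QC", drop = FALSE]
  if (ncol(qc) < 2)
    stop("qc_rsd requires at least 2 QC samples (found ", ncol(qc), ")")
  m <- rowMeans(qc)
  s <- apply(qc, 1, stats::sd)
  out <- ifelse(m == 0, NaN, 100 * s / m)
  names(out) <- x$features$feature_id
  out
}

#' Apply the matrix filters
#'
#' Removes features in the stated order -- isotope companions, early
#' eluters (RT below `min_rt`), then QC-unrepeatable features (%RSD above
#' `max_qc_rsd`; features with undefined %RSD are treated as failing) --
#' and reports the count remaining after each rule. The surviving set is
#' order-invariant (the rules are independent predicates); only the report
#' depends on the stated order.
#'
#' @param x a [feature_table()]
#' @param rules a [filter_rules()]
#' @param block block label recorded in the report
#' @return list with elements `table` (filtered [feature_table()]) and
#'   `report` (a [stage_report()] of kind `"filter"`)
#' @export
filter_features <- function(x, rules = filter_rules(), block = "") {
  stopifnot(inherits(x, "feature_table"), inherits(rules, "filter_rules"))
  keep <- rep(TRUE, n_features(x))
  stages <- "Input features"
  counts <- n_features(x)

  if (rules$drop_isotopes) keep <- keep & x$features$isotope == ""
  stages <- c(stages, "After isotope removal")
  counts <- c(counts, sum(keep))

  keep <- keep & x$features$rt >= rules$min_rt
  stages <- c(stages, sprintf("After RT < %g min removal", rules$min_rt))
  counts <- c(counts, sum(keep))

  rsd <- qc_rsd(x)
  keep <- keep & !is.nan(rsd) & rsd <= rules$max_qc_rsd
  stages <- c(stages, sprintf("After QC %%RSD > %g%% removal",
                              rules$max_qc_rsd))
  counts <- c(counts, sum(keep))

  list(table = subset_features(x, keep),
       report = stage_report(stages, counts, block = block, kind = "filter"))
}

#' QC-based injection-order drift correction
#'
#' For every feature a smooth trend is fitted to the QC intensities as a
#' function of injection order; every sample's intensity is divided by the
#' trend evaluated at its own injection order and rescaled to the feature's
#' median QC intensity. The correction factor depends only on injection
#' order, never on class, so between-class intensity ratios are preserved
#' in expectation.
#'
#' Trend families: `"linear"` (default) interpolates piecewise-linearly
#' through the QC points with constant extrapolation beyond the first/last
#' QC; `"lowess"` smooths the QC trajectory first ([stats::lowess()]) and
#' interpolates the smoothed points.
#'
#' Features whose QC trajectory is entirely zero (or whose fitted trend is
#' non-positive somewhere) cannot be corrected; they are left unchanged and
#' listed in the `"uncorrected"` attribute of the result.
#'
#' @param x a [feature_table()] with at least 2 QC samples
#' @param method `"linear"` or `"lowess"`
#' @param lowess_f smoother span for `method = "lowess"`
#' @return the corrected `feature_table`, with attribute `"uncorrected"`
#'   holding the ids of features left as-is
#' @export
qc_drift_correct <- function(x, method = c("linear", "lowess"),
                             lowess_f = 2 / 3) {
  stopifnot(inherits(x, "feature_table"))
  method <- match.arg(method)
  is_qc <- x$samples$class == "QC"
  if (sum(is_qc) < 2)
    stop("drift correction requires at least 2 QC samples")
  qc_ord <- x$samples$injection_order[is_qc]
  all_ord <- x$samples$injection_order
  o <- order(qc_ord)
  qc_ord <- qc_ord[o]

  qc_int <- x$intensities[, is_qc, drop = FALSE][, o, drop = FALSE]
  uncorrected <- character(0)
  out <- x$intensities
  for (i in seq_len(nrow(out))) {
    y <- qc_int[i, ]
    if (all(y == 0)) {
      uncorrected <- c(uncorrected, x$features$feature_id[i])
      next
    }
    if (method == "lowess") {
      sm <- stats::lowess(qc_ord, y, f = lowess_f)
      trend <- stats::approx(sm$x, sm$y, xout = all_ord, rule = 2)$y
    } else {
      trend <- stats::approx(qc_ord, y, xout = all_ord, rule = 2)$y
    }
    if (any(trend <= 0)) {
      uncorrected <- c(uncorrected, x$features$feature_id[i])
      next
    }
    out[i, ] <- x$intensities[i, ] / trend * stats::median(y)
  }
  x$intensities <- out
  attr(x, "uncorrected") <- uncorrected
  x
}

#' Autoscale a samples-by-features matrix
#'
#' Per-feature mean centering and division by the sample standard
#' deviation, so every non-constant feature has mean 0 and unit variance.
#' Constant features have no scale; they are left as all-zero columns when
#' `allow_constant = TRUE` and are an error otherwise.
#'
#' @param x numeric matrix, samples x features (or a `scaled_matrix`)
#' @param allow_constant tolerate zero-variance columns (default TRUE)
#' @return a `scaled_matrix`: the scaled matrix with attributes `scaling`
#'   (`"autoscale"`), `center` and `scale` (per-feature parameters, reusable
#'   on new samples)
#' @export
autoscale <- function(x, allow_constant = TRUE) {
  x <- unclass_scaled(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  zero <- scl == 0 | is.na(scl)
  if (any(zero) && !allow_constant)
    stop("constant column(s) cannot be autoscaled: ",
         paste(utils::head(colnames(x)[zero], 5), collapse = ", "))
  scl[zero] <- 1
  out <- sweep(sweep(x, 2, ctr, `-`), 2, scl, `/`)
  structure(out, scaling = "autoscale", center = ctr, scale = scl,
            class = c("scaled_matrix", "matrix", "array"))
}

#' Log10-scale a samples-by-features matrix
#'
#' Elementwise log10. Zeros are only admissible with `offset = "auto"`
#' (adds half the smallest positive value in the matrix, reported via a
#' warning and the `"offset"` attribute) or an explicit numeric offset;
#' negative entries are always an error.
#'
#' @param x numeric matrix, samples x features
#' @param offset `0` (default), `"auto"`, or a positive number added before
#'   the log
#' @return a `scaled_matrix` with attribute `scaling = "log10"`
#' @export
log10_scale <- function(x, offset = 0) {
  x <- unclass_scaled(x)
  if (any(x < 0)) stop("log10 scaling requires non-negative intensities")
  if (identical(offset, "auto")) {
    pos <- x[x > 0]
    if (!length(pos)) stop("matrix has no positive entries")
    offset <- min(pos) / 2
    warning("log10 zero policy: adding offset ", signif(offset, 4),
            " (half the smallest positive intensity)")
  }
  if (offset == 0 && any(x == 0))
    stop("zero intensities under log10 without an offset; ",
         "use offset = \"auto\" or a positive offset")
  structure(log10(x + offset), scaling = "log10", offset = offset,
            class = c("scaled_matrix", "matrix", "array"))
}

# Strip scaled_matrix attributes, returning a plain matrix.
unclass_scaled <- function(x) {
  x <- as.matrix(x)
  attr(x, "scaling") <- NULL
  attr(x, "center") <- NULL
  attr(x, "scale") <- NULL
  attr(x, "offset") <- NULL
  class(x) <- c("matrix", "array")
  x
}

#' Apply stored autoscaling parameters to new samples
#'
#' @param model a `scaled_matrix` produced by [autoscale()]
#' @param newdata matrix with the same feature columns
#' @return plain matrix, scaled with the training parameters
#' @export
apply_scaling <- function(model, newdata) {
  ctr <- attr(model, "center")
  scl <- attr(model, "scale")
  if (is.null(ctr) || is.null(scl))
    stop("model carries no centering/scale parameters")
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(ctr))
    stop("newdata has ", ncol(newdata), " columns; expected ", length(ctr))
  sweep(sweep(newdata, 2, ctr, `-`), 2, scl, `/`)
}
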