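#' Construct a feature table
#'
#' The central data container of the package: a feature-by-sample intensity
#' matrix from one ionization mode, together with per-feature metadata
#' (m/z, retention time, isotope flag) and per-sample metadata (class label,
#' injection order).
#'
#' @param features data.frame with columns `feature_id` (unique character),
#'   `mz` (Th, > 0), `rt` (minutes, >= 0) and `isotope` (either `""` or one of
#'   `"[M+1]"`, `"[M+2]"`, `"[M+3]"`).
#' @param intensities numeric matrix, features x samples, non-negative.
#'   `NA` entries are only admissible before a fill policy has been applied
#'   (see [read_feature_table()]).
#' @param samples data.frame with columns `sample_id` (unique character),
#'   `class` (one of `"A"`, `"B"`, `"C"`, `"QC"`) and `injection_order`
#'   (unique positive integers).
#'
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(features, intensities, samples) {
  stopifnot(is.data.frame(features), is.data.frame(samples))
  intensities <- as.matrix(intensities)
  req_f <- c("feature_id", "mz", "rt", "isotope")
  req_s <- c("sample_id", "class", "injection_order")
  if (!all(req_f %in% names(features)))
    stop("features must have columns: ", paste(req_f, collapse = ", "))
  if (!all(req_s %in% names(samples)))
    stop("samples must have columns: ", paste(req_s, collapse = ", "))
  features$feature_id <- as.character(features$feature_id)
  features$isotope <- as.character(features$isotope)
  samples$sample_id <- as.character(samples$sample_id)
  samples$class <- as.character(samples$class)

  if (anyDuplicated(features$feature_id))
    stop("duplicate feature id(s): ",
         paste(unique(features$feature_id[duplicated(features$feature_id)]),
               collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample id(s): ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  if (nrow(intensities) != nrow(features) || ncol(intensities) != nrow(samples))
    stop("intensity matrix dimensions (", nrow(intensities), " x ",
         ncol(intensities), ") do not match ", nrow(features), " features x ",
         nrow(samples), " samples")
  if (any(!is.na(features$mz) & features$mz <= 0))
    stop("all m/z values must be > 0")
  if (any(!is.na(features$rt) & features$rt < 0))
    stop("all retention times must be >= 0")
  bad_iso <- !(features$isotope %in% c("", "[M+1]", "[M+2]", "[M+3]"))
  if (any(bad_iso))
    stop("invalid isotope flag(s): ",
         paste(unique(features$isotope[bad_iso]), collapse = ", "))
  bad_cls <- !(samples$class %in% c("A", "B", "C", "QC"))
  if (any(bad_cls))
    stop("unknown class label(s): ",
         paste(unique(samples$class[bad_cls]), collapse = ", "),
         " (expected A, B, C or QC)")
  ord <- samples$injection_order
  if (any(ord != round(ord)) || any(ord < 1))
    stop("injection orders must be positive integers")
  if (anyDuplicated(ord))
    stop("injection orders must be unique")
  if (any(intensities < 0, na.rm = TRUE))
    stop("intensities must be non-negative")

  dimnames(intensities) <- list(features$feature_id, samples$sample_id)
  structure(
    list(features = features, intensities = intensities, samples = samples),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  n_qc <- sum(x$samples$class == "QC")
  cat("feature_table: ", nrow(x$features), " features x ",
      nrow(x$samples), " samples (", nrow(x$samples) - n_qc, " study, ",
      n_qc, " QC)\n", sep = "")
  cat("  classes: ",
      paste(names(table(x$samples$class)), table(x$samples$class),
            sep = "=", collapse = ", "), "\n", sep = "")
  cat("  rt range: ", min(x$features$rt), "-", max(x$features$rt),
      " min; m/z range: ", min(x$features$mz), "-", max(x$features$mz),
      "\n", sep = "")
  invisible(x)
}

#' Number of features / samples in a feature table
#' @param x a `feature_table`
#' @return integer count
#' @export
n_features <- function(x) nrow(x$features)

#' @rdname n_features
#' @export
n_samples <- function(x) nrow(x$samples)

#' Subset a feature table
#'
#' @param x a `feature_table`
#' @param keep logical or index vector over features (`subset_features`) or
#'   samples (`subset_samples`)
#' @return a `feature_table`
#' @export
subset_features <- function(x, keep) {
  feature_table(x$features[keep, , drop = FALSE],
                x$intensities[keep, , drop = FALSE],
                x$samples)
}

#' @rdname subset_features
#' @export
subset_samples <- function(x, keep) {
  feature_table(x$features,
                x$intensities[, keep, drop = FALSE],
                x$samples[keep, , drop = FALSE])
}

#' Extract an analysis-ready intensity matrix
#'
#' Returns the intensity matrix transposed to the samples-by-features
#' orientation used by all multivariate routines, optionally restricted to
#' study samples (classes A/B/C) or QC samples.
#'
#' @param x a `feature_table`
#' @param which `"study"` (default), `"qc"` or `"all"`
#' @return numeric matrix, samples x features, with dimnames
#' @export
intensity_matrix <- function(x, which = c("study", "qc", "all")) {
  which <- match.arg(which)
  keep <- switch(which,
                 study = x$samples$class != "QC",
                 qc    = x$samples$class == "QC",
                 all   = rep(TRUE, nrow(x$samples)))
  t(x$intensities[, keep, drop = FALSE])
}

#' Class labels of the study samples
#' @param x a `feature_table`
#' @return factor with levels A, B, C for the non-QC samples
#' @export
study_classes <- function(x) {
  cls <- x$samples$class[x$samples$class != "QC"]
  factor(cls, levels = c("A", "B", "C"))
}
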