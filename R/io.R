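#' Read a feature table and its sample metadata from delimited text
#'
#' The feature file holds one row per feature with columns `feature_id`,
#' `mz`, `rt`, `isotope`, followed by one intensity column per sample. The
#' metadata file holds `sample_id`, `class` and `injection_order`. Both are
#' TSV by default; any single-character delimiter is accepted.
#'
#' Missing intensities are rejected unless `na_action = "fill"`, in which
#' case each missing entry is replaced by half the smallest positive
#' intensity of that feature (peak-filling is assumed to have happened
#' upstream, so gaps indicate a broken export).
#'
#' @param path feature table file
#' @param metadata_path sample metadata file
#' @param sep field delimiter (default tab)
#' @param na_action `"error"` (default) or `"fill"`
#' @return a [feature_table()]
#' @export
read_feature_table <- function(path, metadata_path, sep = "\t",
                               na_action = c("error", "fill")) {
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stop("feature table file not found: ", path)
  if (!file.exists(metadata_path))
    stop("metadata file not found: ", metadata_path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = NA, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           na.strings = c("NA", ""))
  req <- c("feature_id", "mz", "rt", "isotope")
  if (!all(req %in% names(raw)))
    stop("feature table header must declare columns: ",
         paste(req, collapse = ", "))
  meta <- utils::read.table(metadata_path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, quote = "")
  sample_cols <- setdiff(names(raw), req)
  missing_samples <- setdiff(sample_cols, meta$sample_id)
  if (length(missing_samples))
    stop("intensity column(s) without metadata: ",
         paste(missing_samples, collapse = ", "))
  absent <- setdiff(meta$sample_id, sample_cols)
  if (length(absent))
    stop("metadata sample(s) without intensity column: ",
         paste(absent, collapse = ", "))

  features <- raw[, req, drop = FALSE]
  features$isotope[is.na(features$isotope)] <- ""
  intens <- as.matrix(raw[, meta$sample_id, drop = FALSE])
  if (!is.numeric(intens)) {
    bad <- which(!vapply(raw[, meta$sample_id, drop = FALSE],
                         is.numeric, logical(1)))
    stop("non-numeric intensities in column(s): ",
         paste(meta$sample_id[bad], collapse = ", "))
  }
  if (anyNA(intens)) {
    if (na_action == "error") {
      idx <- which(is.na(intens), arr.ind = TRUE)[1, ]
      stop("missing intensity at feature '", features$feature_id[idx[1]],
           "', sample '", meta$sample_id[idx[2]],
           "' (pass na_action = \"fill\" to impute)")
    }
    for (i in which(rowSums(is.na(intens)) > 0)) {
      row <- intens[i, ]
      pos <- row[!is.na(row) & row > 0]
      fill <- if (length(pos)) min(pos) / 2 else 0
      intens[i, is.na(row)] <- fill
    }
  }
  feature_table(features, intens, meta)
}

#' Write a feature table and its sample metadata to delimited text
#'
#' m/z is written with 4 decimals and retention time with 2 (the precision
#' carried through all downstream reports); intensities keep full double
#' precision (15 significant digits).
#'
#' @param x a [feature_table()]
#' @param path output feature table file
#' @param metadata_path output metadata file
#' @param sep field delimiter (default tab)
#' @return invisibly, `x`
#' @export
write_feature_table <- function(x, path, metadata_path, sep = "\t") {
  stopifnot(inherits(x, "feature_table"))
  out <- data.frame(
    feature_id = x$features$feature_id,
    mz = sprintf("%.4f", x$features$mz),
    rt = sprintf("%.2f", x$features$rt),
    isotope = x$features$isotope,
    stringsAsFactors = FALSE
  )
  intens <- format(x$intensities, digits = 15, trim = TRUE,
                   scientific = FALSE)
  out <- cbind(out, as.data.frame(intens, stringsAsFactors = FALSE))
  names(out) <- c("feature_id", "mz", "rt", "isotope", x$samples$sample_id)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  utils::write.table(x$samples[, c("sample_id", "class", "injection_order")],
                     metadata_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

.CASCADE_STAGES <- c(
  "Total number after matrix filtering",
  "ANOVA and FDR",
  "Post-hoc Tukey HSD (A != B != C)",
  "Fulfil normality",
  "Do not fulfil normality",
  "Kruskal-Wallis",
  "Total significant features"
)

#' Construct a stage-count report
#'
#' Records how many features survive each stage of a processing chain.
#' Two kinds exist: `"filter"` reports (matrix filtering; counts must be
#' non-increasing) and `"cascade"` reports (the seven-row univariate
#' accounting: total, ANOVA+FDR, Tukey, normal, non-normal, Kruskal-Wallis,
#' total significant; internal arithmetic is checked instead of
#' monotonicity, since the normality split partitions the Tukey survivors
#' and the final row is the sum normal + Kruskal-Wallis passes).
#'
#' @param stages character vector of stage names
#' @param counts integer vector, same length
#' @param block label for the data block (e.g. `"ESI+"`)
#' @param kind `"filter"` or `"cascade"`
#' @return an object of class `stage_report`
#' @export
stage_report <- function(stages, counts, block = "",
                         kind = c("filter", "cascade")) {
  kind <- match.arg(kind)
  stages <- as.character(stages)
  counts <- as.integer(counts)
  if (length(stages) != length(counts))
    stop("stages and counts must have equal length")
  if (any(counts < 0)) stop("stage counts must be non-negative")
  if (kind == "filter") {
    if (is.unsorted(rev(counts)))
      stop("inconsistent filter report: counts must be non-increasing (got ",
           paste(counts, collapse = ", "), ")")
  } else {
    if (length(counts) != 7)
      stop("a cascade report has exactly 7 rows")
    if (counts[2] > counts[1] || counts[3] > counts[2])
      stop("inconsistent cascade report: ANOVA/Tukey counts exceed upstream")
    if (counts[4] + counts[5] != counts[3])
      stop("inconsistent cascade report: normal (", counts[4],
           ") + non-normal (", counts[5],
           ") must equal Tukey survivors (", counts[3], ")")
    if (counts[6] > counts[5])
      stop("inconsistent cascade report: Kruskal-Wallis passes exceed ",
           "non-normal features")
    if (counts[7] != counts[4] + counts[6])
      stop("inconsistent cascade report: total significant (", counts[7],
           ") must equal normal (", counts[4], ") + Kruskal-Wallis (",
           counts[6], ") passes")
  }
  structure(list(stages = stages, counts = counts, block = block,
                 kind = kind),
            class = "stage_report")
}

#' @export
print.stage_report <- function(x, ...) {
  hdr <- if (nzchar(x$block)) paste0(" [", x$block, "]") else ""
  cat("stage_report", hdr, " (", x$kind, ")\n", sep = "")
  w <- max(nchar(x$stages))
  for (i in seq_along(x$stages))
    cat(sprintf("  %-*s %8d\n", w, x$stages[i], x$counts[i]))
  invisible(x)
}

#' Write a stage report to disk
#'
#' Emits a machine-readable TSV (`<path>`) and a human-readable text
#' rendering (`<path>` with extension `.txt`). The report's internal
#' consistency is re-validated before writing; an inconsistent report is
#' refused.
#'
#' @param report a [stage_report()]
#' @param path output TSV path
#' @return invisibly, the paths written
#' @export
write_stage_report <- function(report, path) {
  stopifnot(inherits(report, "stage_report"))
  # re-validate: objects may have been edited after construction
  report <- stage_report(report$stages, report$counts, report$block,
                         report$kind)
  df <- data.frame(stage = report$stages, n_features = report$counts,
                   block = report$block, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  txt <- sub("\\.[^.]*$", "", path)
  txt <- paste0(txt, ".txt")
  con <- file(txt, "w")
  on.exit(close(con))
  writeLines(utils::capture.output(print(report)), con)
  invisible(c(tsv = path, txt = txt))
}

#' Read back a stage report written by [write_stage_report()]
#' @param path TSV path
#' @param kind report kind, `"filter"` or `"cascade"`
#' @return a [stage_report()]
#' @export
read_stage_report <- function(path, kind = c("filter", "cascade")) {
  kind <- match.arg(kind)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  stage_report(df$stage, df$n_features,
               block = if ("block" %in% names(df)) df$block[1] else "",
               kind = kind)
}
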