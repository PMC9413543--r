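# Vectorized one-way fixed-effects ANOVA across the rows of a
# features-by-samples matrix. Returns F, p and the pooled within-group
# mean square (needed by Tukey HSD).
.row_anova <- function(m, classes) {
  classes <- droplevels(factor(classes))
  k <- nlevels(classes)
  N <- length(classes)
  if (k < 2) stop("ANOVA requires at least 2 classes")
  if (any(table(classes) < 2)) stop("every class needs at least 2 samples")
  G <- stats::model.matrix(~ classes - 1)         # N x k indicator
  n_g <- colSums(G)
  sums <- m %*% G                                 # feature x k group sums
  means <- sweep(sums, 2, n_g, `/`)
  grand <- rowSums(sums) / N
  ssb <- rowSums(sweep(sweep(means, 1, grand, `-`)^2, 2, n_g, `*`))
  sst <- rowSums(m^2) - N * grand^2
  ssw <- pmax(sst - ssb, 0)
  df1 <- k - 1; df2 <- N - k
  msb <- ssb / df1
  msw <- ssw / df2
  f <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
  p <- ifelse(is.infinite(f), 0, stats::pf(f, df1, df2, lower.tail = FALSE))
  degenerate <- msw == 0
  list(f = f, p = p, msw = msw, means = means, n_g = n_g,
       df2 = df2, k = k, degenerate = degenerate)
}

#' Per-feature one-way ANOVA with Benjamini-Hochberg FDR
#'
#' Runs a fixed-effects one-way ANOVA for every feature across the study
#' classes and adjusts the p-values for multiple testing with the
#' Benjamini-Hochberg procedure. Features with zero within-group variance
#' but non-zero between-group variance are degenerate perfect separators;
#' their p is set to 0 and they are flagged.
#'
#' @param x a [feature_table()] (QC samples are excluded) or a
#'   features-by-samples matrix
#' @param classes class labels, required when `x` is a matrix
#' @param threshold significance threshold on the adjusted values
#'   (default 0.001)
#' @return data.frame with `feature_id`, `p`, `q`, `pass` (`q < threshold`)
#'   and `degenerate`
#' @export
anova_fdr <- function(x, classes = NULL, threshold = 0.001) {
  if (inherits(x, "feature_table")) {
    classes <- study_classes(x)
    m <- t(intensity_matrix(x, "study"))
    ids <- x$features$feature_id
  } else {
    if (is.null(classes)) stop("classes are required for matrix input")
    m <- as.matrix(x)
    ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  }
  a <- .row_anova(m, classes)
  q <- stats::p.adjust(a$p, method = "BH")
  data.frame(feature_id = ids, p = a$p, q = q, pass = q < threshold,
             degenerate = a$degenerate, stringsAsFactors = FALSE)
}

# Vectorized all-pairs Tukey HSD over the rows of a matrix. TRUE iff every
# pairwise comparison is significant at `alpha`.
.row_tukey_all_distinct <- function(m, classes, alpha = 0.05) {
  a <- .row_anova(m, classes)
  k <- a$k
  pairs <- utils::combn(k, 2)
  all_sig <- rep(TRUE, nrow(m))
  pmat <- matrix(NA_real_, nrow(m), ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(a$msw / 2 * (1 / a$n_g[i1] + 1 / a$n_g[i2]))
    qstat <- abs(a$means[, i1] - a$means[, i2]) / se
    p <- ifelse(se > 0,
                stats::ptukey(qstat, nmeans = k, df = a$df2,
                              lower.tail = FALSE),
                ifelse(a$means[, i1] != a$means[, i2], 0, 1))
    pmat[, j] <- p
    all_sig <- all_sig & p < alpha
  }
  list(all_distinct = all_sig, p_pairs = pmat)
}

#' Tukey HSD all-pairs distinctness
#'
#' TRUE iff every pairwise Tukey honestly-significant-difference
#' comparison between the three classes is significant at `alpha`, i.e.
#' the feature separates A, B and C from one another (A != B != C).
#' Studentized-range quantiles on the pooled within-group mean square are
#' used, as in [stats::TukeyHSD()].
#'
#' @param values numeric vector of intensities
#' @param classes class labels (3 classes, each with >= 2 samples)
#' @param alpha per-family significance level (default 0.05)
#' @return logical scalar with attribute `"p_pairs"` (the three adjusted
#'   pairwise p-values)
#' @export
tukey_all_distinct <- function(values, classes, alpha = 0.05) {
  classes <- droplevels(factor(classes))
  if (nlevels(classes) != 3)
    stop("tukey_all_distinct expects exactly 3 classes (found ",
         nlevels(classes), ")")
  r <- .row_tukey_all_distinct(matrix(values, nrow = 1), classes, alpha)
  structure(r$all_distinct, p_pairs = drop(r$p_pairs))
}

#' Lilliefors normality test on within-class residuals
#'
#' Centers the values within each class and applies the Lilliefors
#' (Kolmogorov-Smirnov with estimated mean and variance) test to the
#' pooled residuals -- the residuals of the one-way ANOVA model whose
#' normality assumption is being screened. The p-value uses the
#' Dallal-Wilkinson approximation ([nortest::lillie.test()]); the method
#' is recorded in the result. A per-class alternative tests each class's
#' residuals separately and returns the smallest p.
#'
#' @param values numeric vector
#' @param classes class labels
#' @param pooled test pooled residuals (default) or per class
#' @return list with `p`, `statistic`, `method`; constant residuals give
#'   `p = 0` with `flag = "constant"` (treated as non-normal)
#' @export
lilliefors_normal <- function(values, classes, pooled = TRUE) {
  classes <- droplevels(factor(classes))
  res <- values - stats::ave(values, classes)
  if (length(res) < 5)
    stop("lilliefors_normal requires at least 5 residuals (found ",
         length(res), ")")
  run <- function(r) {
    if (stats::sd(r) == 0)
      return(list(p = 0, statistic = NA_real_,
                  method = "Lilliefors (Dallal-Wilkinson)",
                  flag = "constant"))
    lt <- nortest::lillie.test(r)
    list(p = unname(lt$p.value), statistic = unname(lt$statistic),
         method = "Lilliefors (Dallal-Wilkinson)", flag = NULL)
  }
  if (pooled) return(run(res))
  per <- lapply(split(res, classes), run)
  ps <- vapply(per, function(z) z$p, numeric(1))
  i <- which.min(ps)
  out <- per[[i]]
  out$per_class_p <- ps
  out
}

#' Kruskal-Wallis rank-sum test
#'
#' Rank-based H statistic with tie correction and a chi-square p-value on
#' k - 1 degrees of freedom ([stats::kruskal.test()]). All-tied input has
#' no rank information; it returns `p = 1` with a flag.
#'
#' @param values numeric vector
#' @param classes class labels
#' @return list with `p`, `statistic` (H) and `flag`
#' @export
kruskal_wallis <- function(values, classes) {
  classes <- droplevels(factor(classes))
  if (length(unique(values)) == 1)
    return(list(p = 1, statistic = 0, flag = "all values tied"))
  kt <- stats::kruskal.test(values, classes)
  list(p = unname(kt$p.value), statistic = unname(kt$statistic),
       flag = NULL)
}

#' Classify the between-class trend of a feature
#'
#' Based on class means: `Up` if mean(A) < mean(B) < mean(C); `Down` if
#' mean(A) > mean(B) > mean(C); `Other` otherwise, with the shape recorded
#' in the `"subtype"` attribute (`B-peak` when B exceeds both A and C,
#' `B-trough` when B is below both, `flat` when any means tie).
#'
#' @param values numeric vector of intensities
#' @param classes class labels A/B/C
#' @return character scalar `"Up"`, `"Down"` or `"Other"` with attribute
#'   `"subtype"`
#' @export
classify_trend <- function(values, classes) {
  classes <- droplevels(factor(classes, levels = c("A", "B", "C")))
  m <- tapply(values, classes, mean)
  if (anyNA(m[c("A", "B", "C")]))
    stop("classify_trend requires samples in all of A, B and C")
  a <- m[["A"]]; b <- m[["B"]]; c <- m[["C"]]
  if (a < b && b < c) return(structure("Up", subtype = "monotone"))
  if (a > b && b > c) return(structure("Down", subtype = "monotone"))
  subtype <- if (b > a && b > c) "B-peak"
  else if (b < a && b < c) "B-trough"
  else "flat"
  structure("Other", subtype = subtype)
}

#' The univariate significance cascade
#'
#' Per-feature pipeline on the filtered, drift-corrected intensities (QC
#' samples excluded; the tests are invariant to per-feature affine
#' scaling, so unscaled intensities are used):
#' \enumerate{
#'   \item one-way ANOVA with Benjamini-Hochberg FDR; keep features with
#'     adjusted `q < q_threshold` (set `use_adjusted = FALSE` to threshold
#'     the raw p instead);
#'   \item Tukey HSD all-pairs test at `tukey_alpha`; keep features with
#'     all three classes mutually distinct (A != B != C);
#'   \item Lilliefors screen at `lilliefors_alpha` splits survivors into
#'     normal and non-normal;
#'   \item non-normal features are re-tested by Kruskal-Wallis at
#'     `kw_threshold`.
#' }
#' The final significant set is the union of normal survivors and
#' Kruskal-Wallis passes, and the stage report's last row always equals
#' that sum.
#'
#' @param x a [feature_table()] with at least 1 feature
#' @param q_threshold ANOVA FDR threshold (default 0.001)
#' @param tukey_alpha Tukey HSD level (default 0.05)
#' @param lilliefors_alpha normality screen level (default 0.05)
#' @param kw_threshold Kruskal-Wallis threshold (default 0.001)
#' @param use_adjusted threshold BH-adjusted q (default) or raw p
#' @param block block label for the report
#' @return an object of class `univariate_result`: `features` (per-feature
#'   data.frame with p, q, verdicts and trend), `report` (cascade
#'   [stage_report()]), `thresholds`
#' @export
significance_cascade <- function(x, q_threshold = 0.001,
                                 tukey_alpha = 0.05,
                                 lilliefors_alpha = 0.05,
                                 kw_threshold = 0.001,
                                 use_adjusted = TRUE, block = "") {
  stopifnot(inherits(x, "feature_table"))
  if (n_features(x) == 0)
    stop("significance cascade refused: the table has no features ",
         "(all were removed upstream)")
  classes <- study_classes(x)
  m <- t(intensity_matrix(x, "study"))
  ids <- x$features$feature_id

  af <- anova_fdr(x, threshold = q_threshold)
  pass1 <- if (use_adjusted) af$q < q_threshold else af$p < q_threshold

  tukey_pass <- rep(NA, length(ids))
  if (any(pass1)) {
    tk <- .row_tukey_all_distinct(m[pass1, , drop = FALSE], classes,
                                  tukey_alpha)
    tukey_pass[pass1] <- tk$all_distinct
  }
  pass2 <- !is.na(tukey_pass) & tukey_pass

  norm_p <- rep(NA_real_, length(ids))
  kw_p <- rep(NA_real_, length(ids))
  for (i in which(pass2)) {
    norm_p[i] <- lilliefors_normal(m[i, ], classes)$p
    if (norm_p[i] < lilliefors_alpha)
      kw_p[i] <- kruskal_wallis(m[i, ], classes)$p
  }
  is_normal <- pass2 & !is.na(norm_p) & norm_p >= lilliefors_alpha
  non_normal <- pass2 & !is_normal
  kw_pass <- non_normal & !is.na(kw_p) & kw_p < kw_threshold
  significant <- is_normal | kw_pass

  trend <- character(length(ids))
  for (i in seq_along(ids))
    trend[i] <- classify_trend(m[i, ], classes)

  report <- stage_report(
    .CASCADE_STAGES,
    c(length(ids), sum(pass1), sum(pass2), sum(is_normal),
      sum(non_normal), sum(kw_pass), sum(significant)),
    block = block, kind = "cascade")

  features <- data.frame(
    feature_id = ids, mz = x$features$mz, rt = x$features$rt,
    p = af$p, q = af$q, anova_pass = pass1, tukey_pass = tukey_pass,
    normality_p = norm_p, kw_p = kw_p, significant = significant,
    trend = trend, stringsAsFactors = FALSE)

  structure(list(features = features, report = report,
                 thresholds = list(q_threshold = q_threshold,
                                   tukey_alpha = tukey_alpha,
                                   lilliefors_alpha = lilliefors_alpha,
                                   kw_threshold = kw_threshold,
                                   use_adjusted = use_adjusted)),
            class = "univariate_result")
}

#' @export
print.univariate_result <- function(x, ...) {
  cat("univariate_result\n")
  print(x$report)
  invisible(x)
}

#' Write per-feature univariate results as TSV
#'
#' One row per feature with m/z (4 decimals), RT (2 decimals), p, q,
#' verdicts and trend -- the per-feature companion of the cascade stage
#' report.
#'
#' @param result a `univariate_result`
#' @param path output TSV path
#' @param significant_only write only the significant features
#' @return invisibly, `path`
#' @export
write_univariate_result <- function(result, path,
                                    significant_only = FALSE) {
  stopifnot(inherits(result, "univariate_result"))
  df <- result$features
  if (significant_only) df <- df[df$significant, , drop = FALSE]
  df$mz <- sprintf("%.4f", df$mz)
  df$rt <- sprintf("%.2f", df$rt)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
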