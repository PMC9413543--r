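# One stratified-bootstrap PLS-DA iteration: returns the out-of-bag
# confusion counts (k x k, rows = true class) or NULL if the out-of-bag
# set came up empty (caller redraws).
.boot_once <- function(x, cls_int, by_class, k, n_lv, scale) {
  train <- unlist(lapply(by_class, function(i)
    i[sample.int(length(i), length(i), replace = TRUE)]),
    use.names = FALSE)
  oob <- setdiff(seq_len(nrow(x)), unique(train))
  if (!length(oob)) return(NULL)

  xt <- x[train, , drop = FALSE]
  nt <- nrow(xt)
  ctr <- colMeans(xt)
  scl <- if (scale) {
    s <- sqrt(pmax(colSums(xt^2) - nt * ctr^2, 0) / (nt - 1))
    s[s == 0 | is.na(s)] <- 1
    s
  } else rep(1, ncol(xt))
  Xs <- scale(xt, center = ctr, scale = scl)
  Y <- matrix(0, length(train), k)
  Y[cbind(seq_along(train), cls_int[train])] <- 1
  y_means <- colMeans(Y)
  core <- .pls2_nipals(Xs, sweep(Y, 2, y_means, `-`), n_lv)

  Xo <- scale(x[oob, , drop = FALSE], center = ctr, scale = scl)
  Yhat <- sweep(Xo %*% core$B, 2, y_means, `+`)
  pred <- max.col(Yhat, ties.method = "first")
  cm <- matrix(0, k, k)
  for (j in seq_along(oob))
    cm[cls_int[oob[j]], pred[j]] <- cm[cls_int[oob[j]], pred[j]] + 1
  cm
}

#' Bootstrap out-of-bag validation of PLS-DA
#'
#' Repeatedly draws a stratified bootstrap sample (with replacement,
#' within each class, preserving class sizes) as the training set, fits a
#' PLS-DA model on it, and classifies the out-of-bag samples. Per
#' iteration the confusion matrix is row-normalized; the reported average
#' confusion matrix is the mean over iterations in which the class
#' appeared in the test set. The overall correct classification rate (CCR)
#' is the mean over iterations of the fraction of out-of-bag samples
#' allocated to their true class. Iterations with an empty out-of-bag set
#' are redrawn and counted in `n_redrawn`.
#'
#' @param x numeric matrix, samples x features
#' @param classes factor of class labels (each class needs >= 3 samples)
#' @param n_boot bootstrap iterations (default 1000)
#' @param n_lv PLS-DA latent variables (default 2)
#' @param scale autoscale within each training set (default TRUE)
#' @return an object of class `validation_result`: `confusion` (k x k
#'   average matrix, rows = true class, entries = mean fraction
#'   allocated), `ccr` (overall), `ccr_per_class` (the diagonal),
#'   `ccr_iterations` (per-iteration CCRs), `n_boot`, `n_redrawn`,
#'   `levels`
#' @export
bootstrap_validate <- function(x, classes, n_boot = 1000, n_lv = 2,
                               scale = TRUE) {
  x <- unclass_scaled(x)
  classes <- droplevels(factor(classes))
  k <- nlevels(classes)
  if (k < 2) stop("validation requires at least 2 classes")
  if (any(table(classes) < 3))
    stop("every class needs at least 3 samples for bootstrap validation")
  if (n_boot < 1) stop("n_boot must be >= 1")
  cls_int <- as.integer(classes)
  by_class <- split(seq_along(cls_int), cls_int)

  conf_sum <- matrix(0, k, k)
  row_n <- rep(0, k)
  ccr_it <- numeric(n_boot)
  n_redrawn <- 0L
  for (it in seq_len(n_boot)) {
    cm <- NULL
    while (is.null(cm)) {
      cm <- .boot_once(x, cls_int, by_class, k, n_lv, scale)
      if (is.null(cm)) n_redrawn <- n_redrawn + 1L
    }
    rs <- rowSums(cm)
    present <- rs > 0
    conf_sum[present, ] <- conf_sum[present, ] +
      cm[present, , drop = FALSE] / rs[present]
    row_n <- row_n + present
    ccr_it[it] <- sum(diag(cm)) / sum(cm)
  }
  confusion <- conf_sum / ifelse(row_n > 0, row_n, 1)
  dimnames(confusion) <- list(true = levels(classes),
                              predicted = levels(classes))
  structure(list(confusion = confusion, ccr = mean(ccr_it),
                 ccr_per_class = diag(confusion),
                 ccr_iterations = ccr_it,
                 n_boot = n_boot, n_redrawn = n_redrawn,
                 levels = levels(classes)),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat("validation_result: ", x$n_boot,
      " stratified bootstrap iterations\n", sep = "")
  cat("  overall CCR: ", sprintf("%.4f", x$ccr), "\n", sep = "")
  cat("  average confusion matrix (rows = true class):\n")
  print(round(x$confusion, 4))
  if (!is.null(x$p_value))
    cat("  permutation p-value: ", format(x$p_value), " (",
        x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

#' Permutation test of PLS-DA classification
#'
#' Builds the null distribution of the correct classification rate by
#' permuting the class labels `n_perm` times and re-running the full
#' bootstrap out-of-bag validation on each permuted labeling (with a
#' reduced inner iteration count, `n_boot_inner`, for tractability). The
#' p-value uses the add-one estimator
#' `p = (1 + #[null CCR >= observed]) / (1 + n_perm)`, so it is never
#' zero and ties count against the model.
#'
#' @param x numeric matrix, samples x features
#' @param classes factor of class labels
#' @param n_perm label permutations (default 1000)
#' @param n_boot_inner bootstrap iterations per permutation (default 100)
#' @param n_lv PLS-DA latent variables
#' @param observed_ccr observed CCR to test; if `NULL` it is computed
#'   with `bootstrap_validate(x, classes, n_boot_observed, n_lv)`
#' @param n_boot_observed iterations for the observed CCR (default 1000)
#' @param scale autoscale within training sets (default TRUE)
#' @return a `validation_result` carrying `observed_ccr`, `null_ccr`
#'   (length `n_perm`), `p_value`, `n_perm`, plus the observed validation
#'   fields when it was computed here
#' @export
permutation_test <- function(x, classes, n_perm = 1000,
                             n_boot_inner = 100, n_lv = 2,
                             observed_ccr = NULL, n_boot_observed = 1000,
                             scale = TRUE) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  x <- unclass_scaled(x)
  classes <- droplevels(factor(classes))
  obs_fit <- NULL
  if (is.null(observed_ccr)) {
    obs_fit <- bootstrap_validate(x, classes, n_boot = n_boot_observed,
                                  n_lv = n_lv, scale = scale)
    observed_ccr <- obs_fit$ccr
  }
  null_ccr <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    perm <- sample(classes)
    null_ccr[i] <- bootstrap_validate(x, perm, n_boot = n_boot_inner,
                                      n_lv = n_lv, scale = scale)$ccr
  }
  p <- (1 + sum(null_ccr >= observed_ccr)) / (1 + n_perm)
  out <- if (is.null(obs_fit)) list() else unclass(obs_fit)
  out$observed_ccr <- observed_ccr
  out$null_ccr <- null_ccr
  out$p_value <- p
  out$n_perm <- n_perm
  out$n_boot_inner <- n_boot_inner
  class(out) <- "validation_result"
  out
}

#' Export a validation result as structured text
#'
#' Writes the average confusion matrix (TSV), the CCR/p-value summary and
#' the null CCR sample (one value per line) next to `path`.
#'
#' @param result a `validation_result`
#' @param path base output path; `_confusion.tsv`, `_summary.tsv` and
#'   `_null_ccr.txt` suffixes are appended
#' @return invisibly, the files written
#' @export
write_validation_result <- function(result, path) {
  stopifnot(inherits(result, "validation_result"))
  files <- character(0)
  if (!is.null(result$confusion)) {
    f <- paste0(path, "_confusion.tsv")
    utils::write.table(result$confusion, f, sep = "\t", quote = FALSE,
                       col.names = NA)
    files <- c(files, f)
  }
  f <- paste0(path, "_summary.tsv")
  summ <- data.frame(
    metric = c("ccr", "n_boot", "observed_ccr", "p_value", "n_perm"),
    value = c(result$ccr %||% NA, result$n_boot %||% NA,
              result$observed_ccr %||% NA, result$p_value %||% NA,
              result$n_perm %||% NA))
  utils::write.table(summ, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  if (!is.null(result$null_ccr)) {
    f <- paste0(path, "_null_ccr.txt")
    writeLines(format(result$null_ccr, digits = 10), f)
    files <- c(files, f)
  }
  invisible(files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
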