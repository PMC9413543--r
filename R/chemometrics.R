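# Fix the sign of a score/loading pair: the largest-magnitude element of
# `ref` is made positive and every vector in `...` is flipped with it.
.sign_fix <- function(ref) {
  j <- which.max(abs(ref))
  if (ref[j] < 0) -1 else 1
}

#' Principal component analysis by singular value decomposition
#'
#' Columns are mean-centered (a no-op on autoscaled input) and the
#' truncated SVD taken. Scores are `U %*% D`, loadings are `V`. The sign
#' convention makes the largest-magnitude loading of every component
#' positive, so score plots are reproducible.
#'
#' @param x numeric matrix, samples x features (a `scaled_matrix` from
#'   [autoscale()] or [log10_scale()], or plain)
#' @param n_components number of components, at most
#'   `min(samples - 1, features)`
#' @return an object of class `pca_model`: `scores`, `loadings`,
#'   `explained_variance` (percent per component), `tev` (total explained
#'   variance, percent), `sdev`, `center`
#' @export
pca_fit <- function(x, n_components = 2) {
  x <- unclass_scaled(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 2) stop("PCA requires at least 2 samples")
  if (n_components < 1 || n_components > min(n - 1, p))
    stop("n_components must lie in [1, min(samples - 1, features)] = [1, ",
         min(n - 1, p), "]")
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr, `-`)
  sv <- svd(xc, nu = n_components, nv = n_components)
  d <- sv$d[seq_len(n_components)]
  scores <- sv$u %*% diag(d, n_components)
  loadings <- sv$v
  for (k in seq_len(n_components)) {
    s <- .sign_fix(loadings[, k])
    loadings[, k] <- s * loadings[, k]
    scores[, k] <- s * scores[, k]
  }
  total_var <- sum(sv$d^2)
  ev <- 100 * d^2 / total_var
  dimnames(scores) <- list(rownames(x),
                           paste0("PC", seq_len(n_components)))
  dimnames(loadings) <- list(colnames(x),
                             paste0("PC", seq_len(n_components)))
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = ev, tev = sum(ev),
                 sdev = d / sqrt(n - 1), center = ctr),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("pca_model: ", nrow(x$scores), " samples, ", nrow(x$loadings),
      " features, ", ncol(x$scores), " components\n", sep = "")
  cat("  explained variance (%):",
      paste(sprintf("%.2f", x$explained_variance), collapse = ", "),
      "| TEV:", sprintf("%.2f", x$tev), "\n")
  invisible(x)
}

#' Consensus multiblock PCA (CPCA-W)
#'
#' Fits a consensus PCA across blocks measured on the same samples. Each
#' block is autoscaled (unless `autoscale = FALSE`) and weighted by
#' `1 / sqrt(n_b)` (`n_b` = number of variables in the block) so no block
#' dominates by dimensionality alone. Components are extracted iteratively:
#' the super score is regressed onto each block to give unit-length block
#' loadings and block scores; the super weights are the normalized
#' regression of the block-score matrix on the super score; the new super
#' score is the block-score matrix times the super weights. After
#' convergence all blocks are deflated by the super score. The resulting
#' super scores equal, up to sign, the PCA scores of the column-wise
#' concatenation of the weighted blocks.
#'
#' @param blocks named list of samples-by-features matrices sharing the
#'   same samples in the same order
#' @param n_components number of consensus components
#' @param autoscale autoscale each block first (default TRUE; set FALSE if
#'   the blocks are already scaled)
#' @param max_iter,tol convergence controls: iteration stops when the
#'   relative change of the super score drops below `tol`
#' @return an object of class `mbpca_model`: `super_scores`,
#'   `super_weights` (blocks x components), `block_scores`,
#'   `block_loadings` (per-block lists), `block_weights` (the `1/sqrt(n_b)`
#'   factors), `explained_variance` and `tev` (percent, of the weighted
#'   concatenated matrix), `block_explained_variance`
#' @export
mbpca_fit <- function(blocks, n_components = 2, autoscale = TRUE,
                      max_iter = 500, tol = 1e-10) {
  stopifnot(is.list(blocks), length(blocks) >= 1)
  if (is.null(names(blocks)) || any(!nzchar(names(blocks))))
    names(blocks) <- paste0("block", seq_along(blocks))
  blocks <- lapply(blocks, unclass_scaled)
  n <- unique(vapply(blocks, nrow, integer(1)))
  if (length(n) != 1)
    stop("all blocks must share the same samples: row counts differ (",
         paste(vapply(blocks, nrow, integer(1)), collapse = ", "), ")")
  rn <- lapply(blocks, rownames)
  if (!all(vapply(rn, is.null, logical(1)))) {
    for (i in seq_along(rn)[-1])
      if (!identical(rn[[i]], rn[[1]]))
        stop("all blocks must share the same samples in the same order ",
             "(rownames differ)")
  }
  if (n_components < 1 || n_components > n - 1)
    stop("n_components must lie in [1, samples - 1]")

  if (autoscale)
    blocks <- lapply(blocks, function(b) unclass_scaled(autoscale(b)))
  else
    blocks <- lapply(blocks, function(b) sweep(b, 2, colMeans(b), `-`))
  w_b <- 1 / sqrt(vapply(blocks, ncol, integer(1)))
  X <- mapply(function(b, w) b * w, blocks, w_b, SIMPLIFY = FALSE)
  total_ss <- sum(vapply(X, function(b) sum(b^2), numeric(1)))
  block_ss <- vapply(X, function(b) sum(b^2), numeric(1))

  nb <- length(X)
  super_scores <- matrix(0, n, n_components)
  super_weights <- matrix(0, nb, n_components,
                          dimnames = list(names(X), NULL))
  block_scores <- lapply(X, function(b) matrix(0, n, n_components))
  block_loadings <- lapply(X, function(b)
    matrix(0, ncol(b), n_components,
           dimnames = list(colnames(b), NULL)))
  ev <- numeric(n_components)
  block_ev <- matrix(0, nb, n_components, dimnames = list(names(X), NULL))

  for (k in seq_len(n_components)) {
    # initialize from the column with the largest sum of squares across
    # the concatenation (deterministic)
    css <- lapply(X, function(b) colSums(b^2))
    bi <- which.max(vapply(css, max, numeric(1)))
    t_s <- X[[bi]][, which.max(css[[bi]])]
    if (sum(t_s^2) == 0)
      stop("CPCA-W failed at component ", k, ": no variance left")
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      p_b <- vector("list", nb)
      T_b <- matrix(0, n, nb)
      for (b in seq_len(nb)) {
        pb <- crossprod(X[[b]], t_s)
        npb <- sqrt(sum(pb^2))
        if (npb == 0) pb[] <- 0 else pb <- pb / npb
        p_b[[b]] <- pb
        T_b[, b] <- X[[b]] %*% pb
      }
      w_s <- crossprod(T_b, t_s)
      w_s <- w_s / sqrt(sum(w_s^2))
      t_new <- T_b %*% w_s
      if (sqrt(sum((t_new - t_s)^2)) / sqrt(sum(t_new^2)) < tol) {
        t_s <- drop(t_new)
        converged <- TRUE
        break
      }
      t_s <- drop(t_new)
    }
    if (!converged)
      stop("CPCA-W did not converge for component ", k, " after ",
           max_iter, " iterations")
    s <- .sign_fix(t_s)
    t_s <- s * t_s
    super_scores[, k] <- t_s
    super_weights[, k] <- s * drop(w_s)
    tt <- sum(t_s^2)
    for (b in seq_len(nb)) {
      block_loadings[[b]][, k] <- s * p_b[[b]]
      block_scores[[b]][, k] <- X[[b]] %*% (s * p_b[[b]])
      # deflation by the super score
      pd <- crossprod(X[[b]], t_s) / tt
      expl <- sum((t_s %*% t(pd))^2)
      block_ev[b, k] <- 100 * expl / block_ss[b]
      X[[b]] <- X[[b]] - t_s %*% t(pd)
    }
    ev[k] <- 100 * sum(vapply(seq_len(nb), function(b)
      block_ss[b] * block_ev[b, k] / 100, numeric(1))) / total_ss
  }
  colnames(super_scores) <- paste0("PC", seq_len(n_components))
  structure(list(super_scores = super_scores,
                 super_weights = super_weights,
                 block_scores = block_scores,
                 block_loadings = block_loadings,
                 block_weights = stats::setNames(w_b, names(blocks)),
                 explained_variance = ev, tev = sum(ev),
                 block_explained_variance = block_ev),
            class = "mbpca_model")
}

#' @export
print.mbpca_model <- function(x, ...) {
  cat("mbpca_model (CPCA-W): ", nrow(x$super_scores), " samples, ",
      length(x$block_weights), " blocks, ", ncol(x$super_scores),
      " components\n", sep = "")
  cat("  block weights (1/sqrt(n)):",
      paste(sprintf("%s=%.4f", names(x$block_weights), x$block_weights),
            collapse = ", "), "\n")
  cat("  explained variance (%):",
      paste(sprintf("%.2f", x$explained_variance), collapse = ", "),
      "| TEV:", sprintf("%.2f", x$tev), "\n")
  invisible(x)
}

# Lean PLS2 NIPALS core on a pre-scaled X and centered Y. Returns the
# weight/loading matrices needed for prediction. Used by plsda_fit and by
# the resampling loops, which cannot afford S3 overhead.
.pls2_nipals <- function(Xs, Yc, n_lv, max_iter = 500, tol = 1e-10) {
  n <- nrow(Xs); p <- ncol(Xs); k <- ncol(Yc)
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  Q <- matrix(0, k, n_lv); Tm <- matrix(0, n, n_lv)
  E <- Xs; F <- Yc
  for (a in seq_len(n_lv)) {
    u <- F[, which.max(colSums(F^2))]
    t_old <- rep(0, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(E, u)
      nw <- sqrt(sum(w^2))
      if (nw == 0) break
      w <- w / nw
      t <- drop(E %*% w)
      tt <- sum(t^2)
      if (tt == 0) break
      q <- crossprod(F, t) / tt
      u <- drop(F %*% q) / sum(q^2)
      if (sqrt(sum((t - t_old)^2)) / sqrt(tt) < tol) break
      t_old <- t
    }
    s <- .sign_fix(w)
    w <- s * w; t <- s * t; q <- s * q
    tt <- sum(t^2)
    p_a <- crossprod(E, t) / tt
    E <- E - tcrossprod(t, p_a)
    F <- F - tcrossprod(t, q)
    W[, a] <- w; P[, a] <- p_a; Q[, a] <- q; Tm[, a] <- t
  }
  B <- W %*% solve(crossprod(P, W), t(Q))
  list(W = W, P = P, Q = Q, scores = Tm, B = B)
}

#' Fit a PLS-DA classifier
#'
#' Class labels are encoded as one indicator column per class; a PLS2 model
#' is fitted by NIPALS between the (auto)scaled feature matrix and the
#' centered indicator matrix. Centering and scaling use the training set
#' only; the stored parameters are applied to any new samples at
#' prediction, so validation splits carry no information leak.
#'
#' @param x numeric matrix, samples x features (raw intensities or a
#'   pre-scaled matrix)
#' @param classes factor (or coercible) of class labels, one per row of `x`
#' @param n_lv number of latent variables (default 2, matching
#'   two-dimensional score plots)
#' @param scale autoscale `x` on the training set (default TRUE); if FALSE
#'   only mean-centering is applied
#' @return an object of class `plsda_model`: `weights`, `loadings`
#'   (X side), `y_loadings`, `coefficients`, `scores`, `levels`,
#'   `x_center`, `x_scale`, `y_means`, `n_lv`
#' @export
plsda_fit <- function(x, classes, n_lv = 2, scale = TRUE) {
  x <- unclass_scaled(x)
  classes <- factor(classes)
  classes <- droplevels(classes)
  if (nlevels(classes) < 2)
    stop("PLS-DA requires at least 2 classes (found ", nlevels(classes), ")")
  if (any(table(classes) < 2))
    stop("every class needs at least 2 samples")
  if (length(classes) != nrow(x))
    stop("length of classes must match rows of x")
  if (n_lv > nrow(x) - 1)
    stop("n_lv must be at most samples - 1")

  ctr <- colMeans(x)
  scl <- if (scale) apply(x, 2, stats::sd) else rep(1, ncol(x))
  scl[scl == 0 | is.na(scl)] <- 1
  Xs <- sweep(sweep(x, 2, ctr, `-`), 2, scl, `/`)
  Y <- stats::model.matrix(~ classes - 1)
  colnames(Y) <- levels(classes)
  y_means <- colMeans(Y)
  Yc <- sweep(Y, 2, y_means, `-`)

  core <- .pls2_nipals(Xs, Yc, n_lv)
  structure(list(weights = core$W, loadings = core$P,
                 y_loadings = core$Q, coefficients = core$B,
                 scores = core$scores, levels = levels(classes),
                 x_center = ctr, x_scale = scl, y_means = y_means,
                 n_lv = n_lv),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat("plsda_model: ", nrow(x$scores), " samples, ",
      length(x$x_center), " features, ", x$n_lv, " latent variables, ",
      "classes: ", paste(x$levels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Predict classes from a fitted PLS-DA model
#'
#' New samples are transformed with the training centering/scaling, the
#' indicator responses predicted, and each sample assigned to the class
#' with the largest predicted indicator. Exact ties go to the first class
#' in the declared level order and are flagged.
#'
#' @param object a [plsda_fit()] model
#' @param newdata numeric matrix, samples x features (training feature
#'   count)
#' @param ... unused
#' @return factor of predicted classes with attributes `"scores"`
#'   (predicted indicator matrix) and `"tie"` (logical vector marking exact
#'   ties)
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  newdata <- unclass_scaled(newdata)
  if (ncol(newdata) != length(object$x_center))
    stop("newdata has ", ncol(newdata), " features; model was trained on ",
         length(object$x_center))
  Xs <- sweep(sweep(newdata, 2, object$x_center, `-`), 2,
              object$x_scale, `/`)
  Yhat <- Xs %*% object$coefficients
  Yhat <- sweep(Yhat, 2, object$y_means, `+`)
  colnames(Yhat) <- object$levels
  idx <- apply(Yhat, 1, which.max)
  tie <- apply(Yhat, 1, function(r) sum(r == max(r)) > 1)
  out <- factor(object$levels[idx], levels = object$levels)
  attr(out, "scores") <- Yhat
  attr(out, "tie") <- tie
  out
}

#' @rdname predict.plsda_model
#' @param model a [plsda_fit()] model
#' @export
plsda_predict <- function(model, newdata) predict(model, newdata)
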