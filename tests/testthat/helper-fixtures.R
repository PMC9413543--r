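# Shared fixtures, built in code at test time.

# A minimal hand-written feature table: nf features, 3 study samples per
# class + n_qc QCs, constant intensities unless a matrix is given.
tiny_table <- function(nf = 3, n_qc = 3, intensities = NULL,
                       rt = NULL, isotope = NULL) {
  classes <- c(rep(c("A", "B", "C"), each = 3), rep("QC", n_qc))
  n <- length(classes)
  samples <- data.frame(
    sample_id = c(sprintf("%s%d", rep(c("A", "B", "C"), each = 3), 1:3),
                  sprintf("QC%d", seq_len(n_qc))),
    class = classes,
    injection_order = seq_len(n),
    stringsAsFactors = FALSE)
  features <- data.frame(
    feature_id = sprintf("F%03d", seq_len(nf)),
    mz = round(seq(100.1234, by = 50, length.out = nf), 4),
    rt = if (is.null(rt)) rep(5, nf) else rt,
    isotope = if (is.null(isotope)) rep("", nf) else isotope,
    stringsAsFactors = FALSE)
  if (is.null(intensities))
    intensities <- matrix(1000, nf, n)
  feature_table(features, intensities, samples)
}

# Three-class Gaussian matrix with class mean shifts along `direction`
# columns; used by classifier tests.
gaussian_classes <- function(n_per = 12, p = 30, shift = 3, seed = 1) {
  set.seed(seed)
  cls <- factor(rep(c("A", "B", "C"), each = n_per))
  x <- matrix(rnorm(3 * n_per * p), 3 * n_per, p)
  x[cls == "B", ] <- x[cls == "B", ] + shift
  x[cls == "C", ] <- x[cls == "C", ] + 2 * shift
  list(x = x, classes = cls)
}

# Hand-rolled Benjamini-Hochberg adjustment (independent of p.adjust).
bh_by_hand <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Hand-rolled Kruskal-Wallis H with tie correction (independent of
# kruskal.test).
kw_by_hand <- function(values, classes) {
  r <- rank(values)
  N <- length(values)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, classes, function(z) length(z) * mean(z)^2)) -
    3 * (N + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Hand-rolled Pearson correlation.
pearson_by_hand <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}
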