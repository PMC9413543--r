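#' Describe a synthetic two-block plasma metabolomics study
#'
#' Parameters mirror the structure of a three-group (newborn/infant/child)
#' plasma study profiled in positive and negative electrospray ionization
#' modes, with pooled QC samples injected at the start of the run and then
#' after every `qc_interval` randomized study samples.
#'
#' @param n_per_group study samples per class (3 classes A, B, C)
#' @param qc_interval study injections between successive QCs
#' @param n_features_pos,n_features_neg base features per block (isotope
#'   companion rows are added on top, see `isotope_fraction`)
#' @param n_significant spiked group-discriminating features per block
#' @param effect_size standardized mean shift between adjacent classes, in
#'   units of the log-intensity noise SD
#' @param drift_magnitude fractional intensity loss across the injection
#'   sequence, in `[0, 1)`
#' @param noise_cv coefficient of variation of the multiplicative
#'   (log-normal) measurement noise
#' @param n_cross_pairs count of cross-mode correlated, co-eluting feature
#'   pairs among the spiked features
#' @param isotope_fraction fraction of base features that receive an
#'   `[M+1]` isotope companion row at m/z + 1.0034
#' @param high_rsd_fraction fraction of null features given inflated noise
#'   (`high_rsd_cv`) so they fail the QC %RSD filter
#' @param high_rsd_cv noise CV of the inflated-noise features
#' @param coelution_tol maximum |RT difference| (minutes) between the two
#'   members of a cross-mode pair
#' @param seed root integer seed; all randomness derives from it
#' @return an object of class `study_design`
#' @export
study_design <- function(n_per_group = 12, qc_interval = 6,
                         n_features_pos = 2000, n_features_neg = 1855,
                         n_significant = 50, effect_size = 2,
                         drift_magnitude = 0.3, noise_cv = 0.1,
                         n_cross_pairs = 10, isotope_fraction = 0.08,
                         high_rsd_fraction = 0.05, high_rsd_cv = 0.35,
                         coelution_tol = 0.02, seed = 1) {
  d <- list(n_per_group = n_per_group, qc_interval = qc_interval,
            n_features_pos = n_features_pos, n_features_neg = n_features_neg,
            n_significant = n_significant, effect_size = effect_size,
            drift_magnitude = drift_magnitude, noise_cv = noise_cv,
            n_cross_pairs = n_cross_pairs,
            isotope_fraction = isotope_fraction,
            high_rsd_fraction = high_rsd_fraction,
            high_rsd_cv = high_rsd_cv,
            coelution_tol = coelution_tol, seed = as.integer(seed))
  for (f in c("n_per_group", "qc_interval", "n_features_pos",
              "n_features_neg"))
    if (length(d[[f]]) != 1 || d[[f]] < 1 || d[[f]] != round(d[[f]]))
      stop("invalid study design: '", f, "' must be a positive integer")
  if (d$n_significant < 0 || d$n_significant != round(d$n_significant))
    stop("invalid study design: 'n_significant' must be a non-negative ",
         "integer")
  if (d$n_significant > min(d$n_features_pos, d$n_features_neg))
    stop("invalid study design: 'n_significant' exceeds the feature count ",
         "of a block")
  if (d$noise_cv < 0)
    stop("invalid study design: 'noise_cv' must be >= 0")
  if (d$drift_magnitude < 0 || d$drift_magnitude >= 1)
    stop("invalid study design: 'drift_magnitude' must lie in [0, 1)")
  if (d$n_cross_pairs < 0 || d$n_cross_pairs > d$n_significant)
    stop("invalid study design: 'n_cross_pairs' must lie in ",
         "[0, n_significant]")
  for (f in c("isotope_fraction", "high_rsd_fraction"))
    if (d[[f]] < 0 || d[[f]] > 1)
      stop("invalid study design: '", f, "' must lie in [0, 1]")
  if (d$effect_size < 0)
    stop("invalid study design: 'effect_size' must be >= 0")
  class(d) <- "study_design"
  d
}

#' A compact, strongly separated study design
#'
#' The scenario used throughout the validation examples: three classes of 12
#' samples, adjacent-class effect size 3 (log-noise SD units), modest block
#' sizes so that resampling-heavy validation runs in minutes on one core.
#'
#' @param seed root seed
#' @param ... overrides passed on to [study_design()]
#' @return a `study_design`
#' @export
strong_separation_design <- function(seed = 1, ...) {
  defaults <- list(n_features_pos = 300, n_features_neg = 250,
                   n_significant = 30, effect_size = 3, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(study_design, args)
}

# Deterministic sub-seed derivation: the root seed yields one integer
# sub-stream seed per generation phase, so e.g. changing the positive
# block's size does not perturb the negative block's draws.
.sub_seeds <- function(seed, n = 6) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Smooth monotone exponential-decay multiplier: 1 at the first injection,
# (1 - magnitude) at the last.
.drift_multiplier <- function(order, n_total, magnitude) {
  if (magnitude == 0 || n_total <= 1) return(rep(1, length(order)))
  (1 - magnitude)^((order - 1) / (n_total - 1))
}

#' Apply monotone injection-order intensity drift
#'
#' Multiplies every intensity by a smooth exponential-decay curve of
#' injection order that runs from 1 (first injection) down to
#' `1 - drift_magnitude` (last injection). This is the instrumental
#' intensity drop that QC-based drift correction must remove.
#'
#' @param x a [feature_table()] with injection orders assigned
#' @param drift_magnitude fractional loss over the run, in `[0, 1)`
#' @return the drifted `feature_table`
#' @export
apply_drift <- function(x, drift_magnitude) {
  stopifnot(inherits(x, "feature_table"))
  if (drift_magnitude < 0 || drift_magnitude >= 1)
    stop("drift_magnitude must lie in [0, 1)")
  n_total <- max(x$samples$injection_order)
  mult <- .drift_multiplier(x$samples$injection_order, n_total,
                            drift_magnitude)
  x$intensities <- sweep(x$intensities, 2, mult, `*`)
  x
}

# Build the randomized injection sequence: QC first (equilibration), then a
# QC after every `qc_interval` study samples.
.injection_layout <- function(classes, sample_ids, qc_interval) {
  n <- length(sample_ids)
  study_order <- sample.int(n)   # randomization of study samples
  ids <- character(0); cls <- character(0)
  qc_i <- 1L
  add_qc <- function() {
    ids <<- c(ids, sprintf("QC%02d", qc_i)); cls <<- c(cls, "QC")
    qc_i <<- qc_i + 1L
  }
  add_qc()
  for (i in seq_len(n)) {
    ids <- c(ids, sample_ids[study_order[i]])
    cls <- c(cls, classes[study_order[i]])
    if (i %% qc_interval == 0) add_qc()
  }
  data.frame(sample_id = ids, class = cls,
             injection_order = seq_along(ids), stringsAsFactors = FALSE)
}

# Per-class multiplicative shifts in log space for one spiked feature.
# Patterns (delta = effect_size * log-noise SD):
#   Up:    A < B < C          -> (0, 1, 2) * delta
#   Down:  A > B > C          -> (2, 1, 0) * delta
#   Other: B above A and C    -> (0, 2, 1) * delta   (A < C < B)
.trend_shift <- function(trend, delta) {
  switch(trend,
         Up    = c(A = 0, B = 1, C = 2) * delta,
         Down  = c(A = 2, B = 1, C = 0) * delta,
         Other = c(A = 0, B = 2, C = 1) * delta)
}

# Generate one block. `shared_noise` is an optional list(feature index ->
# per-study-sample standard normal vector) used to correlate cross-mode
# pairs; QCs always get independent noise.
.generate_block <- function(prefix, n_feat, design, layout, seed,
                            trends, sig_idx, shared_noise = NULL,
                            rt_fixed = NULL) {
  set.seed(seed)
  n_samp <- nrow(layout)
  is_qc <- layout$class == "QC"
  sdlog <- sqrt(log(1 + design$noise_cv^2))
  delta <- design$effect_size * sdlog

  mz <- round(stats::runif(n_feat, 100, 1000), 4)
  rt <- round(stats::runif(n_feat, 0.3, 13.2), 2)
  if (!is.null(rt_fixed))
    rt[sig_idx[seq_along(rt_fixed)]] <- rt_fixed
  base_log10 <- stats::runif(n_feat, 4, 6)
  baseline <- 10^base_log10

  # inflated-noise features drawn from the null set
  null_idx <- setdiff(seq_len(n_feat), sig_idx)
  n_high <- floor(design$high_rsd_fraction * n_feat)
  high_idx <- if (n_high > 0 && length(null_idx) > 0)
    sample(null_idx, min(n_high, length(null_idx))) else integer(0)
  feat_sdlog <- rep(sdlog, n_feat)
  feat_sdlog[high_idx] <- sqrt(log(1 + design$high_rsd_cv^2))

  # expected intensity per feature x sample (before noise/drift)
  shift <- matrix(0, n_feat, n_samp)
  for (j in seq_along(sig_idx)) {
    s <- .trend_shift(trends[j], delta)
    shift[sig_idx[j], !is_qc] <- s[layout$class[!is_qc]]
  }
  expected <- baseline * exp(shift)
  # pooled QC: expected value = mean over all study samples
  qc_expected <- rowMeans(expected[, !is_qc, drop = FALSE])
  expected[, is_qc] <- qc_expected

  # multiplicative log-normal noise, mean-one correction so the empirical
  # CV of QC replicates matches noise_cv
  z <- matrix(stats::rnorm(n_feat * n_samp), n_feat, n_samp)
  if (!is.null(shared_noise)) {
    rho <- 0.25  # independent-noise fraction; shared-factor r ~ 1/(1+rho^2)
    study_cols <- which(!is_qc)
    for (fi in names(shared_noise)) {
      i <- as.integer(fi)
      z[i, study_cols] <- (shared_noise[[fi]] + rho * z[i, study_cols]) /
        sqrt(1 + rho^2)
    }
  }
  noise <- exp(z * feat_sdlog - feat_sdlog^2 / 2)
  intens <- expected * noise

  features <- data.frame(
    feature_id = sprintf("%s%04d", prefix, seq_len(n_feat)),
    mz = mz, rt = rt, isotope = "", stringsAsFactors = FALSE)

  # [M+1] isotope companions: duplicated rows at m/z + 1.0034 with a fixed
  # abundance ratio, perfectly correlated with the parent
  n_iso <- floor(design$isotope_fraction * n_feat)
  if (n_iso > 0) {
    iso_parent <- sample(seq_len(n_feat), n_iso)
    iso_feat <- data.frame(
      feature_id = sprintf("%sI%04d", prefix, seq_len(n_iso)),
      mz = round(mz[iso_parent] + 1.0034, 4),
      rt = rt[iso_parent], isotope = "[M+1]", stringsAsFactors = FALSE)
    features <- rbind(features, iso_feat)
    intens <- rbind(intens, 0.25 * intens[iso_parent, , drop = FALSE])
  }

  feature_table(features, intens, layout)
}

#' Generate a synthetic two-block study with ground truth
#'
#' Produces one positive-mode and one negative-mode feature table for the
#' same injection sequence: randomized study samples, pooled QCs (expected
#' intensity equal to the mean over study samples) injected first and then
#' after every `qc_interval` study samples, spiked group effects with
#' Up/Down/Other patterns, correlated co-eluting cross-mode pairs, `[M+1]`
#' isotope companions, inflated-noise features, and a monotone
#' injection-order intensity drift. Deterministic given `design$seed`.
#'
#' @param design a [study_design()]
#' @return a list with elements `pos` and `neg` ([feature_table()]s) and
#'   `truth`, a `ground_truth` list holding per-block spiked feature ids
#'   with trend classes, cross-mode pair ids, and the drift curve
#'   (multiplier per injection order).
#' @export
generate_study <- function(design) {
  if (!inherits(design, "study_design"))
    design <- do.call(study_design, as.list(design))
  seeds <- .sub_seeds(design$seed, 6)

  n_study <- 3 * design$n_per_group
  classes <- rep(c("A", "B", "C"), each = design$n_per_group)
  sample_ids <- sprintf("%s%02d", classes, rep(seq_len(design$n_per_group), 3))

  set.seed(seeds[1])
  layout <- .injection_layout(classes, sample_ids, design$qc_interval)

  # spiked features, trends and cross-pair structure are drawn once so both
  # blocks agree on which pairs are linked
  set.seed(seeds[2])
  n_sig <- design$n_significant
  trend_pool <- c("Up", "Down", "Other")
  trends_pos <- sample(trend_pool, n_sig, replace = TRUE,
                       prob = c(0.4, 0.4, 0.2))
  trends_neg <- sample(trend_pool, n_sig, replace = TRUE,
                       prob = c(0.4, 0.4, 0.2))
  sig_pos <- sort(sample(seq_len(design$n_features_pos), n_sig))
  sig_neg <- sort(sample(seq_len(design$n_features_neg), n_sig))
  n_pair <- design$n_cross_pairs
  pair_pos <- if (n_pair > 0) sig_pos[seq_len(n_pair)] else integer(0)
  pair_neg <- if (n_pair > 0) sig_neg[seq_len(n_pair)] else integer(0)
  if (n_pair > 0)  # linked pairs share the trend of the positive member
    trends_neg[seq_len(n_pair)] <- trends_pos[seq_len(n_pair)]
  # shared per-study-sample latent noise for the linked pairs
  shared <- lapply(seq_len(n_pair), function(i) stats::rnorm(n_study))
  shared_pos <- stats::setNames(shared, as.character(pair_pos))
  shared_neg <- stats::setNames(shared, as.character(pair_neg))
  # co-elution: pair members share RT up to a jitter within tolerance
  pair_rt <- round(stats::runif(n_pair, 1.5, 13), 2)
  rt_jit <- round(stats::runif(n_pair, -design$coelution_tol / 2,
                               design$coelution_tol / 2), 2)

  rt_pos_fixed <- rt_neg_fixed <- NULL
  if (n_pair > 0) {
    rt_pos_fixed <- pair_rt
    rt_neg_fixed <- pair_rt + rt_jit
  }

  pos <- .generate_block("P", design$n_features_pos, design, layout,
                         seeds[3], trends_pos, sig_pos, shared_pos,
                         rt_pos_fixed)
  neg <- .generate_block("N", design$n_features_neg, design, layout,
                         seeds[4], trends_neg, sig_neg, shared_neg,
                         rt_neg_fixed)

  if (design$drift_magnitude > 0) {
    pos <- apply_drift(pos, design$drift_magnitude)
    neg <- apply_drift(neg, design$drift_magnitude)
  }

  orders <- sort(layout$injection_order)
  truth <- structure(list(
    significant = list(
      pos = data.frame(feature_id = pos$features$feature_id[sig_pos],
                       trend = trends_pos, stringsAsFactors = FALSE),
      neg = data.frame(feature_id = neg$features$feature_id[sig_neg],
                       trend = trends_neg, stringsAsFactors = FALSE)),
    cross_pairs = data.frame(
      pos_id = pos$features$feature_id[pair_pos],
      neg_id = neg$features$feature_id[pair_neg],
      stringsAsFactors = FALSE),
    drift_curve = data.frame(
      injection_order = orders,
      multiplier = .drift_multiplier(orders, max(orders),
                                     design$drift_magnitude)),
    design = design
  ), class = "ground_truth")

  list(pos = pos, neg = neg, truth = truth)
}

#' Write ground truth as a structured-text sidecar
#' @param truth a `ground_truth` object from [generate_study()]
#' @param path output JSON path
#' @return invisibly, `path`
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  out <- unclass(truth)
  out$design <- unclass(out$design)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
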