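#' Assemble a pipeline configuration
#'
#' One flat list of every threshold and count the pipeline uses, with the
#' documented defaults. Values given here override the defaults; the
#' configuration round-trips through JSON ([jsonlite]) so runs are
#' reproducible from the written log.
#'
#' @param ... overrides of the default fields (unknown names are an error)
#' @return a named list of class `pipeline_config`
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    # filtering
    min_rt = 1.0, max_qc_rsd = 20.0, drop_isotopes = TRUE,
    # scaling for classical PCA: autoscale for the positive block, log10
    # for the negative block; multiblock PCA always autoscales
    scaling_pos = "autoscale", scaling_neg = "log10",
    # model sizes
    n_components = 2L, n_lv = 2L,
    # resampling
    n_boot = 1000L, n_perm = 1000L, n_boot_inner = 100L,
    # univariate cascade
    q_threshold = 0.001, tukey_alpha = 0.05, lilliefors_alpha = 0.05,
    kw_threshold = 0.001,
    # annotation
    r_threshold = 0.8, rt_window = 0.1, ppm_tolerance = 5
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, overrides)
  if (cfg$q_threshold <= 0 || cfg$q_threshold > 1 ||
      cfg$tukey_alpha <= 0 || cfg$tukey_alpha > 1 ||
      cfg$lilliefors_alpha <= 0 || cfg$lilliefors_alpha > 1 ||
      cfg$kw_threshold <= 0 || cfg$kw_threshold > 1)
    stop("significance thresholds must lie in (0, 1]")
  if (cfg$r_threshold < -1 || cfg$r_threshold > 1)
    stop("r_threshold must lie in [-1, 1]")
  if (cfg$rt_window < 0) stop("rt_window must be >= 0")
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Run the full two-block analysis pipeline
#'
#' Orchestrates every stage on a pair of feature tables: matrix filtering,
#' QC drift correction, classical PCA per block, multiblock CPCA-W across
#' blocks, PLS-DA with bootstrap out-of-bag validation and permutation
#' testing (positive block), the univariate significance cascade per
#' block, and cross-mode correlation pairing of the significant features.
#' When `out_dir` is given, every result is written there as delimited
#' text together with a JSON run log recording the seed, configuration
#' and stage counts; two runs with identical inputs and configuration are
#' numerically identical.
#'
#' @param pos,neg [feature_table()]s for the two ionization modes, or
#'   `NULL` to simulate a study from `design`
#' @param design a [study_design()] used when `pos`/`neg` are `NULL`
#' @param config a [pipeline_config()]
#' @param out_dir output directory, or `NULL` to skip writing
#' @return invisibly, a list with `filtered`, `filter_reports`, `pca`,
#'   `mbpca`, `validation`, `cascade`, `pairs`, `truth` (when simulated),
#'   `config`
#' @export
run_pipeline <- function(pos = NULL, neg = NULL, design = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  truth <- NULL
  if (is.null(pos) || is.null(neg)) {
    if (is.null(design)) design <- study_design(seed = config$seed)
    sim <- generate_study(design)
    pos <- sim$pos; neg <- sim$neg; truth <- sim$truth
  }

  rules <- filter_rules(min_rt = config$min_rt,
                        max_qc_rsd = config$max_qc_rsd,
                        drop_isotopes = config$drop_isotopes)
  fp <- filter_features(pos, rules, block = "ESI+")
  fn <- filter_features(neg, rules, block = "ESI-")
  if (n_features(fp$table) == 0 || n_features(fn$table) == 0)
    stop("matrix filtering removed every feature of a block; ",
         "downstream analysis refused (check max_qc_rsd/min_rt)")

  cp <- qc_drift_correct(fp$table)
  cn <- qc_drift_correct(fn$table)

  scale_block <- function(m, how) switch(
    how,
    autoscale = autoscale(m),
    log10 = log10_scale(m, offset = if (any(m == 0)) "auto" else 0),
    none = structure(m, class = c("scaled_matrix", "matrix", "array")),
    stop("unknown scaling: ", how))
  mp <- intensity_matrix(cp, "study")
  mn <- intensity_matrix(cn, "study")
  classes <- study_classes(cp)

  pca <- list(
    pos = pca_fit(scale_block(mp, config$scaling_pos),
                  config$n_components),
    neg = pca_fit(scale_block(mn, config$scaling_neg),
                  config$n_components))
  mb <- mbpca_fit(list(`ESI+` = mp, `ESI-` = mn),
                  n_components = config$n_components)

  val <- permutation_test(mp, classes, n_perm = config$n_perm,
                          n_boot_inner = config$n_boot_inner,
                          n_lv = config$n_lv,
                          n_boot_observed = config$n_boot)

  casc <- list(
    pos = significance_cascade(cp, q_threshold = config$q_threshold,
                               tukey_alpha = config$tukey_alpha,
                               lilliefors_alpha = config$lilliefors_alpha,
                               kw_threshold = config$kw_threshold,
                               block = "ESI+"),
    neg = significance_cascade(cn, q_threshold = config$q_threshold,
                               tukey_alpha = config$tukey_alpha,
                               lilliefors_alpha = config$lilliefors_alpha,
                               kw_threshold = config$kw_threshold,
                               block = "ESI-"))

  sig_pos <- casc$pos$features$feature_id[casc$pos$features$significant]
  sig_neg <- casc$neg$features$feature_id[casc$neg$features$significant]
  pairs <- cross_mode_pairs(cp, cn,
                            list(pos = sig_pos, neg = sig_neg),
                            r_threshold = config$r_threshold,
                            rt_window = config$rt_window)

  result <- list(filtered = list(pos = cp, neg = cn),
                 filter_reports = list(pos = fp$report, neg = fn$report),
                 pca = pca, mbpca = mb, validation = val,
                 cascade = casc, pairs = pairs, truth = truth,
                 config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(...) file.path(out_dir, paste0(...))
    write_feature_table(cp, p("filtered_pos.tsv"), p("samples.tsv"))
    write_feature_table(cn, p("filtered_neg.tsv"), p("samples_neg.tsv"))
    write_stage_report(fp$report, p("filter_report_pos.tsv"))
    write_stage_report(fn$report, p("filter_report_neg.tsv"))
    write_stage_report(casc$pos$report, p("cascade_report_pos.tsv"))
    write_stage_report(casc$neg$report, p("cascade_report_neg.tsv"))
    write_univariate_result(casc$pos, p("univariate_pos.tsv"))
    write_univariate_result(casc$neg, p("univariate_neg.tsv"))
    write_validation_result(val, file.path(out_dir, "validation"))
    utils::write.table(as.data.frame(pairs), p("cross_mode_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = rownames(mb$super_scores) %||%
                   seq_len(nrow(mb$super_scores)),
                 class = as.character(classes),
                 round(mb$super_scores, 6)),
      p("mbpca_super_scores.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    if (!is.null(truth)) write_ground_truth(truth, p("ground_truth.json"))
    log <- list(package = "mbmetab",
                version = as.character(utils::packageVersion("mbmetab")),
                seed = config$seed,
                config = unclass(config),
                stage_counts = list(
                  filter_pos = fp$report$counts,
                  filter_neg = fn$report$counts,
                  cascade_pos = casc$pos$report$counts,
                  cascade_neg = casc$neg$report$counts),
                ccr = val$observed_ccr, p_value = val$p_value)
    jsonlite::write_json(log, p("run_log.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(result)
}
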