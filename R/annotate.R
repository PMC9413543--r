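# IUPAC monoisotopic masses (Da) of the elements handled by the mass
# calculator, plus the electron mass.
.ELEMENT_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163,
  S = 31.97207100,
  Na = 22.9897692809,
  K = 38.96370668,
  Cl = 34.96885268
)
.ELECTRON_MASS <- 0.000548579909

#' Parse a molecular formula string
#'
#' Accepts Hill-style strings such as `"C28H50NO7P"`. Element symbols are
#' one capital letter optionally followed by a lowercase letter; a missing
#' count means 1.
#'
#' @param formula character scalar
#' @return named integer vector of element counts
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1)
  s <- gsub("\\s", "", formula)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (!length(toks) || sum(attr(m, "match.length")) != nchar(s))
    stop("cannot parse formula: '", formula, "'")
  el <- sub("[0-9]*$", "", toks)
  ct <- sub("^[A-Za-z]+", "", toks)
  ct <- ifelse(ct == "", 1L, as.integer(ct))
  counts <- tapply(ct, el, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of the IUPAC monoisotopic element masses, adjusted for charge by
#' the electron mass (a +1 ion is lighter by one electron). For a charged
#' species the returned value is the m/z (|z| = `abs(charge)` assumed 1
#' unless stated).
#'
#' @param formula formula string (see [parse_formula()]) or named count
#'   vector
#' @param charge integer charge (default 0, a neutral molecule)
#' @return mass in Da (neutral) or m/z in Th (charged)
#' @export
monoisotopic_mass <- function(formula, charge = 0) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  unknown <- setdiff(names(counts), names(.ELEMENT_MASS))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  if (any(counts < 0)) stop("element counts must be non-negative")
  m <- sum(.ELEMENT_MASS[names(counts)] * counts) -
    charge * .ELECTRON_MASS
  if (charge != 0) m / abs(charge) else m
}

#' The adduct registry
#'
#' Mass deltas (Da, electron mass included) and charge signs of the
#' adducts formed by lyso-glycerophospholipids in electrospray: `[M+H]+`,
#' `[M+Na]+`, `[M-H]-` and the formate adduct `[M+COOH]-`. All deltas are
#' computed from the element masses at load time, so they match IUPAC
#' monoisotopic arithmetic exactly.
#'
#' @return data.frame with columns `name`, `delta` (Da), `charge`
#' @export
adduct_registry <- function() {
  H <- .ELEMENT_MASS[["H"]]; Na <- .ELEMENT_MASS[["Na"]]
  C <- .ELEMENT_MASS[["C"]]; O <- .ELEMENT_MASS[["O"]]
  e <- .ELECTRON_MASS
  data.frame(
    name = c("[M+H]+", "[M+Na]+", "[M-H]-", "[M+COOH]-"),
    delta = c(H - e, Na - e, -(H - e), C + H + 2 * O + e),
    charge = c(1L, 1L, -1L, -1L),
    stringsAsFactors = FALSE
  )
}

#' m/z of an adduct of a neutral molecule
#'
#' @param neutral_mass neutral monoisotopic mass in Da (> 0)
#' @param adduct adduct name registered in [adduct_registry()]
#' @return m/z in Th
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  if (any(neutral_mass <= 0)) stop("neutral mass must be positive")
  reg <- adduct_registry()
  i <- match(adduct, reg$name)
  if (anyNA(i))
    stop("unregistered adduct: ", paste(adduct[is.na(i)], collapse = ", "),
         " (known: ", paste(reg$name, collapse = ", "), ")")
  neutral_mass + reg$delta[i]
}

#' Parts-per-million mass error
#'
#' `ppm = 1e6 * (observed - theoretical) / theoretical`, signed; take
#' `abs()` for the magnitude reported against a tolerance.
#'
#' @param observed observed m/z (Th)
#' @param theoretical theoretical m/z (Th)
#' @return signed ppm error
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(observed <= 0) || any(theoretical <= 0))
    stop("masses must be positive")
  1e6 * (observed - theoretical) / theoretical
}

#' Molecular formula of a lyso-glycerophospholipid
#'
#' Expands the `C:D` shorthand (acyl carbons : double bonds) of the two
#' lyso classes handled here: lysophosphatidylcholine (LPC, glycerophospho-
#' choline backbone C8H20NO6P plus the fatty acyl) and lysophosphatidyl-
#' ethanolamine (LPE, backbone C5H14NO6P). The closed forms are
#' `LPC C:D = C(8+C) H(2C-2D+18) N O7 P` and
#' `LPE C:D = C(5+C) H(2C-2D+12) N O7 P`.
#'
#' @param class `"LPC"` or `"LPE"`
#' @param carbons acyl chain carbons (C)
#' @param double_bonds acyl double bonds (D)
#' @return formula string, e.g. `"C28H50NO7P"` for LPC(20:4)
#' @export
lyso_gpl_formula <- function(class = c("LPC", "LPE"), carbons,
                             double_bonds) {
  class <- match.arg(class)
  stopifnot(carbons >= 2, double_bonds >= 0)
  c_n <- carbons + if (class == "LPC") 8L else 5L
  h_n <- 2L * carbons - 2L * double_bonds + if (class == "LPC") 18L else 12L
  if (h_n <= 0) stop("double bond count too large for the chain length")
  sprintf("C%dH%dNO7P", c_n, h_n)
}

#' Co-elution window from system suitability test retention times
#'
#' The window for declaring that two features elute at the same retention
#' time is twice the maximum RT variability observed across replicate
#' injections of the SST compounds. Variability per compound is the range
#' (max - min; default) or, behind a flag, the standard deviation.
#'
#' @param sst data.frame with columns `compound` and `rt` (minutes), one
#'   row per injection; every compound needs >= 2 injections
#' @param method `"range"` (default) or `"sd"`
#' @return window in minutes
#' @export
rt_window_from_sst <- function(sst, method = c("range", "sd")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(sst), all(c("compound", "rt") %in% names(sst)))
  n_inj <- table(sst$compound)
  if (any(n_inj < 2))
    stop("every SST compound needs at least 2 injections; offending: ",
         paste(names(n_inj)[n_inj < 2], collapse = ", "))
  spread <- tapply(sst$rt, sst$compound, function(r)
    if (method == "range") diff(range(r)) else stats::sd(r))
  2 * max(spread)
}

#' Cross-ionization-mode feature pairing
#'
#' For each candidate feature, finds the features of the opposite block
#' whose per-sample intensity profiles correlate (Pearson r above
#' `r_threshold`, computed on the autoscaled study-sample matrix; QCs are
#' excluded) -- reporting every such partner, since one feature can pair
#' with several (adducts, isotopes, in-source fragments of the same
#' metabolite). The `passes` flag additionally requires co-elution:
#' |RT difference| at most `rt_window`.
#'
#' @param pos,neg [feature_table()]s sharing the same study samples
#' @param candidates list with character elements `pos` and/or `neg`
#'   naming candidate feature ids (typically the significant features), or
#'   a character vector of ids drawn from either block
#' @param r_threshold Pearson correlation gate (default 0.8)
#' @param rt_window co-elution gate in minutes (from
#'   [rt_window_from_sst()] or chosen directly)
#' @return data.frame of class `correlation_pairs`: `pos_id`, `neg_id`,
#'   `r`, `delta_rt`, `passes` -- one row per candidate/partner
#'   combination with `r > r_threshold`, `passes` marking those also
#'   within the RT window
#' @export
cross_mode_pairs <- function(pos, neg, candidates, r_threshold = 0.8,
                             rt_window = 0.1) {
  stopifnot(inherits(pos, "feature_table"), inherits(neg, "feature_table"))
  ps <- pos$samples$sample_id[pos$samples$class != "QC"]
  ns <- neg$samples$sample_id[neg$samples$class != "QC"]
  shared <- intersect(ps, ns)
  if (!length(shared))
    stop("the two blocks share no study samples")
  if (is.character(candidates))
    candidates <- list(pos = intersect(candidates,
                                       pos$features$feature_id),
                       neg = intersect(candidates,
                                       neg$features$feature_id))
  mp <- unclass_scaled(autoscale(
    t(pos$intensities[, shared, drop = FALSE])))
  mn <- unclass_scaled(autoscale(
    t(neg$intensities[, shared, drop = FALSE])))
  r_all <- stats::cor(mp, mn)   # pos features x neg features

  rt_p <- stats::setNames(pos$features$rt, pos$features$feature_id)
  rt_n <- stats::setNames(neg$features$rt, neg$features$feature_id)
  rows <- list()
  add_rows <- function(pid, nid) {
    r <- r_all[pid, nid]
    keep <- !is.na(r) & r > r_threshold
    if (!any(keep)) return(NULL)
    nid <- nid[keep]; r <- r[keep]
    drt <- rt_p[pid] - rt_n[nid]
    data.frame(pos_id = pid, neg_id = nid, r = unname(r),
               delta_rt = unname(drt),
               passes = abs(drt) <= rt_window,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  for (pid in candidates$pos %||% character(0))
    rows[[length(rows) + 1]] <- add_rows(pid, colnames(r_all))
  for (nid in candidates$neg %||% character(0)) {
    r <- r_all[, nid]
    keep <- !is.na(r) & r > r_threshold
    if (!any(keep)) next
    pid <- rownames(r_all)[keep]
    drt <- rt_p[pid] - rt_n[nid]
    rows[[length(rows) + 1]] <- data.frame(
      pos_id = pid, neg_id = nid, r = unname(r[keep]),
      delta_rt = unname(drt), passes = abs(drt) <= rt_window,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(pos_id = character(0), neg_id = character(0),
               r = numeric(0), delta_rt = numeric(0),
               passes = logical(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("correlation_pairs", "data.frame")
  out
}

#' Diagnostic fragment rules
#'
#' The rule table used by [fragment_class_hints()], shipped as an editable
#' TSV (`inst/extdata/fragment_rules.tsv`). Each rule is either a
#' `fragment` (an m/z expected among the MS/MS peaks) or a `neutral_loss`
#' (a precursor-minus-fragment difference). Values are theoretical
#' monoisotopic; the matching tolerance is loose enough (default 20 ppm or
#' 0.005 Th, whichever is larger) to absorb the routine calibration-level
#' deviation of measured fragments.
#'
#' @return data.frame with columns `type`, `mz`, `class`, `note`
#' @export
fragment_rules <- function() {
  path <- system.file("extdata", "fragment_rules.tsv", package = "mbmetab")
  if (nzchar(path))
    return(utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, quote = ""))
  # fallback when running from a source checkout
  data.frame(
    type = c("fragment", "fragment", "neutral_loss", "neutral_loss"),
    mz = c(184.0733, 85.0268, 141.0191, 60.0211),
    class = c("phosphocholine head group (LPC/PC)", "acylcarnitine",
              "LPE (phosphoethanolamine loss)",
              "formate-adduct LPC (methyl formate loss)"),
    note = c("protonated phosphocholine C5H15NO4P",
             "acylcarnitine diagnostic fragment",
             "loss of phosphoethanolamine",
             "loss of methyl formate from [M+COOH]-"),
    stringsAsFactors = FALSE)
}

#' Lipid-class hints from an MS/MS peak list
#'
#' Matches the diagnostic fragment rules against a peak list: `fragment`
#' rules against the peak m/z values directly, `neutral_loss` rules
#' against `precursor_mz - peak m/z` (skipped when no precursor is given).
#' A peak matches within `max(tol_ppm, tol_mz)` of the rule value.
#'
#' For neutral-loss rules the tolerance is evaluated on the precursor m/z
#' scale (a measured loss inherits the absolute error of two m/z
#' measurements, each of order precursor x tol_ppm), not on the loss
#' itself.
#'
#' @param peaks data.frame with columns `mz` and `intensity` (intensity
#'   may be missing), or a numeric vector of m/z values
#' @param precursor_mz precursor m/z, required for neutral-loss rules
#' @param tol_ppm relative tolerance (default 20 ppm)
#' @param tol_mz absolute tolerance floor (default 0.005 Th)
#' @param rules rule table (default [fragment_rules()])
#' @return data.frame with one row per matched rule: `class`, `type`,
#'   `rule_mz`, `matched_mz`, `delta_mz`; zero rows when nothing matches
#' @export
fragment_class_hints <- function(peaks, precursor_mz = NULL,
                                 tol_ppm = 20, tol_mz = 0.005,
                                 rules = fragment_rules()) {
  if (is.numeric(peaks)) peaks <- data.frame(mz = peaks)
  stopifnot(is.data.frame(peaks), "mz" %in% names(peaks))
  empty <- data.frame(class = character(0), type = character(0),
                      rule_mz = numeric(0), matched_mz = numeric(0),
                      delta_mz = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(peaks)) return(empty)
  tol_of <- function(mz) pmax(tol_ppm * 1e-6 * mz, tol_mz)
  hits <- list()
  for (i in seq_len(nrow(rules))) {
    rule <- rules[i, ]
    if (rule$type == "fragment") {
      d <- abs(peaks$mz - rule$mz)
      j <- which(d <= tol_of(rule$mz))
      if (length(j)) {
        j <- j[which.min(d[j])]
        hits[[length(hits) + 1]] <- data.frame(
          class = rule$class, type = rule$type, rule_mz = rule$mz,
          matched_mz = peaks$mz[j], delta_mz = peaks$mz[j] - rule$mz,
          stringsAsFactors = FALSE)
      }
    } else if (rule$type == "neutral_loss" && !is.null(precursor_mz)) {
      loss <- precursor_mz - peaks$mz
      d <- abs(loss - rule$mz)
      j <- which(d <= tol_of(precursor_mz))
      if (length(j)) {
        j <- j[which.min(d[j])]
        hits[[length(hits) + 1]] <- data.frame(
          class = rule$class, type = rule$type, rule_mz = rule$mz,
          matched_mz = peaks$mz[j], delta_mz = loss[j] - rule$mz,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}
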