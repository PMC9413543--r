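test_that("monoisotopic masses follow IUPAC elemental arithmetic", {
  expect_equal(monoisotopic_mass("H2O"), 18.01056, tolerance = 1e-6)
  # protonated phosphocholine, the diagnostic head-group fragment
  expect_equal(monoisotopic_mass("C5H15NO4P", charge = 1), 184.07332,
               tolerance = 1e-5)
  # LPC(20:4): neutral mass and [M+H]+
  expect_equal(monoisotopic_mass("C28H50NO7P"), 543.33249,
               tolerance = 1e-5)
  expect_equal(adduct_mz(monoisotopic_mass("C28H50NO7P"), "[M+H]+"),
               544.33977, tolerance = 1e-5)
  expect_error(monoisotopic_mass("C2Xx3"), "unknown element")
  expect_error(parse_formula("not a formula!"), "parse")
})

test_that("formula parsing handles multi-letter symbols and implicit counts", {
  expect_equal(parse_formula("C5H15NO4P"),
               c(C = 5L, H = 15L, N = 1L, O = 4L, P = 1L)[
                 order(names(c(C = 5L, H = 15L, N = 1L, O = 4L, P = 1L)))])
  expect_equal(parse_formula("NaCl"), c(Cl = 1L, Na = 1L))
  expect_equal(unname(parse_formula("CH3COOH")[c("C", "H", "O")]),
               c(2L, 4L, 2L))
})

test_that("lyso-lipid shorthand expands to the published formulas", {
  expect_equal(lyso_gpl_formula("LPC", 20, 4), "C28H50NO7P")
  expect_equal(lyso_gpl_formula("LPC", 20, 5), "C28H48NO7P")
  expect_equal(lyso_gpl_formula("LPC", 20, 2), "C28H54NO7P")
  expect_equal(lyso_gpl_formula("LPE", 22, 4), "C27H48NO7P")
  expect_equal(lyso_gpl_formula("LPE", 18, 1), "C23H46NO7P")
})

test_that("observed lipid ions fall within the 5 ppm annotation tolerance", {
  within5 <- function(obs, formula, adduct) {
    theo <- adduct_mz(monoisotopic_mass(formula), adduct)
    abs(ppm_error(obs, theo))
  }
  expect_lt(within5(544.3400, "C28H50NO7P", "[M+H]+"), 5)     # LPC(20:4)
  expect_lt(within5(530.3254, "C27H48NO7P", "[M+H]+"), 5)     # LPE(22:4)
  expect_lt(within5(586.3141, "C28H48NO7P", "[M+COOH]-"), 5)  # LPC(20:5)
  expect_lt(within5(478.2922, "C23H46NO7P", "[M-H]-"), 5)     # LPE(18:1)
})

test_that("adduct arithmetic is self-consistent", {
  m <- monoisotopic_mass("C28H50NO7P")
  # protonation vs deprotonation differ by exactly two proton masses
  expect_equal(adduct_mz(m, "[M+H]+") - adduct_mz(m, "[M-H]-"),
               2 * 1.00727646, tolerance = 1e-5)
  expect_equal(ppm_error(m, m), 0)
  expect_error(adduct_mz(m, "[M+NH4]+"), "unregistered")
  expect_error(adduct_mz(-1, "[M+H]+"), "positive")
  reg <- adduct_registry()
  expect_setequal(reg$name, c("[M+H]+", "[M+Na]+", "[M-H]-", "[M+COOH]-"))
})

test_that("the SST co-elution window doubles the worst compound spread", {
  sst <- data.frame(
    compound = rep(c("caffeine", "verapamil", "reserpine"), each = 3),
    rt = c(3.00, 3.01, 3.02,    # spread 0.02
           6.10, 6.15, 6.12,    # spread 0.05
           9.50, 9.53, 9.51))   # spread 0.03
  expect_equal(rt_window_from_sst(sst), 0.10)
  # identical RTs give a zero window
  flat <- data.frame(compound = rep("x", 3), rt = rep(5, 3))
  expect_equal(rt_window_from_sst(flat), 0)
  # adding an injection can only widen the window
  wider <- rbind(sst, data.frame(compound = "verapamil", rt = 6.30))
  expect_gte(rt_window_from_sst(wider), rt_window_from_sst(sst))
  expect_error(rt_window_from_sst(
    data.frame(compound = c("a", "a", "b"), rt = c(1, 2, 3))), "b")
})

test_that("a feature pairs with its rescaled twin at r = 1", {
  set.seed(181)
  s <- generate_study(study_design(n_features_pos = 30,
                                   n_features_neg = 30, n_significant = 3,
                                   n_cross_pairs = 0, seed = 12))
  pos <- s$pos; neg <- s$neg
  # plant an affine copy of a positive feature into the negative block
  i <- match("P0005", pos$features$feature_id)
  j <- match("N0011", neg$features$feature_id)
  neg$intensities[j, ] <- 3.7 * pos$intensities[i, ] + 120
  neg$features$rt[j] <- pos$features$rt[i]
  pairs <- cross_mode_pairs(pos, neg, list(pos = "P0005"),
                            rt_window = 0.1)
  hit <- pairs[pairs$neg_id == "N0011", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$r, 1, tolerance = 1e-12)
  expect_true(hit$passes)
})

test_that("generator cross pairs are recovered with high precision and recall", {
  s <- generate_study(study_design(n_features_pos = 200,
                                   n_features_neg = 180,
                                   n_significant = 20, n_cross_pairs = 10,
                                   drift_magnitude = 0, seed = 13))
  truth <- s$truth$cross_pairs
  pairs <- cross_mode_pairs(
    s$pos, s$neg,
    list(pos = s$truth$significant$pos$feature_id,
         neg = s$truth$significant$neg$feature_id),
    r_threshold = 0.8, rt_window = 0.04)
  got <- pairs[pairs$passes, c("pos_id", "neg_id")]
  key <- function(d) paste(d$pos_id, d$neg_id)
  recall <- mean(key(truth) %in% key(got))
  precision <- mean(key(got) %in% key(truth))
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
})

test_that("co-eluting but uncorrelated features fail the correlation gate", {
  fails <- vapply(1:20, function(i) {
    s <- generate_study(study_design(n_features_pos = 40,
                                     n_features_neg = 40,
                                     n_significant = 2, n_cross_pairs = 0,
                                     drift_magnitude = 0,
                                     seed = 200 + i))
    pos <- s$pos; neg <- s$neg
    neg$features$rt[3] <- pos$features$rt[3]   # force co-elution
    p <- cross_mode_pairs(pos, neg,
                          list(pos = pos$features$feature_id[3]),
                          rt_window = 0.1)
    !any(p$neg_id == neg$features$feature_id[3])
  }, logical(1))
  expect_gte(mean(fails), 0.95)
})

test_that("Pearson r matches the hand formula and ignores affine maps", {
  set.seed(191)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(cor(x, y), pearson_by_hand(x, y), tolerance = 1e-12)
  expect_equal(pearson_by_hand(x, 2.5 * y + 7), pearson_by_hand(x, y),
               tolerance = 1e-12)
})

test_that("fragment rules flag the diagnostic lipid signatures", {
  # phosphocholine head group: theoretical and as-printed variants both hit
  hints <- fragment_class_hints(c(104.1070, 184.0733))
  expect_true(any(grepl("phosphocholine", hints$class)))
  hints2 <- fragment_class_hints(c(184.0718))
  expect_true(any(grepl("phosphocholine", hints2$class)))
  # acylcarnitine fragment
  expect_true(any(grepl("acylcarnitine",
                        fragment_class_hints(c(85.0268))$class)))
  # methyl formate neutral loss from a formate adduct
  hints3 <- fragment_class_hints(c(526.2992), precursor_mz = 586.3141)
  expect_true(any(grepl("formate-adduct LPC", hints3$class)))
  # phosphoethanolamine loss identifies LPE
  hints4 <- fragment_class_hints(c(389.3089), precursor_mz = 530.3254)
  expect_true(any(grepl("LPE", hints4$class)))
  # no precursor: neutral-loss rules are skipped
  expect_false(any(grepl("LPE",
                         fragment_class_hints(c(389.3089))$class)))
  # far-off peaks and empty lists give no hints
  expect_equal(nrow(fragment_class_hints(c(300.1, 420.2))), 0)
  expect_equal(nrow(fragment_class_hints(numeric(0))), 0)
})
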