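cls36 <- factor(rep(c("A", "B", "C"), each = 12))
cls9 <- factor(rep(c("A", "B", "C"), each = 3))

test_that("anova_fdr matches direct F arithmetic at the extremes", {
  # three identical groups: no between-group variance at all
  flat <- matrix(rep(c(1, 2, 3), 3), 1)
  r <- anova_fdr(flat, cls9)
  expect_equal(r$p, 1)
  # widely separated tight groups
  sep <- matrix(c(0, 0.1, -0.1, 5, 5.1, 4.9, 10, 10.1, 9.9), 1)
  expect_lt(anova_fdr(sep, cls9)$p, 1e-6)
  # zero within-group variance: degenerate perfect separator
  deg <- matrix(rep(c(1, 2, 3), each = 3), 1)
  rd <- anova_fdr(deg, cls9)
  expect_equal(rd$p, 0)
  expect_true(rd$degenerate)
})

test_that("ANOVA p-values agree with the aov reference to 1e-8", {
  set.seed(131)
  m <- matrix(rnorm(20 * 36, sd = 2), 20, 36)
  m[1:5, ] <- m[1:5, ] + rep(c(0, 1, 2), each = 12)[col(m[1:5, ])]
  r <- anova_fdr(m, cls36)
  oracle <- apply(m, 1, function(v)
    summary(aov(v ~ cls36))[[1]][["Pr(>F)"]][1])
  expect_equal(r$p, oracle, tolerance = 1e-8)
})

test_that("BH adjustment matches the hand-rolled formula", {
  set.seed(141)
  m <- matrix(rnorm(50 * 36), 50, 36)
  r <- anova_fdr(m, cls36)
  expect_equal(r$q, bh_by_hand(r$p), tolerance = 1e-12)
  # the frozen textbook example
  expect_equal(bh_by_hand(c(0.001, 0.01, 0.02, 0.8)),
               c(0.004, 0.02, 0.8 / 30, 0.8), tolerance = 1e-12)
  # q >= p and q non-decreasing in p rank order
  expect_true(all(r$q >= r$p))
  o <- order(r$p)
  expect_true(all(diff(r$q[o]) >= -1e-15))
})

test_that("Tukey all-distinct verdicts follow the studentized range", {
  set.seed(151)
  well <- rep(c(0, 5, 10), each = 12) + rnorm(36, sd = 0.1)
  expect_true(tukey_all_distinct(well, cls36))
  two_equal <- rep(c(0, 0, 10), each = 12) + rnorm(36, sd = 0.1)
  expect_false(tukey_all_distinct(two_equal, cls36))
  identical_groups <- rnorm(36, sd = 0.1)
  expect_false(tukey_all_distinct(identical_groups, cls36))
  expect_error(tukey_all_distinct(well[1:24], cls36[1:24]), "3 classes")
})

test_that("Tukey pairwise p-values agree with TukeyHSD to 1e-8", {
  set.seed(161)
  for (i in 1:10) {
    v <- rnorm(36) + rep(c(0, 0.5, 1), each = 12) * runif(1, 0, 2)
    ours <- sort(attr(tukey_all_distinct(v, cls36), "p_pairs"))
    ref <- sort(TukeyHSD(aov(v ~ cls36))$cls36[, "p adj"])
    expect_equal(ours, ref, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("Lilliefors screen separates normal from heavy-tailed residuals", {
  p_norm <- p_t1 <- numeric(200)
  for (i in 1:200) {
    set.seed(1000 + i)
    p_norm[i] <- lilliefors_normal(rnorm(36), cls36)$p
    p_t1[i] <- lilliefors_normal(rt(36, df = 1), cls36)$p
  }
  expect_gte(mean(p_norm > 0.05), 0.9)
  expect_gte(mean(p_t1 < 0.05), 0.9)
  expect_error(lilliefors_normal(c(1, 2, 3), factor(c("A", "A", "A"))),
               "at least 5")
  const <- lilliefors_normal(rep(c(1, 2, 3), each = 3), cls9)
  expect_equal(const$p, 0)
  expect_equal(const$flag, "constant")
})

test_that("Kruskal-Wallis matches the hand-rolled H statistic", {
  # disjoint rank blocks: H near its maximum
  blocks <- c(1:12, 101:112, 1001:1012)
  kw <- kruskal_wallis(blocks, cls36)
  expect_lt(kw$p, 1e-6)
  set.seed(171)
  for (i in 1:10) {
    v <- round(rnorm(36), 1)  # rounding induces ties
    ours <- kruskal_wallis(v, cls36)
    expect_equal(ours$statistic, kw_by_hand(v, cls36), tolerance = 1e-10)
  }
  ident <- kruskal_wallis(rep(c(1, 2, 3), 12), cls36)
  expect_gt(ident$p, 0.99)
  tied <- kruskal_wallis(rep(7, 36), cls36)
  expect_equal(tied$p, 1)
  expect_equal(tied$flag, "all values tied")
})

test_that("trend classification implements the A/B/C mean ordering", {
  v <- function(a, b, c) rep(c(a, b, c), each = 3)
  expect_equal(as.character(classify_trend(v(1, 2, 3), cls9)), "Up")
  expect_equal(as.character(classify_trend(v(3, 2, 1), cls9)), "Down")
  other <- classify_trend(v(1, 5, 2), cls9)
  expect_equal(as.character(other), "Other")
  expect_equal(attr(other, "subtype"), "B-peak")
  expect_equal(attr(classify_trend(v(5, 1, 4), cls9), "subtype"),
               "B-trough")
})

test_that("the cascade accounts for every feature and adds up", {
  s <- generate_study(study_design(n_features_pos = 250,
                                   n_features_neg = 40, n_significant = 25,
                                   n_cross_pairs = 0, effect_size = 3,
                                   isotope_fraction = 0,
                                   high_rsd_fraction = 0, seed = 8))
  res <- significance_cascade(qc_drift_correct(s$pos), block = "ESI+")
  counts <- res$report$counts
  expect_equal(counts[7], counts[4] + counts[6])
  expect_equal(counts[4] + counts[5], counts[3])
  expect_equal(counts[1], 250)
  expect_equal(sum(res$features$significant), counts[7])
  # spiked features recovered with their designed trends
  found <- res$features[res$features$significant, ]
  truth <- s$truth$significant$pos
  hit <- found$feature_id %in% truth$feature_id
  expect_gte(mean(truth$feature_id %in% found$feature_id), 0.8)
  expect_equal(found$trend[hit],
               truth$trend[match(found$feature_id[hit],
                                 truth$feature_id)])
})

test_that("the cascade is equivariant to per-feature affine rescaling", {
  s <- generate_study(study_design(n_features_pos = 60,
                                   n_features_neg = 20, n_significant = 10,
                                   n_cross_pairs = 0, effect_size = 2.5,
                                   drift_magnitude = 0, seed = 9))
  x <- s$pos
  res1 <- significance_cascade(x)
  set.seed(10)
  a <- runif(n_features(x), 0.5, 20)
  b <- runif(n_features(x), 0, 50)
  x$intensities <- x$intensities * a + b
  res2 <- significance_cascade(x)
  expect_equal(res1$features$p, res2$features$p, tolerance = 1e-9)
  expect_equal(res1$features$tukey_pass, res2$features$tukey_pass)
  expect_equal(res1$features$kw_p, res2$features$kw_p, tolerance = 1e-9)
  expect_equal(res1$features$trend, res2$features$trend)
  expect_equal(res1$report$counts, res2$report$counts)
})

test_that("a cascade where nothing passes ANOVA reports zeros downstream", {
  set.seed(11)
  x <- tiny_table(30, intensities = matrix(rnorm(30 * 12, 1000, 10), 30, 12))
  res <- significance_cascade(x)
  expect_equal(res$report$counts[2:7], rep(0L, 6))
  expect_true(all(is.na(res$features$tukey_pass)))
  # per-feature TSV export
  path <- tempfile(fileext = ".tsv")
  write_univariate_result(res, path)
  expect_equal(nrow(read.table(path, sep = "\t", header = TRUE)), 30)
})
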