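test_that("normalization divides by the untreated group mean exactly", {
  rec <- data.frame(panel = "P1", arm = "specific", channel = "FITC",
                    treatment = c("U", "U", "F"),
                    concentration = c(2, 4, 3))
  out <- normalize_to_untreated(rec)
  expect_equal(out$normalized, c(2 / 3, 4 / 3, 1))
  expect_equal(mean(out$normalized[out$treatment == "U"]), 1)
  # randomized table against the brute-force group-by oracle
  rec2 <- fake_records(seed = 7, treatments = c("U", "C5", "F"))
  out2 <- normalize_to_untreated(rec2)
  expect_equal(out2$normalized, brute_normalize(rec2))
  # per-group untreated means are exactly 1 after normalization
  key <- interaction(out2$panel, out2$arm, out2$channel, drop = TRUE)
  for (g in levels(key)) {
    sel <- key == g & out2$treatment == "U"
    expect_equal(mean(out2$normalized[sel]), 1)
  }
  bad <- rec
  bad$concentration[bad$treatment == "U"] <- 0
  expect_error(normalize_to_untreated(bad), "untreated mean is zero")
  expect_error(
    normalize_to_untreated(data.frame(panel = "P1", arm = "a",
                                      channel = "PE", treatment = "F",
                                      concentration = 1)),
    "no untreated")
})

test_that("fold change reproduces the published worked examples", {
  # untreated total FITC vs unlabelled buffer: 70,130 / 3,798
  fc1 <- fold_change(70130, 3798)
  expect_equal(fc1$fc, 70130 / 3798)
  expect_lt(abs(fc1$fc - 18.4), 0.1)
  # P2 specific FITC: 38,179 / 3,798
  expect_lt(abs(fold_change(38179, 3798)$fc - 10.1), 0.1)
  # AF700: untreated total and P2-specific against unlabelled buffer
  expect_lt(abs(fold_change(37419, 6642)$fc - 5.6), 0.1)
  expect_lt(abs(fold_change(25931, 6642)$fc - 3.9), 0.1)
  # identical labelled and buffer values give exactly 1
  expect_equal(fold_change(c(5, 5), c(5, 5))$fc, 1)
  expect_error(fold_change(c(1, 2), c(0, 0)), "zero")
  # per-replicate mean against the overall buffer mean equals the
  # ratio of means, and the SD is the SD of the per-replicate ratios
  lab <- c(50, 100, 150)
  f <- fold_change(lab, c(8, 12))
  expect_equal(f$fc_mean, f$fc)
  expect_equal(f$fc_sd, sd(lab / 10))
})

test_that("reduction summaries reproduce the published CV arithmetic", {
  expect_equal(reduction_percent(100, u_mean = 100)$reductions, 0)
  # two replicates engineered to mean 47, SD 24 (the filtration row)
  r <- reduction_percent(100 * (1 - (47 + c(-24, 24) / sqrt(2)) / 100),
                         u_mean = 100)
  expect_equal(r$mean, 47)
  expect_equal(r$sd, 24)
  expect_equal(r$cv, 100 * 24 / 47)
  expect_lt(abs(r$cv - 51), 0.5)
  # washed filter row: mean 57, SD 18
  r2 <- reduction_percent(100 * (1 - (57 + c(-18, 18) / sqrt(2)) / 100),
                          u_mean = 100)
  expect_equal(r2$cv, 100 * 18 / 57)
  expect_lt(abs(r2$cv - 32), 0.5)
  # increases stay negative, never truncated
  expect_equal(reduction_percent(c(150), 100)$reductions, -50)
  expect_error(reduction_percent(1, 0), "positive")
})

test_that("pairwise Wilcoxon matches enumeration and R conventions", {
  # {1,2} vs {3,4}: exact two-sided p = 2/6
  res <- wilcoxon_pairwise(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(res$p, 1 / 3, tolerance = 1e-12)
  expect_equal(res$p, brute_wilcoxon_p(c(1, 2), c(3, 4)))
  # identical multisets: ties force the corrected approximation, p ~ 1
  res2 <- wilcoxon_pairwise(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_gte(res2$p, 0.99)
  # tie-free random samples, n <= 7: exact agreement with full enumeration
  set.seed(12)
  for (i in 1:10) {
    x <- round(rnorm(sample(3:7, 1)), 6)
    y <- round(rnorm(sample(3:7, 1)) + 0.5, 6)
    got <- wilcoxon_pairwise(c(x, y),
                             rep(c("x", "y"), c(length(x), length(y))))
    expect_equal(got$p, brute_wilcoxon_p(x, y), tolerance = 1e-12)
  }
})

test_that("Wilcoxon p is invariant to monotone transforms and group swap", {
  set.seed(13)
  x <- rlnorm(15); y <- rlnorm(20, 0.5)
  v <- c(x, y); g <- rep(c("a", "b"), c(15, 20))
  p0 <- wilcoxon_pairwise(v, g)$p
  expect_equal(wilcoxon_pairwise(log(v), g)$p, p0)
  expect_equal(wilcoxon_pairwise(v^3, g)$p, p0)
  expect_equal(wilcoxon_pairwise(v, rev(g))$p,
               wilcoxon_pairwise(rev(v), g)$p)
  expect_warning(wilcoxon_pairwise(c(1, 2, 3, 4, 9), c("a", "a", "b", "b", "c")),
                 "fewer than 2")
})

test_that("rejection rate under the null is calibrated at alpha = 0.05", {
  set.seed(14)
  rej <- mean(vapply(1:2000, function(i) {
    v <- rlnorm(140)
    wilcoxon_pairwise(v, rep(c("a", "b"), each = 70))$p < 0.05
  }, TRUE))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("aggregation strata have the design's sample sizes", {
  rec <- fake_records(seed = 20, treatments = c("U", "F", "WF"),
                      replicates = 5)
  norm <- normalize_to_untreated(rec)
  all_level <- aggregate_levels(norm, "all")$all
  expect_equal(unname(table(all_level$treatment)["F"]), 70L)
  panel_level <- aggregate_levels(norm, "panel")
  expect_equal(sort(names(panel_level)),
               sort(c("P1.specific", "P1.isotype",
                      "P2.specific", "P2.isotype")))
  expect_equal(sum(panel_level$P1.specific$treatment == "F"), 15L)
  expect_equal(sum(panel_level$P2.specific$treatment == "F"), 20L)
  label_level <- aggregate_levels(norm, "label")
  expect_equal(length(label_level), 14L)  # 3 + 3 + 4 + 4 label series
  expect_true(all(vapply(label_level, function(s)
    sum(s$treatment == "WF"), 1L) == 5L))
  cmp <- compare_treatments(norm, "all")
  expect_equal(nrow(cmp), choose(3, 2))
  expect_true(all(cmp$p > 0 & cmp$p <= 1))
})
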