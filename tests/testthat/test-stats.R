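test_that("Welch t agrees with stats::t.test on raw vectors", {
  set.seed(1)
  for (k in 1:10) {
    x <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    ours <- welch_t(x, y)
    ref <- t.test(x, y)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(ours$p_raw, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Welch t has the expected structural properties", {
  x <- c(1, 2, 3, 4)
  y <- c(2.5, 2.5, 2.5, 2.51)
  eq <- welch_t(summary_stats(5, 1, 10), summary_stats(5, 3, 20))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_raw, 1)

  fwd <- welch_t(x, y)
  rev <- welch_t(y, x)
  expect_equal(fwd$statistic, -rev$statistic)
  expect_equal(fwd$p_raw, rev$p_raw)

  # equal variance, equal n: Welch statistic equals the pooled-variance t
  set.seed(2)
  a <- rnorm(30); b <- rnorm(30, 0.5)
  expect_equal(welch_t(a, b)$statistic,
               unname(t.test(a, b, var.equal = TRUE)$statistic),
               tolerance = 1e-9)

  expect_error(welch_t(summary_stats(1, 0, 5), summary_stats(1, 0, 5)),
               "zero variance")
})

test_that("published atom-count summaries give the recorded Welch result", {
  s <- reference_summaries()
  row <- s[s$descriptor == "n_atoms", ]
  wt <- welch_t(summary_stats(row$rna_mean, row$rna_sd, row$n_per_group),
                summary_stats(row$protein_mean, row$protein_sd,
                              row$n_per_group))
  expect_equal(wt$statistic, 10.95223, tolerance = 1e-5)
  expect_equal(wt$df, 500.7402, tolerance = 1e-4)
  # Holm over the two size descriptors doubles the smallest raw p,
  # reproducing the published adjusted 7.175e-25 from 3-decimal inputs
  expect_equal(2 * wt$p_raw, 7.175e-25, tolerance = 2e-3)
})

test_that("Cohen's d uses the pooled-SD denominator, direction group1 - group2", {
  d <- cohen_d(summary_stats(244.713, 91.756, 300),
               summary_stats(176.353, 57.169, 300))
  expect_equal(round(d$cohen_d, 3), 0.894)
  # equal n: pooled SD reduces to sqrt((s1^2 + s2^2) / 2)
  expect_equal(d$cohen_d,
               (244.713 - 176.353) / sqrt((91.756^2 + 57.169^2) / 2))
  x <- rnorm(20)
  expect_equal(cohen_d(x, x)$cohen_d, 0)
  expect_equal(cohen_d(x, x + 1)$cohen_d, -cohen_d(x + 1, x)$cohen_d)
  expect_error(cohen_d(rep(1, 5), rep(1, 5)), "pooled SD")
})

test_that("Holm and BH adjustments match the hand-worked step rules", {
  expect_equal(unclass(holm_adjust(c(0.01, 0.04, 0.03))),
               c(0.03, 0.06, 0.06), ignore_attr = TRUE)
  expect_equal(as.numeric(holm_adjust(0.2)), 0.2)
  expect_equal(as.numeric(holm_adjust(c(1, 1, 1))), c(1, 1, 1))

  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  sorted <- bh_adjust(sort(runif(10)))
  expect_false(is.unsorted(sorted))

  # dominance: raw <= BH <= Holm <= 1, elementwise
  set.seed(4)
  for (k in 1:20) {
    p <- runif(sample(2:12, 1))
    h <- as.numeric(holm_adjust(p))
    b <- bh_adjust(p)
    expect_true(all(h >= p - 1e-15) && all(b >= p - 1e-15))
    expect_true(all(h >= b - 1e-15))
    expect_true(all(h <= 1) && all(b <= 1))
  }
})

test_that("Pillai's trace matches the hand SSCP computation", {
  # 6-row worked dataset
  Y <- rbind(c(0.60, 0.50), c(0.65, 0.55), c(0.55, 0.60),
             c(0.40, 0.70), c(0.45, 0.75), c(0.35, 0.65))
  g <- rep(c("RNA", "protein"), each = 3)
  res <- manova_two_group(Y, g)

  grand <- colMeans(Y)
  H <- matrix(0, 2, 2)
  E <- matrix(0, 2, 2)
  for (lev in unique(g)) {
    Yg <- Y[g == lev, ]
    mg <- colMeans(Yg)
    H <- H + nrow(Yg) * tcrossprod(mg - grand)
    E <- E + crossprod(sweep(Yg, 2, mg))
  }
  V <- sum(diag(H %*% solve(H + E)))
  expect_equal(res$pillai_trace, V, tolerance = 1e-12)
  expect_true(res$pillai_trace >= 0 && res$pillai_trace <= 1)

  # two-group Pillai is a monotone transform of the Hotelling-Lawley trace
  # U = tr(H E^-1) (itself T^2 / (n - 2)): V = U / (1 + U)
  set.seed(6)
  Y2 <- matrix(rnorm(60), 30, 2)
  g2 <- rep(c("a", "b"), 15)
  r2 <- manova_two_group(Y2, g2)
  hot <- summary(manova(Y2 ~ g2), test = "Hotelling-Lawley")$stats[1, 2]
  expect_equal(r2$pillai_trace, hot / (1 + hot), tolerance = 1e-9)
})

test_that("MANOVA detects strong shifts and rejects bad input", {
  set.seed(7)
  n <- 50
  Y <- rbind(cbind(rnorm(n), rnorm(n)),
             cbind(rnorm(n, 5), rnorm(n)))  # 5 SD shift in response 1
  g <- rep(c("a", "b"), each = n)
  res <- manova_two_group(Y, g)
  expect_lt(res$p, 1e-6)
  expect_true(is.finite(res$box_m$p))

  expect_error(manova_two_group(Y, rep("a", 2 * n)), "two groups")
  expect_error(manova_two_group(Y[1:5, ], c("a", "a", "a", "b", "b")),
               ">= 3")
  Ysing <- cbind(Y[, 1], Y[, 1])  # collinear responses
  expect_error(manova_two_group(Ysing, g), "singular|collinear")
})

test_that("chi-square matches the expected-count oracle and is permutation invariant", {
  counts <- reference_archetype_counts()
  res <- chi_square_independence(counts)
  expect_equal(res$statistic, oracle_chisq(counts), tolerance = 1e-10)
  expect_equal(res$df, 3)
  expect_lt(res$p, 0.01)
  expect_equal(rowSums(res$expected), rowSums(counts), ignore_attr = TRUE)
  expect_equal(colSums(res$expected), colSums(counts), ignore_attr = TRUE)

  prop <- outer(c(10, 20, 30), c(2, 3))
  resp <- chi_square_independence(prop)
  expect_equal(resp$statistic, 0)
  expect_equal(resp$p, 1)

  set.seed(8)
  tab <- matrix(rpois(8, 40), 4, 2)
  r1 <- chi_square_independence(tab)
  r2 <- chi_square_independence(tab[sample(4), sample(2)])
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-10)
  expect_equal(r1$statistic, oracle_chisq(tab), tolerance = 1e-12)

  expect_error(chi_square_independence(matrix(c(0, 0, 1, 2), 2)), "margin")
})

test_that("compare_groups produces a coherent full report", {
  set.seed(10)
  coh <- sample_cohort(seed = 10)
  rep <- compare_groups(coh, group_col = "group")
  expect_s3_class(rep, "comparison_report")
  expect_equal(rep$groups, c("RNA", "protein"))

  dt <- rep$descriptor_tests
  expect_setequal(dt$descriptor, c("rEV21", "rEV32", "rEV31", "n_atoms", "Rg"))
  expect_true(all(dt$p_holm >= dt$p_raw - 1e-15))
  expect_equal(sign(dt$cohen_d), sign(dt$mean1 - dt$mean2))
  # Holm families are separate: shape family of 3, size family of 2
  shape <- dt[dt$family == "shape", ]
  expect_equal(shape$p_holm,
               as.numeric(holm_adjust(shape$p_raw)))

  expect_equal(sum(rep$counts), nrow(coh))
  expect_equal(rep$chi_square$df, 3)
  at <- rep$archetype_tests$sphere
  expect_true(!is.null(at$manova))
  expect_true(all(at$shape_univariate$p_bh >= at$shape_univariate$p_raw - 1e-15))
})

test_that("identical groups yield null effects everywhere", {
  set.seed(11)
  half <- sample_cohort(seed = 11)
  half <- half[half$group == "RNA", ]
  dup <- rbind(half, transform(half, group = "protein"))
  rep <- compare_groups(dup, group_col = "group")
  expect_true(all(abs(rep$descriptor_tests$cohen_d) < 1e-12))
  expect_true(all(abs(rep$descriptor_tests$p_raw - 1) < 1e-12))
  expect_equal(rep$chi_square$statistic, 0, tolerance = 1e-12)
})
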