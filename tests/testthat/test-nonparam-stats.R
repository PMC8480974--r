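test_that("Mann-Whitney exact p matches full label enumeration", {
  x <- c(1, 2); y <- c(3, 4)
  res <- mann_whitney(x, y, "less")
  expect_equal(res$statistic_value, 0)
  expect_equal(res$p_value, 1 / 6, tolerance = 1e-12)
  expect_equal(res$p_value, oracle_mw_p(x, y, "less"))

  set.seed(21)
  for (i in 1:15) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- round(rnorm(n1), 3); y <- round(rnorm(n2, 0.5), 3)
    for (alt in c("greater", "less", "two.sided")) {
      expect_equal(mann_whitney(x, y, alt)$p_value, oracle_mw_p(x, y, alt),
                   tolerance = 1e-12,
                   label = sprintf("MW %s n1=%d n2=%d rep %d", alt, n1, n2, i))
    }
  }
})

test_that("Mann-Whitney agrees with wilcox.test on the exact path", {
  set.seed(4)
  x <- rnorm(8); y <- rnorm(7, 1)
  mine <- mann_whitney(x, y, "greater")
  ref <- wilcox.test(x, y, alternative = "greater", exact = TRUE)
  expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-12)
  expect_equal(mine$statistic_value, unname(ref$statistic))
})

test_that("U at its null centre gives z = 0 and r = 0", {
  res_z <- u_to_z(72, 12, 12)
  expect_equal(res_z, 0)
  expect_equal(effect_size_r(res_z, 24), 0)
})

test_that("the published U -> z -> r mapping reproduces without continuity correction", {
  expect_equal(u_to_z(114, 12, 12), (114 - 72) / sqrt(300), tolerance = 1e-12)
  expect_equal(round(u_to_z(114, 12, 12), 3), 2.425)
  expect_equal(round(u_to_z(120.5, 12, 12), 3), 2.800)
  expect_equal(round(effect_size_r(u_to_z(114, 12, 12), 24), 3), 0.495)
  expect_error(u_to_z(200, 12, 12), "out of range")
})

test_that("effect size r = |z|/sqrt(N) under both N conventions", {
  expect_equal(round(effect_size_r(3.624, 24), 3), 0.740)   # pooled N
  expect_equal(round(effect_size_r(-2.287, 12), 3), 0.660)  # group N, |z|
  expect_equal(effect_size_r(0, 100), 0)
  expect_equal(effect_size_r(-1.5, 9), effect_size_r(1.5, 9))
})

test_that("signed-rank exact p matches sign-pattern enumeration", {
  res <- wilcoxon_signed_rank(c(2, 3, 4), c(1, 1, 1), "greater")
  expect_equal(res$p_value, 1 / 8)
  expect_equal(res$p_value, oracle_wsr_p(c(1, 2, 3), "greater"))

  res1 <- wilcoxon_signed_rank(2, 1, "greater")
  expect_equal(res1$p_value, 0.5)

  set.seed(33)
  for (i in 1:12) {
    n <- sample(3:8, 1)
    x <- round(rnorm(n), 2); y <- round(rnorm(n), 2)
    d <- x - y
    if (all(d == 0)) next
    for (alt in c("greater", "less", "two.sided")) {
      expect_equal(wilcoxon_signed_rank(x, y, alt)$p_value,
                   oracle_wsr_p(d, alt), tolerance = 1e-12,
                   label = sprintf("WSR %s n=%d rep %d", alt, n, i))
    }
  }
})

test_that("signed-rank matches wilcox.test paired exact p without ties", {
  set.seed(5)
  x <- rnorm(9); y <- rnorm(9)
  mine <- wilcoxon_signed_rank(x, y, "two.sided")
  ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-12)
})

test_that("signed-rank r uses the group-size denominator", {
  # construct differences giving z = 2.521-ish is unnecessary: check the
  # arithmetic convention directly
  expect_equal(round(effect_size_r(-2.521, 12), 3), 0.728)
  expect_error(wilcoxon_signed_rank(c(1, 1), c(1, 1)), "all differences")
})

test_that("Friedman statistic matches the rank-sum formula and friedman.test", {
  m2 <- rbind(c(1, 2, 3), c(2, 4, 6))  # identical orderings, 2 subjects
  expect_equal(friedman(m2)$statistic_value, 4)
  expect_equal(friedman(m2)$df, 2)
  m3 <- rbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  expect_equal(friedman(m3)$statistic_value, 6)
  expect_equal(friedman(matrix(1, 3, 3))$statistic_value, 0)
  expect_error(friedman(rbind(c(1, NA, 2), c(1, 2, 3))), "complete")

  set.seed(8)
  for (i in 1:5) {
    m <- matrix(rnorm(24), 8, 3)
    ref <- stats::friedman.test(m)
    mine <- friedman(m)
    expect_equal(mine$statistic_value, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-10)
  }
})

test_that("Spearman correlation handles the canonical rank patterns", {
  expect_equal(spearman_rho(1:5, 2 * (1:5), "greater")$statistic_value, 1)
  expect_equal(spearman_rho(1:5, rev(1:5), "less")$statistic_value, -1)
  r <- spearman_rho(c(1, 2, 3), c(1, 3, 2), "greater")
  expect_equal(r$statistic_value, 0.5)  # 1 - 6*2/(3*8)
  expect_error(spearman_rho(c(1, 1, 1), 1:3), "constant")
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  res <- fisher_exact(matrix(c(5, 0, 0, 5), 2), "greater")
  expect_equal(res$p_value, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(1, 2, 2))$p_value, 1)
  # monotonicity: concentrating the diagonal at fixed margins never raises
  # the one-sided p
  p_prev <- Inf
  for (a in 0:5) {
    p <- fisher_exact(matrix(c(a, 5 - a, 5 - a, a), 2), "greater")$p_value
    expect_lte(p, p_prev + 1e-12)
    p_prev <- p
  }
})

test_that("Bonferroni levels match the published adjusted cutoffs", {
  expect_equal(round(bonferroni_level(0.05, 3), 3), 0.017)
  expect_equal(round(bonferroni_level(0.05, 6), 4), 0.0083)
  expect_equal(bonferroni_level(0.05, 1), 0.05)
  expect_error(bonferroni_level(0.05, 0))
})

test_that("exact and normal-approximation p agree closely at n = 10 vs 10", {
  set.seed(12)
  x <- rnorm(10); y <- rnorm(10, 0.8)
  ex <- mann_whitney(x, y, "less", exact_limit = 20L)
  ap <- mann_whitney(x, y, "less", exact_limit = 0L)
  expect_lt(abs(ex$p_value - ap$p_value), 0.02)
})

test_that("results are invariant to sample order", {
  set.seed(14)
  x <- rnorm(9); y <- rnorm(11, 0.3)
  a <- mann_whitney(x, y, "greater")
  b <- mann_whitney(sample(x), sample(y), "greater")
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$statistic_value, b$statistic_value)
})
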