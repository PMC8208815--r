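# Statistical toolbox: two-way type II ANOVA, Sidak adjustment,
# Mann-Whitney U, phospho normalization.

test_that("two-way ANOVA isolates a pure factor-A shift exactly", {
  # balanced 2x2; +2 by factor A only -> B and interaction SS identically 0
  a <- rep(c("a1", "a2"), each = 4)
  b <- rep(rep(c("b1", "b2"), each = 2), times = 2)
  y <- c(1, 3, 1, 3, 3, 5, 3, 5)  # cell means 2, 2, 4, 4
  tab <- two_way_anova(y, a, b)
  expect_equal(tab$statistic[tab$effect == "B"], 0)
  expect_equal(tab$statistic[tab$effect == "A:B"], 0)
  expect_gt(tab$statistic[tab$effect == "A"], 0)
})

test_that("balanced designs match the closed-form SS decomposition", {
  set.seed(5)
  for (k in 1:5) {
    a <- rep(c("x", "y", "z"), each = 8)
    b <- rep(rep(c("u", "v"), each = 4), times = 3)
    y <- rnorm(24, mean = 2 * (a == "y") + 1.5 * (b == "v"))
    tab <- two_way_anova(y, a, b)
    oracle <- oracle_balanced_anova(y, a, b)
    expect_equal(tab$sum_sq[tab$effect == "A"], oracle$ss_a, tolerance = 1e-10)
    expect_equal(tab$sum_sq[tab$effect == "B"], oracle$ss_b, tolerance = 1e-10)
    expect_equal(tab$sum_sq[tab$effect == "A:B"], oracle$ss_int, tolerance = 1e-10)
    expect_equal(tab$sum_sq[tab$effect == "residuals"], oracle$ss_res,
                 tolerance = 1e-10)
  }
})

test_that("unbalanced type II sums of squares agree with the model-comparison oracle", {
  skip_if_not_installed("car")
  set.seed(13)
  a <- factor(sample(c("a1", "a2"), 60, replace = TRUE, prob = c(0.7, 0.3)))
  b <- factor(sample(c("b1", "b2", "b3"), 60, replace = TRUE))
  y <- rnorm(60, mean = as.integer(a) + 0.5 * as.integer(b))
  tab <- two_way_anova(y, a, b)
  ref <- car::Anova(lm(y ~ a * b), type = 2)
  expect_equal(tab$sum_sq[1:3], ref[["Sum Sq"]][1:3], tolerance = 1e-10)
  expect_equal(tab$p_value[1:3], ref[["Pr(>F)"]][1:3], tolerance = 1e-10)
})

test_that("degenerate and malformed designs are handled as documented", {
  a <- rep(c("a1", "a2"), each = 4)
  b <- rep(rep(c("b1", "b2"), each = 2), times = 2)
  tab <- two_way_anova(rep(3, 8), a, b)
  expect_true(all(tab$statistic[1:3] == 0))
  expect_true(all(tab$p_value[1:3] == 1))
  # empty design cell named in the error
  expect_error(two_way_anova(1:6, c("a1", "a1", "a1", "a1", "a2", "a2"),
                             c("b1", "b2", "b1", "b2", "b1", "b1")),
               "a2 x b2")
  expect_error(two_way_anova(1:4, rep("a1", 4), rep(c("b1", "b2"), 2)),
               "2 levels")
})

test_that("Sidak adjustment follows its formula and monotonicity", {
  expect_equal(sidak_adjust(0.05, m = 1), 0.05)
  expect_equal(sidak_adjust(0.01, m = 3), 0.029701)
  expect_equal(sidak_adjust(0.5, m = 2), 0.75)
  expect_equal(sidak_adjust(c(0, 1), m = 5), c(0, 1))  # fixed points
  p <- seq(0, 1, by = 0.05)
  expect_true(all(diff(sidak_adjust(p, m = 4)) >= 0))       # monotone in p
  expect_true(all(sidak_adjust(p, m = 6) >= sidak_adjust(p, m = 2)))  # in m
  expect_error(sidak_adjust(0.05, m = 0), "m")
  expect_error(sidak_adjust(1.2), "0, 1")
})

test_that("pairwise Sidak comparisons adjust over all pairs", {
  set.seed(2)
  g <- rep(c("g1", "g2", "g3"), each = 10)
  y <- rnorm(30) + 2 * (g == "g3")
  res <- pairwise_sidak(y, g)
  expect_equal(nrow(res), 3L)
  expect_equal(res$p_adjusted, sidak_adjust(res$p_value, m = 3))
})

test_that("exact Mann-Whitney matches full enumeration", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1 / 3)
  expect_equal(r$mode, "exact")

  # complete ties: U = nA nB / 2, p = 1
  tied <- mann_whitney_u(c(5, 5), c(5, 5))
  expect_equal(tied$statistic, 2)
  expect_equal(tied$p_value, 1)

  # brute-force oracle over random small samples, with and without ties
  set.seed(17)
  for (k in 1:10) {
    n_a <- sample(2:6, 1); n_b <- sample(2:6, 1)
    a <- sample(1:8, n_a, replace = TRUE)
    b <- sample(1:8, n_b, replace = TRUE)
    got <- mann_whitney_u(a, b, mode = "exact")
    expect_equal(got$p_value, oracle_mwu_exact(a, b), label =
                   sprintf("case %d", k))
  }
})

test_that("exact p agrees with wilcox.test on tie-free samples", {
  set.seed(23)
  for (k in 1:5) {
    a <- sample(seq(1, 99, by = 2), 6)   # odd values
    b <- sample(seq(2, 100, by = 2), 5)  # even values: no ties
    got <- mann_whitney_u(a, b, mode = "exact")
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("asymptotic approximation tracks the exact p at moderate n", {
  set.seed(31)
  for (k in 1:5) {
    a <- rnorm(7); b <- rnorm(7, mean = 0.5)
    ex <- mann_whitney_u(a, b, mode = "exact")$p_value
    as <- mann_whitney_u(a, b, mode = "asymptotic")$p_value
    expect_lt(abs(ex - as), 0.02)
  }
  # auto switches on combined size
  expect_equal(mann_whitney_u(rnorm(7), rnorm(7))$mode, "exact")
  expect_equal(mann_whitney_u(rnorm(8), rnorm(7))$mode, "asymptotic")
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("phospho normalization is exact scale-equivariant arithmetic", {
  expect_equal(normalize_phospho(10, 2, 5), 1.0)
  expect_equal(normalize_phospho(0, 3, 100), 0)
  base <- normalize_phospho(7, 2, 50)
  expect_equal(normalize_phospho(14, 2, 50), 2 * base)
  expect_equal(normalize_phospho(7, 2, 100), base / 2)
  expect_equal(normalize_phospho(7, 4, 50), base / 2)
  expect_error(normalize_phospho(1, 0, 5), "positive")
  expect_error(normalize_phospho(-1, 2, 5), "non-negative")
})
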