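# Multinomial logistic regression: likelihood, MLE, prediction, profiles

wt_beta <- published_model("WT")$beta
ko_beta <- published_model("KO")$beta

test_that("log-likelihood matches direct per-cell evaluation", {
  # uniform softmax under zero coefficients
  x <- matrix(rnorm(9, sd = 2), 3, 3)
  expect_equal(mlr_log_likelihood(matrix(0, 2, 4), x, c("type1", "type2a", "type2b")),
               3 * log(1 / 3))
  # single cell at the origin under the printed wild-type coefficients
  expect_equal(mlr_log_likelihood(wt_beta, c(0, 0, 0), "type1"),
               log(1 / (1 + exp(-0.343) + exp(-3.074))))
  # random betas against the brute-force per-cell oracle
  set.seed(21)
  for (k in 1:5) {
    beta <- matrix(rnorm(8), 2, 4)
    x <- matrix(rnorm(36), 12, 3)
    labels <- sample(c("type1", "type2a", "type2b"), 12, replace = TRUE)
    expect_equal(mlr_log_likelihood(beta, x, labels),
                 oracle_mlr_ll(beta, x, labels), tolerance = 1e-12)
  }
  expect_error(mlr_log_likelihood(wt_beta, matrix(numeric(0), 0, 3),
                                  character(0)), "empty")
})

test_that("log-likelihood is stable for extreme logits", {
  beta <- matrix(c(700, 0, 0, 0, -700, 0, 0, 0), 2, 4, byrow = TRUE)
  ll <- mlr_log_likelihood(beta, c(0, 0, 0), "type2a")
  expect_true(is.finite(ll))
  expect_equal(ll, 0, tolerance = 1e-10)  # p(type2a) ~ 1
})

test_that("intercept-only fit recovers the closed-form log frequency ratios", {
  n <- c(50, 30, 20)
  labels <- rep(c("type1", "type2a", "type2b"), times = n)
  x <- matrix(0, sum(n), 3)
  fit <- fit_mlr(x, labels)
  expect_true(fit$fit_meta$converged)
  expect_equal(unname(fit$beta[, "intercept"]),
               c(log(0.3 / 0.5), log(0.2 / 0.5)), tolerance = 1e-6)
  expect_equal(unname(fit$beta[, 2:4]), matrix(0, 2, 3), tolerance = 1e-8)
})

test_that("the fitted optimum satisfies first-order conditions and beats perturbations", {
  sim <- make_overlapping_dataset(300, wt_beta, seed = 5)
  fit <- fit_mlr(sim$x, sim$labels)
  expect_true(fit$fit_meta$converged)
  g <- oracle_mlr_grad(as.vector(t(fit$beta)), sim$x,
                       match(sim$labels, c("type1", "type2a", "type2b")))
  expect_lt(max(abs(g)), 1e-6)
  ll_hat <- mlr_log_likelihood(fit$beta, sim$x, sim$labels)
  set.seed(99)
  for (k in 1:100) {
    pert <- fit$beta + matrix(rnorm(8, sd = 0.05), 2, 4)
    expect_lte(mlr_log_likelihood(pert, sim$x, sim$labels), ll_hat)
  }
})

test_that("separation and degenerate label sets are reported, not silently fitted", {
  # perfectly separable: label decided by sign of x3
  x <- matrix(rnorm(90), 30, 3)
  labels <- ifelse(x[, 3] > 0, "type2b", "type1")
  labels[1] <- "type2a"; x[1, 3] <- 5  # keep three classes, still separable
  expect_warning(fit <- fit_mlr(x, labels), "separation")
  expect_true(fit$fit_meta$separation)

  expect_error(fit_mlr(x, rep("type1", 30)), "single class")
  expect_error(fit_mlr(x, rep(c("type2a", "type2b"), 15)), "type1 absent")
  expect_error(fit_mlr(x[1:2, ], c("type1", "type2a")), "at least 3")
})

test_that("posteriors under the printed coefficients match hand evaluation", {
  m <- published_model("WT")
  p0 <- predict_proba(m, c(0, 0, 0))
  den <- 1 + exp(-0.343) + exp(-3.074)
  expect_equal(unname(p0$probabilities[1, ]),
               c(1, exp(-0.343), exp(-3.074)) / den, tolerance = 1e-12)
  expect_equal(round(unname(p0$probabilities[1, ]), 3), c(0.570, 0.404, 0.026))
  expect_equal(as.character(p0$assigned), "type1")

  # hyperpolarized-feature corner: logits (0, 2.519, 6.700) by hand
  p1 <- predict_proba(m, c(-2, 2, 2))
  expect_equal(as.character(p1$assigned), "type2b")
  expect_gt(p1$probabilities[1, "type2b"], 0.98)

  # zero model: exact ties broken toward type1
  p2 <- predict_proba(matrix(0, 2, 4), c(0.3, -1, 2))
  expect_equal(unname(p2$probabilities[1, ]), rep(1 / 3, 3))
  expect_equal(as.character(p2$assigned), "type1")
  expect_true(p2$tie)
})

test_that("posterior normalization holds for random models and inputs", {
  set.seed(42)
  for (k in 1:20) {
    beta <- matrix(rnorm(8, sd = 3), 2, 4)
    x <- matrix(rnorm(60, sd = 3), 20, 3)
    p <- predict_proba(beta, x)
    expect_true(all(abs(rowSums(p$probabilities) - 1) < 1e-12))
    expect_true(all(p$probabilities >= 0))
    # assigned always attains the maximum
    expect_equal(apply(p$probabilities, 1, max),
                 p$probabilities[cbind(1:20, as.integer(p$assigned))])
  }
})

test_that("published coefficient fixtures carry the printed values", {
  expect_equal(wt_beta["type2a", "x3"], 1.681)
  expect_equal(wt_beta["type2b", "intercept"], -3.074)
  expect_equal(ko_beta["type2b", "x3"], 5.549)
  expect_equal(ko_beta["type2a", "x1"], -1.373)
  expect_error(published_model("HET"))
  # prediction from raw records without standardization is refused
  expect_error(classify_cells(published_model("WT"), make_records(5)),
               "standardization")
})

test_that("probability profiles are consistent, normalized and monotone where implied", {
  m <- published_model("WT")
  one <- probability_profile(m, 3, 0.7, others_at = c(0.2, -0.1))
  expect_equal(unname(one[1, ]),
               unname(predict_proba(m, c(0.2, -0.1, 0.7))$probabilities[1, ]))
  grid <- seq(-3, 3, length.out = 61)
  prof <- probability_profile(m, 3, grid)
  expect_true(all(abs(rowSums(prof) - 1) < 1e-12))
  # larger Vm raises the odds of type 2b over type 1 (positive Vm slope in
  # the type2b contrast); the absolute type2b probability need not be
  # monotone because the type2a Vm slope is larger still
  expect_true(all(diff(prof[, "type2b"] / prof[, "type1"]) > 0))
  # smaller Cm -> higher type2b probability (negative x1 slope in both the
  # odds and, here, the absolute probability)
  prof1 <- probability_profile(m, 1, grid)
  expect_true(all(diff(prof1[, "type2b"] / prof1[, "type1"]) < 0))
  expect_true(all(diff(prof1[, "type2b"]) < 0))
  # zero model: constant 1/3 everywhere
  flat <- probability_profile(mlr_model(matrix(0, 2, 4)), 2, grid)
  expect_true(all(abs(flat - 1 / 3) < 1e-15))
  expect_error(probability_profile(m, 3, numeric(0)), "grid")
})

test_that("classify_cells assigns by maximum posterior and counts per class", {
  rec <- make_records(40, seed = 13)
  std <- fit_standardization(rec)
  m <- mlr_model(wt_beta, genotype = "WT", standardization = std)
  res <- classify_cells(m, rec)
  expect_equal(sum(res$counts), 40L)
  expect_equal(unname(res$counts),
               unname(as.integer(table(factor(res$assignments$assigned,
                                              levels = c("type1", "type2a", "type2b"))))))
  # cells exactly at the training means get the class favored at the origin
  centre <- cell_records("m", "WT", vm = std$means[["vm"]],
                         rm = exp(std$means[["log_rm"]]),
                         cm = exp(std$means[["log_cm"]]))
  expect_equal(classify_cells(m, centre)$assignments$assigned, "type1")
  # empty input -> empty table, zero counts
  empty <- classify_cells(m, rec[0, , drop = FALSE])
  expect_equal(unname(empty$counts), c(0L, 0L, 0L))
})

test_that("training accuracy scores exact and partial agreement", {
  rec <- make_records(12, seed = 31)
  std <- fit_standardization(rec)
  m <- mlr_model(wt_beta, genotype = "WT", standardization = std)
  assigned <- classify_cells(m, rec)$assignments$assigned
  rec$known_type <- assigned
  expect_equal(training_accuracy(m, rec), 1.0)
  flip <- rec
  flip$known_type[1:6] <- ifelse(assigned[1:6] == "type1", "type2b", "type1")
  expect_equal(training_accuracy(m, flip), 0.5)
  rec$known_type[2] <- NA
  expect_error(training_accuracy(m, rec), "known_type")
})

test_that("models round-trip through JSON serialization", {
  rec <- make_records(60, seed = 17)
  std <- fit_standardization(rec)
  sim <- make_overlapping_dataset(200, wt_beta, seed = 6)
  fit <- fit_mlr(sim$x, sim$labels, genotype = "WT", standardization = std)
  path <- withr::local_tempfile(fileext = ".json")
  write_mlr_model(fit, path)
  back <- read_mlr_model(path)
  expect_equal(back$beta, fit$beta)
  expect_equal(back$standardization$means, std$means)
  expect_equal(back$genotype, "WT")
})

test_that("classification is invariant to unit and log-base choices end to end", {
  rec <- make_records(80, seed = 23)
  std <- fit_standardization(rec)
  m <- mlr_model(wt_beta, genotype = "WT", standardization = std)
  base <- classify_cells(m, rec)$assignments

  rescaled <- rec
  rescaled$cm <- rec$cm * 1000
  rescaled$rm <- rec$rm / 1e3
  rescaled$vm <- rec$vm + 12
  m2 <- mlr_model(wt_beta, genotype = "WT",
                  standardization = fit_standardization(rescaled))
  alt <- classify_cells(m2, rescaled)$assignments
  expect_equal(alt$assigned, base$assigned)
  expect_equal(alt$p_type2b, base$p_type2b, tolerance = 1e-12)
})
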