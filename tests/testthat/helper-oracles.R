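# Independent oracles used across tests. These deliberately re-derive the
# quantities with different code paths (per-cell products, explicit
# enumeration, closed-form decompositions) from the implementations they
# check.

# Per-cell softmax log-likelihood via direct probability products.
oracle_mlr_ll <- function(beta, x, labels) {
  idx <- match(as.character(labels), c("type1", "type2a", "type2b"))
  ll <- 0
  for (i in seq_len(nrow(x))) {
    logits <- c(0,
                beta[1, 1] + sum(beta[1, 2:4] * x[i, ]),
                beta[2, 1] + sum(beta[2, 2:4] * x[i, ]))
    p <- exp(logits) / sum(exp(logits))
    ll <- ll + log(p[idx[i]])
  }
  ll
}

# Analytic gradient of the log-likelihood (length 8, contrast-major),
# derived independently for the optimizer cross-check.
oracle_mlr_grad <- function(beta_vec, x, y_idx) {
  beta <- matrix(beta_vec, 2, 4, byrow = TRUE)
  z <- cbind(1, x)
  eta <- cbind(0, z %*% t(beta))
  p <- exp(eta) / rowSums(exp(eta))
  g <- numeric(8)
  for (cl in 1:2) {
    ind <- as.numeric(y_idx == cl + 1)
    g[(cl - 1) * 4 + 1:4] <- colSums(z * (ind - p[, cl + 1]))
  }
  g
}

# Brute-force exact Mann-Whitney two-sided p (symmetric-tail definition)
# by enumerating every assignment of observations to group A.
oracle_mwu_exact <- function(a, b) {
  n_a <- length(a); n <- n_a + length(b)
  ranks <- rank(c(a, b))
  u_obs <- sum(ranks[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mu <- n_a * (n - n_a) / 2
  combos <- utils::combn(n, n_a)
  u_all <- apply(combos, 2, function(ix) sum(ranks[ix]) - n_a * (n_a + 1) / 2)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Classical closed-form sum-of-squares decomposition for a balanced
# two-factor design with replication.
oracle_balanced_anova <- function(values, fa, fb) {
  fa <- factor(fa); fb <- factor(fb)
  gm <- mean(values)
  cell_n <- table(fa, fb)
  stopifnot(length(unique(c(cell_n))) == 1)
  r <- cell_n[1, 1]
  ma <- tapply(values, fa, mean)
  mb <- tapply(values, fb, mean)
  mab <- tapply(values, list(fa, fb), mean)
  ss_a <- r * nlevels(fb) * sum((ma - gm)^2)
  ss_b <- r * nlevels(fa) * sum((mb - gm)^2)
  ss_int <- r * sum((outer(ma - gm, mb - gm, "+") + gm - mab)^2)
  ss_res <- sum((values - mab[cbind(fa, fb)])^2)
  list(ss_a = ss_a, ss_b = ss_b, ss_int = ss_int, ss_res = ss_res)
}

# Small labeled cohort with overlapping classes (non-separable), for fits
# that must stay in the interior of the parameter space.
make_overlapping_dataset <- function(n, beta, seed) {
  set.seed(seed)
  x <- matrix(rnorm(3 * n), n, 3)
  eta <- cbind(0, cbind(1, x) %*% t(beta))
  p <- exp(eta) / rowSums(exp(eta))
  u <- runif(n)
  idx <- 1 + (u > p[, 1]) + (u > p[, 1] + p[, 2])
  list(x = x, labels = c("type1", "type2a", "type2b")[idx])
}

make_records <- function(n = 6, genotype = "WT", seed = 42) {
  set.seed(seed)
  cell_records(
    cell_id = sprintf("%s-%03d", genotype, seq_len(n)),
    genotype = genotype,
    vm = rnorm(n, -80, 5),
    rm = rlnorm(n, log(300), 0.5),
    cm = rlnorm(n, log(25), 0.4)
  )
}
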