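# Inferential toolbox: two-way type II ANOVA, Sidak adjustment, exact and
# asymptotic Mann-Whitney U, phospho-intensity normalization.

#' Two-way ANOVA with type II sums of squares
#'
#' Tests both main effects and their interaction. Sums of squares follow
#' the model-comparison (type II) definition, which coincides with the
#' classical decomposition on balanced designs and handles unbalanced cell
#' counts without depending on factor order:
#' `SS_A = RSS(B) - RSS(A + B)`, `SS_B = RSS(A) - RSS(A + B)`,
#' `SS_AB = RSS(A + B) - RSS(A * B)`. Every design cell must be non-empty.
#' When the residual mean square is zero (all values identical) the
#' convention F = 0, p = 1 is reported for zero-SS effects.
#'
#' @param values numeric response.
#' @param factor_a,factor_b factor labels, >= 2 levels each.
#' @return data.frame with rows A, B, A:B, residuals and columns
#'   effect, df, sum_sq, mean_sq, statistic (F), p_value.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  values <- as.numeric(values)
  a <- factor(factor_a)
  b <- factor(factor_b)
  if (nlevels(a) < 2L || nlevels(b) < 2L) {
    stop("both factors need at least 2 levels", call. = FALSE)
  }
  counts <- table(a, b)
  if (any(counts == 0L)) {
    empty <- which(counts == 0L, arr.ind = TRUE)[1L, ]
    stop("empty design cell: ", levels(a)[empty[1L]], " x ",
         levels(b)[empty[2L]], call. = FALSE)
  }
  rss <- function(formula) {
    sum(stats::resid(stats::lm(formula, data = data.frame(y = values, a = a, b = b)))^2)
  }
  rss_a <- rss(y ~ a)
  rss_b <- rss(y ~ b)
  rss_ab <- rss(y ~ a + b)
  rss_full <- rss(y ~ a * b)
  df_a <- nlevels(a) - 1L
  df_b <- nlevels(b) - 1L
  df_int <- df_a * df_b
  df_res <- length(values) - nlevels(a) * nlevels(b)
  if (df_res < 1L) stop("residual degrees of freedom < 1", call. = FALSE)
  ss <- c(A = rss_b - rss_ab, B = rss_a - rss_ab, `A:B` = rss_ab - rss_full)
  # snap floating-point dust to exact zero (scale-relative)
  eps <- 1e-12 * max(sum((values - mean(values))^2), 1)
  ss[ss < eps] <- 0
  if (rss_full < eps) rss_full <- 0
  df <- c(df_a, df_b, df_int)
  ms <- ss / df
  ms_res <- rss_full / df_res
  f <- if (ms_res > 0) ms / ms_res else ifelse(ss > 0, Inf, 0)
  p <- ifelse(ss == 0, 1, stats::pf(f, df, df_res, lower.tail = FALSE))
  data.frame(
    effect = c("A", "B", "A:B", "residuals"),
    df = c(df, df_res),
    sum_sq = c(ss, rss_full),
    mean_sq = c(ms, ms_res),
    statistic = c(f, NA_real_),
    p_value = c(p, NA_real_),
    row.names = NULL
  )
}

#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m`, clipped to `[0, 1]`.
#'
#' @param p_values p-values in `[0, 1]`.
#' @param m number of comparisons (default: length of `p_values`).
#' @return adjusted p-values.
#' @export
sidak_adjust <- function(p_values, m = length(p_values)) {
  if (m < 1) stop("m must be at least 1", call. = FALSE)
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  pmin(1, pmax(0, 1 - (1 - p_values)^m))
}

#' Sidak-adjusted pairwise Welch comparisons
#'
#' Pairwise two-sample Welch t-tests across group levels with Sidak
#' adjustment over the number of comparisons performed — the package's
#' post-hoc comparison after ANOVA.
#'
#' @param values numeric response.
#' @param groups group labels.
#' @return data.frame (group1, group2, statistic, df, p_value, p_adjusted).
#' @export
pairwise_sidak <- function(values, groups) {
  g <- factor(groups)
  lev <- levels(g)
  if (length(lev) < 2L) stop("need at least 2 groups", call. = FALSE)
  pairs <- utils::combn(lev, 2L)
  res <- apply(pairs, 2L, function(pr) {
    tt <- stats::t.test(values[g == pr[1L]], values[g == pr[2L]])
    c(statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value)
  })
  out <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                    t(res), row.names = NULL)
  out$p_adjusted <- sidak_adjust(out$p_value, m = ncol(pairs))
  out
}

# Exact null distribution of U by enumeration of all C(nA+nB, nA)
# assignments of the (mid-)ranks to group A.
.mwu_exact_p <- function(ranks, n_a, u_obs) {
  n <- length(ranks)
  mu <- n_a * (n - n_a) / 2
  combos <- utils::combn(n, n_a)
  r_a <- colSums(matrix(ranks[combos], nrow = n_a))
  u_all <- r_a - n_a * (n_a + 1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

#' Mann-Whitney U test (exact by enumeration or asymptotic)
#'
#' The statistic is `U` for the first sample (computed from midranks, so
#' ties contribute 1/2). The exact two-sided p-value enumerates all
#' `choose(nA+nB, nA)` arrangements of the combined ranks and is the
#' probability of `|U - nA nB / 2|` at least as large as observed (the
#' symmetric-tail definition); `mode = "auto"` uses it for `nA + nB <= 14`.
#' The asymptotic p uses the normal approximation with tie correction and a
#' continuity correction.
#'
#' @param sample_a,sample_b numeric samples (non-empty).
#' @param mode `"auto"` (default), `"exact"` or `"asymptotic"`.
#' @return list: method, statistic (U for sample_a), p_value, n, mode.
#' @export
mann_whitney_u <- function(sample_a, sample_b,
                           mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  n_a <- length(sample_a)
  n_b <- length(sample_b)
  if (n_a == 0L || n_b == 0L) stop("both samples must be non-empty", call. = FALSE)
  n <- n_a + n_b
  ranks <- rank(c(sample_a, sample_b))
  u <- sum(ranks[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  use_exact <- mode == "exact" || (mode == "auto" && n <= 14L)
  if (use_exact) {
    p <- .mwu_exact_p(ranks, n_a, u)
    used <- "exact"
  } else {
    mu <- n_a * n_b / 2
    ties <- table(ranks)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sigma2)  # continuity correction
      p <- min(1, 2 * stats::pnorm(max(z, 0), lower.tail = FALSE))
    }
    used <- "asymptotic"
  }
  list(method = paste0("Mann-Whitney U (", used, ")"),
       statistic = u, p_value = p, n = c(a = n_a, b = n_b), mode = used)
}

#' Normalized phospho-signal intensity
#'
#' Phospho-receptor fluorescence `f1` normalized to the cell-marker
#' fluorescence `f2` and the measured cell area: `f1 / (f2 * area)`, in
#' 1/nm^2 when the area is in nm^2.
#'
#' @param f1 phospho-signal intensity (>= 0).
#' @param f2 marker intensity (> 0).
#' @param area_nm2 measured cell area, nm^2 (> 0).
#' @return normalized intensity, vectorized.
#' @export
normalize_phospho <- function(f1, f2, area_nm2) {
  if (any(f2 <= 0) || any(area_nm2 <= 0)) {
    stop("f2 and area must be strictly positive", call. = FALSE)
  }
  if (any(f1 < 0)) stop("f1 must be non-negative", call. = FALSE)
  f1 / (f2 * area_nm2)
}
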