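#' Two-sided Dunnett many-to-one comparisons
#'
#' Compares each test group against a single control under the equal-variance
#' one-way ANOVA model. For test group i, `T_i = (m_i - m_0) / (s sqrt(1/n_i
#' + 1/n_0))` with `s^2` the pooled within-group variance on `N - k` degrees
#' of freedom; the familywise-adjusted two-sided p-value is
#' `1 - P(max_j |T_j| <= |t_i|)` under the k-1 dimensional multivariate t
#' with the Dunnett correlation structure `rho_ij = lambda_i lambda_j`,
#' `lambda_i = sqrt(n_i / (n_i + n_0))` (evaluated with
#' [mvtnorm::pmvt()]). With a single test group this reduces exactly to the
#' two-sided pooled-variance t-test.
#'
#' @param data Tibble with `group` and `response` columns; >= 2 replicates
#'   per group.
#' @param control Name of the control group.
#' @return Tibble, one row per test group: `group`, `estimate` (mean
#'   difference from control), `se`, `statistic`, `df`, `p_unadj`, `p_adj`,
#'   `stars` (`*` <= 0.05, `**` <= 0.01, `***` <= 0.001, `****` <= 0.0001).
#' @export
dunnett_compare <- function(data, control) {
  data <- as_tibble(data)
  stopifnot(all(c("group", "response") %in% names(data)))
  if (!control %in% data$group) abort("control group not present")
  gs <- summarise(group_by(data, .data$group),
                  n = dplyr::n(), mean = mean(.data$response),
                  ss = sum((.data$response - mean(.data$response))^2),
                  .groups = "drop")
  if (nrow(gs) < 2L) abort("need at least two groups")
  if (any(gs$n < 2L)) abort("need >= 2 replicates per group")
  df <- sum(gs$n) - nrow(gs)
  s2 <- sum(gs$ss) / df
  if (s2 == 0) abort("zero within-group variance everywhere")

  ctrl <- filter(gs, .data$group == control)
  test <- filter(gs, .data$group != control)
  se <- sqrt(s2 * (1 / test$n + 1 / ctrl$n))
  tstat <- (test$mean - ctrl$mean) / se
  lambda <- sqrt(test$n / (test$n + ctrl$n))
  corr <- outer(lambda, lambda)
  diag(corr) <- 1
  k <- nrow(test)

  p_adj <- vapply(seq_len(k), function(i) {
    ti <- abs(tstat[i])
    if (k == 1L) {
      2 * stats::pt(-ti, df)
    } else {
      1 - mvtnorm::pmvt(lower = rep(-ti, k), upper = rep(ti, k),
                        df = df, corr = corr)[1]
    }
  }, numeric(1))
  p_adj <- pmin(pmax(p_adj, 0), 1)
  p_unadj <- 2 * stats::pt(-abs(tstat), df)

  tibble(group = test$group,
         estimate = test$mean - ctrl$mean,
         se = se, statistic = tstat, df = df,
         p_unadj = p_unadj, p_adj = p_adj,
         stars = significance_stars(p_adj))
}

#' Significance stars as used in figure legends
#'
#' @param p Numeric p-values.
#' @return `"****"`, `"***"`, `"**"`, `"*"` or `""` at the 1e-4, 1e-3, 0.01
#'   and 0.05 levels.
#' @export
significance_stars <- function(p) {
  cut_pts <- c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf)
  labs <- c("****", "***", "**", "*", "")
  as.character(cut(p, cut_pts, labels = labs))
}

#' Two-sided Dunnett equicoordinate critical value
#'
#' The |T| threshold at which the smallest adjusted p-value equals `alpha`;
#' used for fast familywise error-rate simulation.
#'
#' @param n_per_group Replicates per group (equal allocation), or a vector of
#'   group sizes with the control first.
#' @param k Number of test groups.
#' @param alpha Familywise level.
#' @return Critical value (numeric).
#' @export
dunnett_critical <- function(n_per_group, k, alpha = 0.05) {
  n <- if (length(n_per_group) == 1L) rep(n_per_group, k + 1L) else n_per_group
  stopifnot(length(n) == k + 1L)
  df <- sum(n) - (k + 1L)
  lambda <- sqrt(n[-1] / (n[-1] + n[1]))
  corr <- outer(lambda, lambda)
  diag(corr) <- 1
  mvtnorm::qmvt(1 - alpha, tail = "both.tails", df = df, corr = corr)$quantile
}

#' Simulate the familywise type-I error of the Dunnett procedure
#'
#' Draws Gaussian null data (all group means equal) and reports the fraction
#' of replicates in which any adjusted p-value falls at or below `alpha`,
#' i.e. in which `max_i |T_i|` exceeds the Dunnett critical value. Group
#' statistics are computed with the same pooled-variance formulas as
#' [dunnett_compare()], vectorised across replicates.
#'
#' @param n_groups Total number of groups including the control.
#' @param n_per_group Replicates per group.
#' @param n_reps Simulation replicates.
#' @param alpha Familywise level.
#' @param seed Integer seed.
#' @return Observed familywise error rate (numeric scalar).
#' @export
dunnett_fwer <- function(n_groups = 6L, n_per_group = 3L, n_reps = 1e4,
                         alpha = 0.05, seed = 1L) {
  set.seed(seed)
  k <- n_groups - 1L
  crit <- dunnett_critical(n_per_group, k, alpha)
  df <- n_groups * (n_per_group - 1L)
  # array: reps x groups x replicates-within-group
  x <- array(stats::rnorm(n_reps * n_groups * n_per_group),
             dim = c(n_reps, n_groups, n_per_group))
  m <- apply(x, c(1, 2), mean)
  ss <- apply(x, c(1, 2), function(v) sum((v - mean(v))^2))
  s2 <- rowSums(ss) / df
  se <- sqrt(s2 * (2 / n_per_group))
  tmax <- apply(abs(m[, -1, drop = FALSE] - m[, 1]), 1, max) / se
  mean(tmax > crit)
}
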