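#' @title Statistical layer
#' @name stats-layer
#' @description Mass-univariate F-regression with false-discovery-rate
#'   control, plain / partial / dependent correlations, paired parametric
#'   and rank tests, and Kruskal-Wallis, all returning a common result
#'   record. Every p-value is two-sided (5% type-I error convention).
NULL

#' Construct a statistical result record
#'
#' @param feature Feature or comparison label.
#' @param method Test name.
#' @param estimate Point estimate (slope, r, rho, difference...).
#' @param statistic Test statistic (F, t, Z, H, W...).
#' @param n Sample size.
#' @param p Two-sided p-value.
#' @param ci_low,ci_high Confidence bounds where defined.
#' @param effect_size Standardized effect size where defined.
#' @return A one-row data frame of class `stat_result`.
#' @export
stat_result <- function(feature, method, estimate, statistic, n, p,
                        ci_low = NA_real_, ci_high = NA_real_,
                        effect_size = NA_real_) {
  out <- data.frame(feature = feature, method = method,
                    estimate = estimate, statistic = statistic,
                    n = as.integer(n), p = p, q = NA_real_,
                    ci_low = ci_low, ci_high = ci_high,
                    effect_size = effect_size,
                    stringsAsFactors = FALSE)
  class(out) <- c("stat_result", class(out))
  out
}

#' Univariate regression with an F-test
#'
#' Ordinary least squares of `y` on `x` with an intercept; the regression
#' F statistic on (1, n-2) degrees of freedom equals the square of the
#' slope's t statistic.
#'
#' @param x Predictor (non-constant numeric).
#' @param y Response.
#' @param feature Label for the result record.
#' @return `stat_result` with the slope as estimate, F as statistic, and a
#'   95% slope confidence interval.
#' @export
univariate_f_regression <- function(x, y, feature = "feature") {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0) stop("degenerate predictor: x is constant")
  n <- length(x)
  # constant response: zero slope, no evidence of association
  if (stats::sd(y) == 0)
    return(stat_result(feature, "f_regression", 0, 0, n, 1, 0, 0))
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2])
  if (sm$sigma <= 1e-10 * stats::sd(y)) {
    # numerically perfect sloped fit: p underflows to 0
    fstat <- Inf
    p <- 0
    ci <- c(slope, slope)
  } else {
    fstat <- unname(sm$fstatistic[1])
    p <- stats::pf(fstat, 1, n - 2, lower.tail = FALSE)
    ci <- unname(stats::confint(fit, "x", level = 0.95))
  }
  stat_result(feature, "f_regression", slope, fstat, n, p, ci[1], ci[2])
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted q-values: monotone in the sorted order, never below
#' the input p, capped at 1, invariant to input order up to permutation.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as `p`.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pearson or Spearman correlation
#'
#' Pearson: the product-moment correlation with the t-based two-sided
#' p-value and Fisher-z 95% interval. Spearman: the same machinery applied
#' to midranks (rho with a t-based p on n-2 degrees of freedom), the usual
#' large-sample treatment for tied data.
#'
#' @param x,y Numeric vectors.
#' @param method `"pearson"` or `"spearman"`.
#' @param feature Label.
#' @return `stat_result` with r (or rho) as estimate and t as statistic.
#' @export
correlation <- function(x, y, method = c("pearson", "spearman"),
                        feature = "feature") {
  method <- match.arg(method)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stopifnot(n >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: zero variance")
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  if (abs(r) < 1 && n > 3) {
    z <- atanh(r); se <- 1 / sqrt(n - 3)
    ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  } else ci <- c(NA_real_, NA_real_)
  stat_result(feature, paste0(method, "_correlation"), r, tstat, n, p,
              ci[1], ci[2], effect_size = r)
}

#' Partial correlation controlling for one covariate
#'
#' Correlation of the residuals of `x` and `y` after regressing each on
#' `z` (variables are rank-transformed first for the Spearman flavour);
#' the p-value uses n - 3 effective degrees of freedom. Equals the
#' recursive formula (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2)).
#'
#' @param x,y Variables of interest.
#' @param z Covariate to partial out (non-constant).
#' @param method `"pearson"` or `"spearman"`.
#' @param feature Label.
#' @return `stat_result` with the partial r as estimate.
#' @export
partial_correlation <- function(x, y, z, method = c("pearson", "spearman"),
                                feature = "feature") {
  method <- match.arg(method)
  ok <- stats::complete.cases(x, y, z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- length(x)
  stopifnot(n >= 4)
  if (stats::sd(z) == 0) stop("degenerate covariate: z is constant")
  if (method == "spearman") { x <- rank(x); y <- rank(y); z <- rank(z) }
  rx <- stats::resid(stats::lm(x ~ z))
  ry <- stats::resid(stats::lm(y ~ z))
  tol <- 1e-10
  if (stats::sd(rx) <= tol * max(stats::sd(x), 1) ||
      stats::sd(ry) <= tol * max(stats::sd(y), 1))
    stop("degenerate input: a variable is collinear with the covariate")
  r <- stats::cor(rx, ry)
  df <- n - 3
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  if (abs(r) < 1 && n > 4) {
    zr <- atanh(r); se <- 1 / sqrt(n - 4)
    ci <- tanh(zr + c(-1, 1) * stats::qnorm(0.975) * se)
  } else ci <- c(NA_real_, NA_real_)
  stat_result(feature, paste0("partial_", method), r, tstat, n, p,
              ci[1], ci[2], effect_size = r)
}

#' Paired t-test
#'
#' @param x,y Paired measurements.
#' @param feature Label.
#' @return `stat_result` with the mean difference as estimate, t as
#'   statistic, Cohen's d of the differences as effect size.
#' @export
paired_t <- function(x, y, feature = "feature") {
  stopifnot(length(x) == length(y), length(x) >= 3)
  d <- x - y
  if (all(d == 0)) stop("degenerate pairs: all differences are zero")
  if (stats::sd(d) == 0) {
    # constant nonzero shift: the statistic diverges, p underflows to 0
    m <- mean(d)
    return(stat_result(feature, "paired_t", m, sign(m) * Inf, length(x), 0,
                       m, m, effect_size = sign(m) * Inf))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  stat_result(feature, "paired_t", unname(ht$estimate), unname(ht$statistic),
              length(x), ht$p.value, ht$conf.int[1], ht$conf.int[2],
              effect_size = mean(d) / stats::sd(d))
}

# Exact two-sided signed-rank p-value by dynamic programming over doubled
# midranks (exact even under ties, where the textbook tables do not apply).
.signed_rank_exact_p <- function(w2, ranks2) {
  total <- sum(ranks2)
  dist <- numeric(total + 1L)  # index s+1 holds count of sign patterns with 2W = s
  dist[1L] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), dist[seq_len(length(dist) - r)])
    dist <- dist + shifted
  }
  dist <- dist / sum(dist)
  lo <- sum(dist[seq_len(w2 + 1L)])            # P(2W <= w2)
  hi <- sum(dist[(w2 + 1L):(total + 1L)])      # P(2W >= w2)
  min(1, 2 * min(lo, hi))
}

#' Wilcoxon signed-rank test for paired data
#'
#' Zero differences are dropped; ranks of the absolute differences use
#' midranks. For n <= 25 non-zero pairs the two-sided p-value is exact,
#' computed from the full sign-flip null distribution (valid under ties);
#' above that a normal approximation with the tie-corrected variance is
#' used. The effect size is r = |Z| / sqrt(n) from the (uncorrected)
#' normal approximation in both regimes.
#'
#' @param x,y Paired measurements.
#' @param feature Label.
#' @param exact_max Largest n for the exact null distribution.
#' @return `stat_result` with V (sum of positive ranks) as statistic and
#'   the median difference as estimate.
#' @export
wilcoxon_paired <- function(x, y, feature = "feature", exact_max = 25) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0L) stop("degenerate pairs: all differences are zero")
  n <- length(d)
  rk <- rank(abs(d))
  w <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(rk)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w - mu) / sqrt(sigma2)
  if (n <= exact_max) {
    p <- .signed_rank_exact_p(as.integer(round(2 * w)), as.integer(round(2 * rk)))
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  stat_result(feature, "wilcoxon_signed_rank", stats::median(d), w, n, p,
              effect_size = abs(z) / sqrt(n))
}

#' Steiger's Z for two dependent correlations sharing a variable
#'
#' Tests whether corr(j, k) differs from corr(j, h) when both are computed
#' on the same sample and share variable j (e.g. one feature against two
#' alliance subscores). Uses Fisher transforms, the dependent-correlation
#' covariance term, and the back-transformed average correlation.
#'
#' @param r_jk,r_jh The two correlations being compared (share variable j).
#' @param r_kh Correlation between the two non-shared variables.
#' @param n Sample size (>= 4).
#' @param feature Label.
#' @return `stat_result` with Z as statistic and r_jk - r_jh as estimate.
#' @export
steiger_z <- function(r_jk, r_jh, r_kh, n, feature = "feature") {
  stopifnot(n >= 4)
  if (any(abs(c(r_jk, r_jh, r_kh)) >= 1))
    stop("correlations must lie strictly inside (-1, 1)")
  z1 <- atanh(r_jk); z2 <- atanh(r_jh)
  rbar <- tanh((z1 + z2) / 2)
  psi <- r_kh * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_kh^2)
  sbar <- psi / (1 - rbar^2)^2
  z <- (z1 - z2) * sqrt((n - 3) / (2 * (1 - sbar)))
  p <- 2 * stats::pnorm(-abs(z))
  stat_result(feature, "steiger_z", r_jk - r_jh, z, n, p)
}

#' Kruskal-Wallis rank test across groups
#'
#' H statistic with tie correction, p from the chi-squared distribution on
#' (number of groups - 1) degrees of freedom.
#'
#' @param values Numeric outcome.
#' @param groups Group labels (>= 2 non-empty groups).
#' @param feature Label.
#' @return `stat_result` with H as statistic; epsilon-squared
#'   (H - k + 1) / (n - k) as effect size.
#' @export
kruskal_wallis <- function(values, groups, feature = "feature") {
  groups <- as.factor(groups)
  k <- nlevels(droplevels(groups))
  if (k < 2) stop("design error: at least two groups are required")
  ht <- stats::kruskal.test(values, groups)
  n <- length(values)
  h <- unname(ht$statistic)
  stat_result(feature, "kruskal_wallis", NA_real_, h, n, ht$p.value,
              effect_size = max(0, (h - k + 1) / (n - k)))
}
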