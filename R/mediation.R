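#' Quasi-Bayesian causal mediation analysis
#'
#' Estimates how much of the effect of an exposure `x` on an outcome `y`
#' flows through a mediator `m`. Two least-squares fits define the paths:
#' the mediator model `m ~ x` (slope a) and the outcome model `y ~ x + m`
#' (direct slope c', mediator slope b); the total effect c comes from
#' `y ~ x`. Uncertainty in the indirect effect a*b is propagated by a
#' quasi-Bayesian approximation: coefficient vectors are drawn from the
#' asymptotic multivariate normal of each fit, the product a_i * b_i is
#' formed per draw, and the draw distribution yields a percentile
#' confidence interval and a sign-share p-value
#' (2 * min(share <= 0, share >= 0), draws at exactly zero counted in
#' both shares).
#'
#' The mediation is declared significant when the indirect-effect interval
#' excludes zero, the total effect c is significant at `alpha`, and the
#' direct effect c' is no longer significant once the mediator is in the
#' model — full mediation in the classical sense.
#'
#' @param x Exposure (non-constant numeric).
#' @param m Mediator (not perfectly collinear with `x`).
#' @param y Outcome.
#' @param iterations Number of quasi-Bayesian draws (>= 100; default 1000).
#' @param alpha Two-sided type-I error level (default 0.05).
#' @param seed Optional integer seed for the draws.
#' @param feature Label for the exposure feature.
#' @return A `mediation_result` list: `a`, `b`, `c`, `c_prime`, `indirect`
#'   (= a*b from the point fits), `ci_low`, `ci_high`, `p_indirect`,
#'   `p_total`, `p_direct`, `iterations`, `significant`, `n`, `feature`.
#' @export
mediate <- function(x, m, y, iterations = 1000, alpha = 0.05, seed = NULL,
                    feature = "exposure") {
  stopifnot(length(x) == length(m), length(m) == length(y))
  ok <- stats::complete.cases(x, m, y)
  x <- x[ok]; m <- m[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10) stop("mediation needs at least 10 complete cases")
  if (iterations < 100) stop("iterations must be at least 100")
  if (stats::sd(x) == 0) stop("degenerate exposure: x is constant")
  if (abs(stats::cor(x, m)) >= 1 - 1e-12)
    stop("collinearity: mediator is a perfect linear function of the exposure")
  local_rng(seed)

  fit_m <- stats::lm(m ~ x)
  fit_y <- stats::lm(y ~ x + m)
  fit_c <- stats::lm(y ~ x)
  a <- unname(stats::coef(fit_m)["x"])
  b <- unname(stats::coef(fit_y)["m"])
  c_prime <- unname(stats::coef(fit_y)["x"])
  c_total <- unname(stats::coef(fit_c)["x"])
  p_total <- summary(fit_c)$coefficients["x", 4]
  p_direct <- summary(fit_y)$coefficients["x", 4]

  draw_a <- MASS::mvrnorm(iterations, stats::coef(fit_m), stats::vcov(fit_m))[, "x"]
  draw_b <- MASS::mvrnorm(iterations, stats::coef(fit_y), stats::vcov(fit_y))[, "m"]
  ab <- draw_a * draw_b
  ci <- unname(stats::quantile(ab, c(alpha / 2, 1 - alpha / 2)))
  p_ind <- min(1, 2 * min(mean(ab <= 0), mean(ab >= 0)))

  structure(list(feature = feature, a = a, b = b, c = c_total,
                 c_prime = c_prime, indirect = a * b,
                 ci_low = ci[1], ci_high = ci[2], p_indirect = p_ind,
                 p_total = p_total, p_direct = p_direct,
                 iterations = as.integer(iterations), alpha = alpha, n = n,
                 significant = (ci[1] > 0 || ci[2] < 0) &&
                   p_total < alpha && p_direct >= alpha),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Quasi-Bayesian mediation (", x$iterations, " draws, n = ", x$n, ")\n",
      sep = "")
  cat(sprintf("  paths: a = %.4g, b = %.4g, c = %.4g, c' = %.4g\n",
              x$a, x$b, x$c, x$c_prime))
  cat(sprintf("  indirect a*b = %.4g, %.0f%% CI [%.4g, %.4g], p = %.4g\n",
              x$indirect, 100 * (1 - x$alpha), x$ci_low, x$ci_high,
              x$p_indirect))
  cat("  significant mediation:", x$significant, "\n")
  invisible(x)
}
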