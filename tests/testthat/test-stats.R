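test_that("univariate F-regression matches the closed-form OLS oracle", {
  r0 <- univariate_f_regression(c(1, 2, 3), c(5, 5, 5))
  expect_equal(r0$estimate, 0)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)

  set.seed(51)
  x <- rnorm(10)
  r1 <- univariate_f_regression(x, x)
  expect_equal(r1$p, 0)
  expect_equal(r1$estimate, 1)

  expect_error(univariate_f_regression(rep(2, 5), rnorm(5)), "constant")

  # explicit matrix-formula oracle: slope, t, F = t^2
  for (rep in 1:20) {
    n <- 30
    x <- rnorm(n); y <- 0.4 * x + rnorm(n)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    resid <- y - mean(y) - slope * (x - mean(x))
    se <- sqrt(sum(resid^2) / (n - 2) / sum((x - mean(x))^2))
    tstat <- slope / se
    r <- univariate_f_regression(x, y)
    expect_equal(r$estimate, slope, tolerance = 1e-12)
    expect_equal(r$statistic, tstat^2, tolerance = 1e-10)
    expect_equal(r$p, 2 * pt(-abs(tstat), n - 2), tolerance = 1e-12)
  }
})

test_that("F-regression p-values are uniform under the null", {
  set.seed(52)
  p <- replicate(2000, univariate_f_regression(rnorm(20), rnorm(20))$p)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("BH adjustment matches direct step-up computation and its invariants", {
  # direct step-up: q_(i) = min over j >= i of p_(j) * m / j
  bh_oracle <- function(p) {
    m <- length(p); o <- order(p); q <- numeric(m)
    sorted <- p[o] * m / seq_len(m)
    q[o] <- rev(cummin(rev(sorted)))
    pmin(q, 1)
  }
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(fdr_adjust(0.5), 0.5)
  expect_error(fdr_adjust(c(0.2, 1.7)), "\\[0, 1\\]")
  set.seed(53)
  for (rep in 1:100) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- fdr_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-14)
    expect_true(all(q >= p))
    perm <- sample(length(p))
    expect_equal(fdr_adjust(p[perm]), q[perm])
  }
})

test_that("correlations behave at the extremes and converge to the truth", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(correlation(x, x)$estimate, 1)
  expect_equal(correlation(x, rev(sort(x)) [rank(x)], "spearman")$estimate, -1)
  expect_error(correlation(x, rep(1, 5)), "zero variance")

  set.seed(54)
  n <- 10000
  z <- rnorm(n); x <- z + rnorm(n); y <- z + rnorm(n)  # true rho = 0.5
  expect_lt(abs(correlation(x, y)$estimate - 0.5), 0.03)

  # spearman equals pearson on midranks
  xx <- c(1, 2, 2, 5, 7, 7, 7); yy <- c(3, 1, 4, 4, 9, 2, 6)
  expect_equal(correlation(xx, yy, "spearman")$estimate,
               cor(rank(xx), rank(yy)))
})

test_that("partial correlation matches the recursive closed form", {
  set.seed(55)
  # z orthogonal to x and y by construction: residualize both against z
  z <- rnorm(40)
  x0 <- rnorm(40); y0 <- 0.5 * x0 + rnorm(40)
  x <- resid(lm(x0 ~ z)); y <- resid(lm(y0 ~ z))
  plain <- correlation(x, y)$estimate
  expect_equal(partial_correlation(x, y, z)$estimate, plain, tolerance = 1e-10)

  # y identical to z: the residual of y is zero-variance
  expect_error(partial_correlation(rnorm(20), z2 <- rnorm(20), z2),
               "collinear")

  for (rep in 1:30) {
    n <- 25
    z <- rnorm(n); x <- 0.6 * z + rnorm(n); y <- -0.4 * z + rnorm(n)
    rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
    oracle <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    expect_equal(partial_correlation(x, y, z)$estimate, oracle,
                 tolerance = 1e-10)
  }
  expect_error(partial_correlation(rnorm(10), rnorm(10), rep(1, 10)),
               "constant")
})

test_that("paired t-test handles null, degenerate and shifted designs", {
  y <- c(0, 0, 0); x <- y + c(1, 1, -2)
  r <- paired_t(x, y)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  expect_error(paired_t(1:5, 1:5), "all differences are zero")

  set.seed(56)
  a <- rnorm(20)
  r2 <- paired_t(a + 3, a)   # constant shift: p underflows
  expect_lt(r2$p, 1e-12)
  expect_equal(r2$estimate, 3)

  b <- rnorm(20)
  r3 <- paired_t(a, b)
  ht <- t.test(a, b, paired = TRUE)
  expect_equal(r3$statistic, unname(ht$statistic))
  expect_equal(r3$p, ht$p.value)
})

test_that("signed-rank test is exact for small n, including the all-positive case", {
  # five equal positive differences: 2 / 2^5 by sign-pattern enumeration
  r <- wilcoxon_paired(c(2, 2, 2, 2, 2), rep(0, 5))
  expect_equal(r$p, 2 / 32)

  # full enumeration oracle on distinct ranks
  set.seed(57)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    d <- sample(1:50, n) * sample(c(-1, 1), n, replace = TRUE)
    w_obs <- sum(rank(abs(d))[d > 0])
    ws <- vapply(0:(2^n - 1), function(mask) {
      signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
      sum(rank(abs(d))[signs])
    }, numeric(1))
    p_oracle <- min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
    r <- wilcoxon_paired(d, rep(0, n))
    expect_equal(r$statistic, w_obs)
    expect_equal(r$p, p_oracle, tolerance = 1e-12)
    # cross-check against the standard implementation (tie-free, zero-free)
    expect_equal(r$p, wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
  }

  expect_error(wilcoxon_paired(1:4, 1:4), "all differences are zero")
})

test_that("signed-rank normal approximation applies tie corrections above the exact limit", {
  set.seed(58)
  x <- round(rnorm(40, 0.3), 1); y <- round(rnorm(40), 1)
  d <- (x - y)[x != y]
  n <- length(d); rk <- rank(abs(d)); w <- sum(rk[d > 0])
  ties <- table(rk)
  z <- (w - n * (n + 1) / 4) /
    sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48)
  r <- wilcoxon_paired(x, y)
  expect_equal(r$p, 2 * pnorm(-abs(z)), tolerance = 1e-12)
  expect_equal(r$effect_size, abs(z) / sqrt(n), tolerance = 1e-12)
})

test_that("Steiger's Z compares dependent correlations sharing one variable", {
  expect_equal(steiger_z(0.5, 0.5, 0.3, 30)$statistic, 0)
  expect_equal(steiger_z(0.5, 0.5, 0.3, 30)$p, 1)
  expect_equal(steiger_z(0.6, 0.3, 0.5, 28)$statistic,
               -steiger_z(0.3, 0.6, 0.5, 28)$statistic)
  expect_error(steiger_z(1, 0.5, 0.2, 30), "strictly inside")

  # independent transcription of the published formula as oracle
  oracle <- function(r_jk, r_jh, r_kh, n) {
    z1 <- 0.5 * log((1 + r_jk) / (1 - r_jk))
    z2 <- 0.5 * log((1 + r_jh) / (1 - r_jh))
    zbar <- (z1 + z2) / 2
    rbar <- (exp(2 * zbar) - 1) / (exp(2 * zbar) + 1)
    num <- r_kh * (1 - rbar^2 - rbar^2) - 0.5 * rbar^2 *
      (1 - rbar^2 - rbar^2 - r_kh^2)
    s <- num / ((1 - rbar^2)^2)
    (z1 - z2) * sqrt((n - 3) / (2 - 2 * s))
  }
  expect_equal(steiger_z(0.6, 0.3, 0.5, 28)$statistic,
               oracle(0.6, 0.3, 0.5, 28), tolerance = 1e-12)
  set.seed(59)
  for (rep in 1:100) {
    # draw valid (positive-definite) correlation triples from random data
    d <- matrix(rnorm(60), 20) %*% matrix(rnorm(9), 3)
    d <- d + matrix(rnorm(60, 0, 0.5), 20)
    r <- cor(d)
    expect_equal(steiger_z(r[1, 2], r[1, 3], r[2, 3], 20)$statistic,
                 oracle(r[1, 2], r[1, 3], r[2, 3], 20), tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis H matches the brute-force rank formula and is label invariant", {
  h_oracle <- function(values, groups) {
    r <- rank(values); n <- length(values)
    h <- 12 / (n * (n + 1)) *
      sum(tapply(r, groups, function(g) length(g) * mean(g)^2)) - 3 * (n + 1)
    ties <- table(values)
    h / (1 - sum(ties^3 - ties) / (n^3 - n))
  }
  v <- c(1, 2, 3, 4); g <- c("a", "a", "b", "b")
  expect_equal(kruskal_wallis(v, g)$statistic, h_oracle(v, g))

  set.seed(60)
  for (rep in 1:50) {
    v <- sample(1:20, 24, replace = TRUE)
    g <- sample(letters[1:3], 24, replace = TRUE)
    if (length(unique(g)) < 2) next
    expect_equal(kruskal_wallis(v, g)$statistic, h_oracle(v, g),
                 tolerance = 1e-10)
  }

  # permuting labels of equal-size identical-value groups leaves H unchanged
  v2 <- c(5, 7, 5, 7);
  expect_equal(kruskal_wallis(v2, c("a", "a", "b", "b"))$statistic,
               kruskal_wallis(v2, c("b", "b", "a", "a"))$statistic)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "two groups")
})

test_that("Kruskal-Wallis type-I error is calibrated under the null", {
  set.seed(61)
  rej <- mean(replicate(1000, {
    kruskal_wallis(rnorm(30), rep(c("a", "b"), 15))$p < 0.05
  }))
  expect_gte(rej, 0.03); expect_lte(rej, 0.07)
})
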