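# group_stats: t / KS tests, paired permutation machinery, Bonferroni,
# Cohen's d, rating correlations, and multiple correlation variants.

test_that("ttest2 matches the textbook pooled-variance formula", {
  same <- ttest2(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  expect_lt(ttest2(c(1, 2, 3), c(11, 12, 13))$p, 0.01)

  a <- c(1.2, 3.4, 2.2); b <- c(4.1, 5.0, 3.3)
  tt <- ttest2(a, b)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(tt$statistic, t_hand, tolerance = 1e-12)
  expect_equal(tt$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)
  expect_error(ttest2(1, c(1, 2)), ">= 2")
})

test_that("kstest2 equals a brute-force ECDF sweep", {
  set.seed(50)
  a <- rnorm(40); b <- rnorm(35, 0.5)
  D <- kstest2(a, b)$statistic
  grid <- sort(c(a, b))
  D_oracle <- max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
  expect_equal(D, D_oracle, tolerance = 1e-12)

  expect_equal(kstest2(a, a)$statistic, 0)
  expect_equal(kstest2(rnorm(20), rnorm(20) + 100)$statistic, 1)
  expect_error(kstest2(1:3, 1:10), ">= 5")
})

test_that("paired permutation test: ties, floor, exhaustive equivalence", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(permutation_test(x, x)$p, 1)

  # Monte-Carlo add-one floor at 1/(n_perm + 1)
  set.seed(51)
  a <- rnorm(20) + 50; b <- rnorm(20)
  mc <- permutation_test(a, b, n_perm = 1000, seed = 2)
  expect_identical(mc$method, "monte-carlo")
  expect_equal(mc$p, 1 / 1001)

  # exhaustive path: exact p equals an independent bit-mask enumeration
  set.seed(52)
  for (r in 1:5) {
    a <- rnorm(8); b <- rnorm(8, 0.8)
    res <- permutation_test(a, b, n_perm = 10000, seed = 1)
    expect_identical(res$method, "exhaustive")
    d <- a - b; n <- 8
    cnt <- 0
    for (mask in 0:(2^n - 1)) {
      s <- ifelse(bitwAnd(mask, 2^(0:(n - 1))) > 0, 1, -1)
      if (abs(mean(s * d)) >= abs(mean(d)) - 1e-12) cnt <- cnt + 1
    }
    expect_equal(res$p, cnt / 2^n)
  }

  # Monte-Carlo converges to the exhaustive value
  set.seed(53)
  a <- rnorm(12); b <- rnorm(12, 0.6)
  exact <- permutation_test(a, b, n_perm = 5000)$p       # 2^12 <= 5000
  mc2 <- permutation_test(a, b, n_perm = 4000, seed = 7) # forced MC path
  expect_lt(abs(mc2$p - exact), 3 * sqrt(exact * (1 - exact) / 4000) + 1e-3)
  expect_error(permutation_test(a, b, n_perm = 50), "100")
  expect_error(permutation_test(1:3, 1:4), "equal length")
})

test_that("bonferroni multiplies and caps at one", {
  expect_equal(bonferroni(0.03, 1), 0.03)
  expect_equal(bonferroni(0.004, 15), 0.06)
  expect_equal(bonferroni(c(0.2, 0.5), 10), c(1, 1))
  expect_error(bonferroni(c(0.1, 0.2), 1), "at least")
})

test_that("cohens_d matches the pooled-SD formula", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- c(0, 2); b <- a + sqrt(2)                # shift = pooled SD = sqrt(2)
  expect_equal(cohens_d(b, a), 1, tolerance = 1e-12)

  set.seed(54)
  x <- rnorm(15); y <- rnorm(20, 0.4)
  sp <- sqrt((14 * var(x) + 19 * var(y)) / 33)
  expect_equal(cohens_d(x, y), (mean(x) - mean(y)) / sp, tolerance = 1e-12)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled")
})

test_that("energy-rating correlation equals the covariance formula", {
  e <- c(1, 2, 3, 4, 5)
  expect_equal(energy_rating_correlation(e, 3 * e + 1)$statistic, 1)

  set.seed(55)
  x <- rnorm(24); y <- rnorm(24)
  r <- energy_rating_correlation(x, y)$statistic
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r, r_hand, tolerance = 1e-12)

  # null: |r| rarely large at n = 24
  hits <- sapply(1:100, function(s) {
    set.seed(s); abs(energy_rating_correlation(rnorm(24), rnorm(24))$statistic)
  })
  expect_gte(mean(hits < 0.5), 0.95)
  expect_error(energy_rating_correlation(1:3, 1:3), "4 pairs")
})

test_that("multiple correlation equals sqrt of the OLS R^2", {
  set.seed(56)
  X <- matrix(rnorm(24 * 3), 24, 3)
  y <- rnorm(24)
  mc <- multiple_correlation(X, y)
  R2_oracle <- summary(lm(y ~ X))$r.squared
  expect_equal(mc$R2, R2_oracle, tolerance = 1e-10)
  expect_equal(mc$statistic, sqrt(R2_oracle), tolerance = 1e-10)
  f_oracle <- summary(lm(y ~ X))$fstatistic
  expect_equal(mc$F, unname(f_oracle[1]), tolerance = 1e-8)

  # single predictor reduces to |Pearson r|
  expect_equal(multiple_correlation(X[, 1, drop = FALSE], y)$statistic,
               abs(cor(X[, 1], y)), tolerance = 1e-12)
  # exact linear combination
  expect_equal(multiple_correlation(X, X %*% c(1, -2, 0.5))$statistic, 1,
               tolerance = 1e-8)
  expect_error(multiple_correlation(cbind(X[, 1], X[, 1]), y), "singular")
  expect_error(multiple_correlation(X[1:3, ], y[1:3]), "observations")
})

test_that("indirect multiple correlation re-represents through harmonics", {
  set.seed(57)
  n_obs <- 24; q <- 3; H <- 200
  E <- matrix(rnorm(n_obs * H), n_obs, H)
  X <- matrix(rnorm(n_obs * q), n_obs, q)

  # response identical to a predictor stays perfectly correlated
  res <- indirect_multiple_correlation(X, X[, 2], E)
  expect_equal(res$statistic, 1, tolerance = 1e-8)
  expect_match(res$warning, "nominal")

  # re-representation with a single harmonic: correlation vector is cor(v, v)
  expect_equal(as.numeric(cor(matrix(X[, 1], ncol = 1), X[, 1])), 1)

  # distinct inputs stay distinct (injectivity on seeded inputs) and the
  # resolution does not degrade from 30 to 200 harmonics
  y <- rnorm(n_obs)
  rep_d <- function(h) {
    r1 <- as.numeric(cor(E[, 1:h], X[, 1]))
    r2 <- as.numeric(cor(E[, 1:h], y))
    sqrt(sum((r1 - r2)^2))
  }
  expect_gt(rep_d(30), 0)
  expect_gte(rep_d(200), rep_d(30))
  expect_error(indirect_multiple_correlation(X, y, E, n_harmonics = 4),
               "networks \\+ 2")
})
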