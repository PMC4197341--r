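test_that("T1 collapse counts variants with at least one rare allele", {
  r <- make_region(rbind(c(0L, 1L, 2L, 0L, 1L),
                         c(0L, 0L, 0L, 0L, 0L),
                         c(NA, 1L, 0L, 0L, 0L)),
                   maf = rep(0.01, 5))
  expect_equal(as.vector(t1_collapse(r)), c(3L, 0L, 1L))
  expect_equal(attr(t1_collapse(r), "scheme"), "t1_count")
})

test_that("MB weighted score matches hand arithmetic", {
  # n = 100, single variant p = 0.005, dosage 2:
  # w = sqrt(100 * 0.005 * 0.995) = sqrt(0.4975); s = 2 / w
  dos <- matrix(c(2L, rep(0L, 99)), ncol = 1)
  r <- make_region(dos, maf = 0.005)
  st <- data.frame(maf_hat = 0.005, missing_frac = 0, allele_count = 2L,
                   folded = FALSE)
  s <- mb_score(r, stats = st, n = 100)
  expect_equal(s[1], 2 / sqrt(0.4975), tolerance = 1e-10)
  expect_equal(round(s[1], 4), 2.8355)
  expect_equal(s[2], 0)
  # two variants with equal p and dosages (1,1) equal one dosage-2 variant
  dos2 <- rbind(c(1L, 1L), matrix(0L, 4, 2))
  r2 <- make_region(dos2, maf = c(0.1, 0.1))
  st2 <- data.frame(maf_hat = c(0.1, 0.1), missing_frac = 0,
                    allele_count = 1L, folded = FALSE)
  s2 <- mb_score(r2, stats = st2, n = 5)
  expect_equal(s2[1], 2 / sqrt(5 * 0.1 * 0.9))
  expect_error(mb_score(r2, stats = data.frame(maf_hat = c(0, 0.1))),
               "degenerate weight")
})

test_that("burden regression matches lm and behaves under transformations", {
  set.seed(61)
  n <- 120
  s <- rpois(n, 1.2)
  Z <- cbind(1, rnorm(n))
  y <- 0.5 + 0.3 * Z[, 2] + 0.2 * s + rnorm(n)
  attr(s, "scheme") <- "t1_count"
  res <- burden_regression(s, y, Z)
  fit <- summary(lm(y ~ Z[, 2] + s))
  expect_equal(res$p_value, fit$coefficients["s", "Pr(>|t|)"],
               tolerance = 1e-10)
  expect_equal(res$statistic, fit$coefficients["s", "t value"],
               tolerance = 1e-10)
  # location shift of y changes nothing (intercept present)
  res_shift <- burden_regression(s, y + 57, Z)
  expect_equal(res_shift$p_value, res$p_value, tolerance = 1e-10)
  # joint row permutation changes nothing
  perm <- sample(n)
  s_p <- s[perm]; attr(s_p, "scheme") <- "t1_count"
  res_perm <- burden_regression(s_p, y[perm], Z[perm, ])
  expect_equal(res_perm$p_value, res$p_value, tolerance = 1e-10)
  # perfect fit drives p to zero
  res_perfect <- burden_regression(s, 2 * s + 1)
  expect_lt(res_perfect$p_value, 1e-12)
  expect_error(burden_regression(rep(1L, n), y), "collinear")
})

test_that("equal-MAF 0/1 regions give identical T1 and MB p-values", {
  set.seed(62)
  dos <- matrix(rbinom(200 * 8, 1, 0.05), 200, 8)
  r <- make_region(dos, maf = rep(0.05, 8))
  st <- data.frame(maf_hat = rep(0.05, 8), missing_frac = 0,
                   allele_count = colSums(dos), folded = FALSE)
  y <- rnorm(200)
  p_t1 <- burden_regression(t1_collapse(r), y)$p_value
  p_mb <- burden_regression(mb_score(r, stats = st), y)$p_value
  expect_equal(p_mb, p_t1, tolerance = 1e-10)
})

test_that("kernel weights follow the Beta(1,25) squared-density convention", {
  expect_equal(skat_weights(1e-9), (25 * (1 - 1e-9)^24)^2, tolerance = 1e-6)
  expect_equal(skat_weights(0.01), (25 * 0.99^24)^2)
  expect_equal(round(sqrt(skat_weights(0.01)), 3), 19.642)
  expect_equal(skat_weights(c(0.1, 0.3), 1, 1), c(1, 1))
  expect_equal(skat_weights(0.01, squared = FALSE), 25 * 0.99^24)
  expect_error(skat_weights(0), "maf_hat")
  # rarer variants get larger weights
  expect_true(all(diff(skat_weights(c(0.01, 0.005, 0.001))) > 0))
})

test_that("single-variant kernel test equals the closed-form score test", {
  set.seed(63)
  n <- 300
  g <- rbinom(n, 2, 0.05)
  y <- rnorm(n) + 0.1 * g
  Z <- cbind(1, rnorm(n))
  r <- make_region(matrix(g, ncol = 1), maf = 0.05)
  res <- skat_test(y, r, Z = Z, weights = 1)
  # oracle: two-sided normal score test with the same residual variance
  Q <- qr.Q(qr(Z))
  e <- y - Q %*% crossprod(Q, y)
  g_t <- g - Q %*% crossprod(Q, g)
  sigma2 <- sum(e^2) / (n - 2)
  z_stat <- sum(g * e) / sqrt(sigma2 * sum(g_t^2))
  expect_equal(res$p_value, 2 * pnorm(-abs(z_stat)), tolerance = 1e-6)
})

test_that("kernel test is invariant to variant order and weight scale", {
  set.seed(64)
  sp <- sample_region_spec(12, maf_range = c(0.02, 0.05),
                           missing_beta = NULL, seed = 65)
  r <- simulate_genotypes(sp, 400, seed = 66)
  y <- rnorm(400)
  w <- skat_weights(compute_variant_stats(r)$maf_hat)
  p0 <- skat_test(y, r, weights = w)$p_value
  perm <- sample(12)
  p_perm <- skat_test(y, ccrvsim:::subset_region(r, perm),
                      weights = w[perm])$p_value
  expect_equal(p_perm, p0, tolerance = 1e-9)
  p_scaled <- skat_test(y, r, weights = 7.3 * w)$p_value
  expect_equal(p_scaled, p0, tolerance = 1e-9)
  # orthogonal residuals give Q = 0, p = 1
  r0 <- make_region(matrix(0L, 50, 3), maf = rep(0.01, 3))
  res0 <- skat_test(rnorm(50), r0, weights = rep(1, 3))
  expect_equal(res0$p_value, 1)
  expect_equal(res0$statistic, 0)
})

test_that("kernel analytic p-value agrees with its permutation estimate", {
  set.seed(67)
  sp <- sample_region_spec(15, maf_range = c(0.01, 0.05),
                           missing_beta = NULL, seed = 68)
  r <- simulate_genotypes(sp, 200, seed = 69)
  y <- rnorm(200)
  res <- skat_test(y, r, n_perm = 2000, seed = 70)
  mc_sd <- sqrt(res$p_value * (1 - res$p_value) / 2000)
  expect_lt(abs(res$p_value_perm - res$p_value), 3 * mc_sd + 1e-3)
})

test_that("score test reproduces the three-individual worked example", {
  r <- make_region(matrix(c(0L, 1L, 2L), ncol = 1), maf = 0.25)
  res <- scoreseq_test(c(1, 2, 3), r, xi = 1)
  expect_equal(res$details$U, 2)
  expect_equal(res$details$sigma2, 2 / 3)
  expect_equal(res$details$V, 4 / 3)
  expect_equal(res$statistic, sqrt(3), tolerance = 1e-10)
})

test_that("score test is scale invariant in xi and degenerate-safe", {
  set.seed(71)
  sp <- sample_region_spec(10, missing_beta = NULL, seed = 72)
  r <- simulate_genotypes(sp, 300, seed = 73)
  y <- rnorm(300)
  t1 <- scoreseq_test(y, r, xi = rep(1, 10))
  t2 <- scoreseq_test(y, r, xi = rep(3.7, 10))
  expect_equal(t2$statistic, t1$statistic, tolerance = 1e-10)
  expect_equal(t2$p_value, t1$p_value, tolerance = 1e-10)
  # location shift of y changes nothing
  t3 <- scoreseq_test(y + 11, r, xi = rep(1, 10))
  expect_equal(t3$p_value, t1$p_value, tolerance = 1e-10)
  # xi = 0 collapses to no information
  t0 <- scoreseq_test(y, r, xi = rep(0, 10))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  # mb-style weights run and differ in general
  tmb <- scoreseq_test(y, r, xi = "mb")
  expect_true(is.finite(tmb$statistic))
})

test_that("score-test permutation p agrees with the asymptotic p under the null", {
  set.seed(74)
  sp <- sample_region_spec(10, maf_range = c(0.01, 0.05),
                           missing_beta = NULL, seed = 75)
  r <- simulate_genotypes(sp, 500, seed = 76)
  y <- rnorm(500)
  res <- scoreseq_test(y, r, n_perm = 10000, seed = 77)
  mc_sd <- sqrt(res$p_value * (1 - res$p_value) / 10000)
  expect_lt(abs(res$p_value_perm - res$p_value), 3 * mc_sd + 2e-3)
  expect_gte(res$p_value_perm, 1 / 10001)
})
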