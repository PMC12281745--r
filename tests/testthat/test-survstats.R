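test_that("KM without censoring reproduces the empirical survival function", {
  times <- c(1, 2, 3, 4, 5, 6)
  km <- km_logrank(times, rep(TRUE, 6), rep(c("a", "b"), each = 3))
  expect_equal(km$medians[["a"]], 2)   # sample median of {1,2,3} reached at S<=0.5
  f <- km$fits[["a"]]
  expect_equal(f$surv, 1 - cumsum(rep(1 / 3, 3)), tolerance = 1e-12)
  # identical groups: p ~ 1, HR ~ 1
  km2 <- km_logrank(rep(times, 2), rep(TRUE, 12),
                    rep(c("a", "b"), each = 6))
  expect_gt(km2$logrank_p, 0.9)
  expect_equal(km2$hr, 1, tolerance = 1e-6)
})

test_that("exponential rate ratios are recovered as hazard ratios", {
  set.seed(61)
  t1 <- rexp(500, 1); t2 <- rexp(500, 2)
  g <- factor(rep(c("slow", "fast"), each = 500), levels = c("slow", "fast"))
  km <- km_logrank(c(t1, t2), rep(TRUE, 1000), g)
  expect_lt(abs(km$hr - 2), 0.2)
  expect_lt(km$logrank_p, 1e-10)
})

test_that("Cox coefficient matches brute-force partial-likelihood maximization", {
  x <- c(0.5, -1.2, 0.3, 2.0, -0.7, 1.1)
  times <- c(3, 9, 5, 1, 12, 7)
  events <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  fit <- cox_fit(matrix(x, 6, 1, dimnames = list(NULL, "x")),
                 times, events, ties = "efron")
  brute <- optimize(function(b) -cox_partial_loglik(b, x, times, events),
                    c(-10, 10), tol = 1e-10)
  expect_lt(abs(fit$coef - brute$minimum), 1e-6)
})

test_that("tie methods coincide on tie-free data", {
  set.seed(67)
  x <- rnorm(30); times <- rexp(30, exp(0.5 * x)); events <- rep(TRUE, 30)
  X <- matrix(x, dimnames = list(NULL, "x"))
  co <- vapply(c("efron", "exact", "breslow"), function(m)
    cox_fit(X, times, events, ties = m)$coef, numeric(1))
  expect_lt(max(co) - min(co), 1e-8)
  # auto mode picks exact for small tie groups
  times_t <- rep(1:10, 3)
  fit_auto <- cox_fit(X, times_t, events, ties = "auto")
  expect_equal(attr(fit_auto, "ties_used"), "exact")
})

test_that("planted protective hazard is recovered with nominal coverage", {
  hits <- replicate(20, {
    seed <- sample.int(1e6, 1)
    freq <- matrix(runif(500), 500, 1, dimnames = list(NULL, "HG1"))
    out <- simulate_outcomes(freq, c(HG1 = log(0.58)), 0.01, 0.1,
                             seed = seed)
    cx <- cox_fit(freq, out$ttf2_days, out$ttf2_event)
    c(sign_ok = cx$coef < 0,
      covered = cx$ci_lo <= 0.58 && cx$ci_hi >= 0.58)
  })
  expect_gte(mean(hits["sign_ok", ]), 0.95)
  expect_gte(mean(hits["covered", ]), 0.9)
})

test_that("Spearman matrix equals the rank-then-Pearson oracle", {
  set.seed(71)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  X[, 2] <- X[, 1]^3              # monotone map: rho exactly 1
  sm <- spearman_matrix(X)
  oracle <- cor(apply(X, 2, rank))
  expect_equal(unname(sm$rho), unname(oracle), tolerance = 1e-12)
  expect_equal(sm$rho["a", "b"], 1)
  Xc <- cbind(X, d = rep(1, 20))
  sm2 <- spearman_matrix(Xc)
  expect_equal(sm2$constant_columns, "d")
  expect_true(all(is.na(sm2$rho["d", ])))
})

test_that("independent columns rarely show strong rank correlation", {
  hits <- replicate(40, {
    x <- rnorm(100); y <- rnorm(100)
    abs(cor(x, y, method = "spearman")) < 0.3
  })
  expect_gte(mean(hits), 0.95)
})

test_that("D'Agostino-Pearson matches an independent reference implementation", {
  # reference values computed with scipy.stats.normaltest 1.17
  x <- c(0.304717, -1.039984, 0.750451, 0.940565, -1.951035, -1.30218,
         0.12784, -0.316243, -0.016801, -0.853044, 0.879398, 0.777792,
         0.066031, 1.127241, 0.467509, -0.859292, 0.368751, -0.958883,
         0.87845, -0.049926)
  r <- dagostino_pearson(x)
  expect_equal(r$statistic, 1.6864870246395252, tolerance = 1e-9)
  expect_equal(r$p_value, 0.43031253345223686, tolerance = 1e-9)
  y <- c(1.247386, 0.223576, 1.83797, 1.227086, 0.655796, 0.417087,
         0.45332, 0.077077, 0.179632, 0.68532, 0.38868, 1.264207,
         0.708491, 0.23793, 0.461088, 0.641557, 0.343833, 0.321911,
         0.878915, 0.296947, 1.333702, 1.390864, 1.084083, 0.073028,
         1.134068, 1.354338, 1.12204, 0.280049, 0.320936, 0.165736)
  r2 <- dagostino_pearson(y)
  expect_equal(r2$statistic, 3.3424204612532122, tolerance = 1e-9)
  expect_equal(r2$p_value, 0.18801938107774643, tolerance = 1e-9)
  expect_error(dagostino_pearson(rnorm(5)), "n >= 8")
})

test_that("Fisher's exact test equals hypergeometric enumeration", {
  tab <- matrix(c(8, 2, 1, 9), 2, byrow = TRUE)
  r <- compare_groups(tab, design = "categorical")
  expect_equal(r$p_value, fisher_oracle(tab), tolerance = 1e-12)
  set.seed(73)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 6), 2)
    expect_equal(compare_groups(tab, design = "categorical")$p_value,
                 fisher_oracle(tab), tolerance = 1e-12)
  }
})

test_that("two-group branch gates on normality and has power", {
  set.seed(79)
  # same normal distribution: t branch selected, p not small
  x <- rnorm(60); g <- rep(c("a", "b"), 30)
  r <- compare_groups(x, g, "two_group")
  expect_equal(r$test, "t")
  expect_gt(r$p_value, 0.01)
  # exponential data routes to Mann-Whitney
  r2 <- compare_groups(rexp(60), g, "two_group")
  expect_equal(r2$test, "mann_whitney")
  # small groups default to nonparametric, flagged
  r3 <- compare_groups(rnorm(10), rep(c("a", "b"), 5), "two_group")
  expect_true(r3$small_sample)
  expect_equal(r3$test, "mann_whitney")
  # power: N(0,1) vs N(1,1) at n = 50/50 rejects nearly always
  rej <- replicate(200, {
    v <- c(rnorm(50), rnorm(50, 1))
    compare_groups(v, rep(c("a", "b"), each = 50), "two_group")$p_value < 0.05
  })
  expect_gt(mean(rej), 0.99)
})

test_that("multi-group, paired and ANOVA branches return sane structures", {
  set.seed(83)
  v <- c(rnorm(20), rnorm(20, 2), rnorm(20))
  g <- rep(c("a", "b", "c"), each = 20)
  r <- compare_groups(v, g, "multi_group")
  expect_equal(r$test, "anova_sidak")
  expect_lt(r$p_value, 0.001)
  expect_equal(nrow(r$pairwise), 3)
  expect_true(all(r$pairwise$p_sidak >= r$pairwise$p_raw - 1e-12))
  rp <- compare_groups(list(rnorm(15), rnorm(15, 1)), design = "paired")
  expect_equal(rp$test, "wilcoxon_signed_rank")
})

test_that("ROUT flags gross outliers but spares clean Gaussians", {
  set.seed(89)
  frac <- replicate(100, mean(rout_outliers(rnorm(50), Q = 0.02)))
  expect_lte(mean(frac), 0.02)
  hit <- replicate(100, {
    x <- c(rnorm(19), 10)
    rout_outliers(x, Q = 0.02)[20]
  })
  expect_gte(mean(hit), 0.99)
  expect_false(any(rout_outliers(rep(3, 5), Q = 0.02)))
  expect_error(rout_outliers(rnorm(4)), "n >= 5")
  expect_error(rout_outliers(rnorm(10), Q = 0.5), "Q")
})

test_that("median fold separation reproduces the worked ratios", {
  expect_equal(median_fold_separation(243, 65)$fold, 3.7)
  expect_equal(median_fold_separation(177, 53)$fold, 3.3)
  expect_equal(median_fold_separation(10, 10)$fold, 1)
  expect_error(median_fold_separation(1, 0), "zero")
})
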