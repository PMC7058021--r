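test_that("OLS fit matches the closed-form oracle", {
  # exact line: slope recovered, residuals zero
  x <- c(1, 2, 3, 4)
  f <- fit_expression_change(2 * x, x)
  expect_equal(f$beta1, 2)
  expect_equal(f$residuals, rep(0, 4), tolerance = 1e-12)

  # cross-check coefficients, slope p and residual-sum constraint against lm
  f2 <- fit_expression_change(c(1, 3, 2, 4), c(1, 2, 3, 4))
  lm_fit <- lm(c(1, 3, 2, 4) ~ c(1, 2, 3, 4))
  expect_equal(f2$beta1, unname(coef(lm_fit)[2]), tolerance = 1e-12)
  expect_equal(f2$beta0, unname(coef(lm_fit)[1]), tolerance = 1e-12)
  expect_equal(f2$p_beta, summary(lm_fit)$coefficients[2, 4], tolerance = 1e-12)
  expect_equal(sum(f2$residuals), 0, tolerance = 1e-8)

  # constant expression: flagged, not an error
  f3 <- fit_expression_change(rep(1, 5), 1:5)
  expect_true(f3$degenerate)
  expect_equal(f3$beta1, 0)
  expect_equal(f3$p_beta, 1)

  expect_error(fit_expression_change(1:3, 1:3), ">= 4")
  expect_error(fit_expression_change(1:4, rep(2, 4)), "constant")
})

test_that("heterogeneity change is the tie-aware Spearman of |residuals| vs age", {
  age <- c(1, 2, 3, 4)
  expect_equal(heterogeneity_change(c(1, -2, 3, -4), age)$rho, 1)
  expect_equal(heterogeneity_change(c(4, -3, 2, -1), age)$rho, -1)

  # mid-rank ties: |resid| = (0.5, 1, 0.5, 1) symmetric around age -> rho 0
  r <- heterogeneity_change(c(0.5, 1, 0.5, 1), c(1, 2, 3, 4))
  oracle <- cor(rank(c(0.5, 1, 0.5, 1)), rank(c(1, 2, 3, 4)))
  expect_equal(r$rho, oracle)

  # all |residuals| equal: degenerate, rho 0 / p 1
  d <- heterogeneity_change(c(1, -1, 1, -1), age)
  expect_true(d$degenerate)
  expect_equal(d$rho, 0)
  expect_equal(d$p_rho, 1)
})

test_that("rho is invariant under strictly monotone age transforms", {
  withr::with_seed(3, {
    age <- runif(30, 100, 30000)
    res <- rnorm(30)
  })
  base <- heterogeneity_change(res, age)$rho
  expect_equal(heterogeneity_change(res, age^4)$rho, base)
  expect_equal(heterogeneity_change(res, log(age + 1))$rho, base)
})

test_that("small-sample Spearman p-values match exhaustive enumeration", {
  withr::with_seed(8, {
    x <- rnorm(6)
    y <- rnorm(6)
  })
  got <- heterogeneity_change(y, x)   # n = 6 < 10 -> exact permutation path
  # independent brute-force oracle over all 6! permutations
  rho_obs <- cor(rank(abs(y)), rank(x))
  perms <- gtools_perm(6)
  rho_null <- apply(perms, 1, function(p) cor(rank(abs(y))[p], rank(x)))
  p_oracle <- mean(abs(rho_null) >= abs(rho_obs) - 1e-12)
  expect_equal(got$rho, rho_obs, tolerance = 1e-12)
  expect_equal(got$p_rho, p_oracle, tolerance = 1e-12)
})

test_that("BH adjustment matches the step-up hand computation", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(0.2), 0.2)
  expect_equal(adjust_fdr(rep(0.5, 7)), rep(0.5, 7))
  # hand step-up oracle on an unordered vector
  p <- c(0.03, 0.001, 0.04, 0.7)
  o <- order(p)
  q_hand <- numeric(4)
  q_sorted <- rev(cummin(rev(sort(p) * 4 / seq_len(4))))
  q_hand[o] <- pmin(q_sorted, 1)
  expect_equal(adjust_fdr(p), q_hand)
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Breusch-Pagan score test behaves and matches lmtest", {
  # squared residuals uncorrelated with age by construction -> statistic ~ 0
  x <- 1:8
  res_pattern <- c(1, -1, 1, -1, 1, -1, 1, -1)  # |res| constant
  y <- 0.5 * x + res_pattern
  bp <- breusch_pagan_check(y, x)
  expect_lt(bp$statistic, 1e-20)

  withr::with_seed(4, {
    xr <- rnorm(60)
    yr <- 1 + 2 * xr + rnorm(60) * (1 + 0.5 * abs(xr))
  })
  ours <- breusch_pagan_check(yr, xr)
  ref <- lmtest::bptest(lm(yr ~ xr))   # Koenker studentized form = n * R^2
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(ours$p, unname(ref$p.value), tolerance = 1e-8)
})

test_that("Breusch-Pagan is calibrated under the null and powered under the alternative", {
  t_age <- transform_age(seq(20, 90, length.out = 100) * 365)
  ps_null <- withr::with_seed(21, vapply(1:400, function(i) {
    y <- simulate_gene_profile(t_age, 0.5, var_slope = 0, base_sd = 0.5)
    breusch_pagan_check(y, t_age)$p
  }, numeric(1)))
  expect_gt(mean(ps_null < 0.05), 0.02)
  expect_lt(mean(ps_null < 0.05), 0.09)

  ps_alt <- withr::with_seed(22, vapply(1:200, function(i) {
    y <- simulate_gene_profile(t_age, 0.5, var_slope = 1.5, base_sd = 0.5)
    breusch_pagan_check(y, t_age)$p
  }, numeric(1)))
  expect_gt(mean(ps_alt < 0.05), 0.5)
})

test_that("loess heterogeneity agrees with the linear model on linear data", {
  t_age <- transform_age(seq(20, 90, length.out = 60) * 365)
  deltas <- withr::with_seed(31, vapply(1:200, function(i) {
    y <- simulate_gene_profile(t_age, 1, var_slope = 0.5, base_sd = 0.5)
    lin <- heterogeneity_change(fit_expression_change(y, t_age)$residuals, t_age)$rho
    lo <- loess_heterogeneity(y, t_age^4, span = 0.75)$rho
    abs(lin - lo)
  }, numeric(1)))
  expect_lt(median(deltas), 0.1)

  expect_error(loess_heterogeneity(rnorm(20), runif(20, 1, 100), span = 1.5),
               "span")
  expect_error(loess_heterogeneity(rnorm(5), runif(5, 1, 100)), ">= 10")

  # quadratic mean trend with constant noise: loess absorbs the trend,
  # leaving no heterogeneity signal
  rhos <- withr::with_seed(32, vapply(1:50, function(i) {
    age <- seq(1, 100, length.out = 80)
    y <- (age - 50)^2 / 500 + rnorm(80, 0, 0.1)
    loess_heterogeneity(y, age, span = 0.5, age_scale = "linear")$rho
  }, numeric(1)))
  expect_lt(abs(mean(rhos)), 0.1)
})

test_that("vectorized dataset fit equals the per-gene scalar operations", {
  ds <- toy_dataset(n_genes = 8, ages_years = c(21, 30, 41, 52, 63, 75, 81, 90, 33, 47),
                    seed = 14)
  fit <- fit_dataset_changes(ds)
  x <- transform_age(ds$meta$age_days)
  for (i in c(1, 4, 8)) {
    sc <- fit_expression_change(ds$expr[i, ], x)
    expect_equal(fit$table$beta1[i], sc$beta1, tolerance = 1e-10)
    expect_equal(fit$table$p_beta[i], sc$p_beta, tolerance = 1e-10)
    expect_equal(unname(fit$residuals[i, ]), unname(sc$residuals), tolerance = 1e-10)
    hc <- heterogeneity_change(sc$residuals, x)
    expect_equal(fit$table$rho[i], hc$rho, tolerance = 1e-10)
    expect_equal(fit$table$p_rho[i], hc$p_rho, tolerance = 1e-10)
  }
  expect_equal(unname(rowSums(fit$residuals)), rep(0, 8), tolerance = 1e-8)
  expect_true(all(fit$table$rho >= -1 & fit$table$rho <= 1))
  expect_true(all(diff(fit$table$q_rho[order(fit$table$p_rho)]) >= -1e-12))
})

test_that("slope on scaled genes equals raw slope divided by the gene sd", {
  ds <- toy_dataset(n_genes = 6, ages_years = c(25, 30, 45, 52, 67, 80), seed = 9)
  raw <- fit_dataset_changes(ds)
  sds <- apply(ds$expr, 1, sd)
  ds_scaled <- ds
  ds_scaled$expr <- scale_genes(ds$expr)
  scaled <- fit_dataset_changes(ds_scaled)
  expect_equal(scaled$table$beta1, unname(raw$table$beta1 / sds), tolerance = 1e-8)
})
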