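test_that("per-instrument marginal OLS matches closed form and lm", {
  d <- mr_data(Y = c(5, 5, 5), X = c(0, 1, 2), Z = cbind(Z1 = c(0L, 1L, 2L)))
  s <- per_instrument_associations(d)
  expect_equal(s$beta_X, 1.0)
  expect_equal(s$beta_Y, 0.0)

  z <- c(0, 0, 1, 2); x <- c(1, 2, 2, 4); y <- c(0.5, 1, 1.5, 3)
  d2 <- mr_data(Y = y, X = x, Z = cbind(Z1 = as.integer(z)))
  s2 <- per_instrument_associations(d2)
  expect_equal(s2$beta_X, sum((z - mean(z)) * (x - mean(x))) /
                 sum((z - mean(z))^2))
  f <- summary(lm(x ~ z))$coefficients
  expect_equal(s2$beta_X, unname(f[2, 1]))
  expect_equal(s2$se_X, unname(f[2, 2]))

  dz <- mr_data(Y = y, X = x, Z = cbind(Z1 = c(1L, 1L, 1L, 1L)))
  expect_error(per_instrument_associations(dz), "Z1")
})

test_that("ratio estimates and weights follow their definitions", {
  s <- data.frame(variant_id = "a", beta_X = 0.5, se_X = 0.1,
                  beta_Y = 1.0, se_Y = 0.1)
  r <- ratio_estimates(s)
  expect_equal(r$ratios, 2.0)
  expect_equal(r$weights, 0.25 / 0.01)
  s$beta_X <- 0
  expect_error(ratio_estimates(s), "zero")
})

test_that("noise-free structural data give exact ratio recovery", {
  G <- simulate_genotypes(200, 8, maf = 0.3, seed = 31)
  p <- structural_params(theta = 2, alpha = rep(1, 8), beta = rep(0, 8),
                         omega_X = 0, omega_Y = 0, delta_X = 0, delta_Y = 0,
                         sigma_X = 1e-12, sigma_Y = 1e-12)
  set.seed(32)
  d <- simulate_dataset(p, G)
  r <- ratio_estimates(per_instrument_associations(d))
  expect_true(all(abs(r$ratios - 2) < 1e-6))
})

test_that("weighted median interpolates the weighted CDF", {
  expect_equal(weighted_median(7, 3), 7)
  expect_equal(weighted_median(c(1, 2, 3), rep(1, 3)), 2.0)
  expect_equal(weighted_median(c(1, 100), c(0.99, 0.01)), 1.99)
  # joint permutation invariance
  set.seed(33)
  v <- runif(7); w <- runif(7) + 0.1
  o <- sample(7)
  expect_equal(weighted_median(v, w), weighted_median(v[o], w[o]))
  expect_error(weighted_median(numeric(0), numeric(0)), "empty")
  expect_error(weighted_median(1:2, c(1, 0)), "positive")
})

test_that("weighted median equals the brute-force weighted-CDF oracle", {
  set.seed(34)
  for (k in 1:1000) {
    J <- sample(1:9, 1)
    v <- runif(J, -5, 5)
    w <- runif(J, 0.05, 2)
    expect_equal(weighted_median(v, w), wm_oracle(v, w), tolerance = 1e-8)
  }
})

test_that("bootstrap WME interval behaves at the definition level", {
  G <- simulate_genotypes(150, 6, maf = 0.3, seed = 35)
  p <- structural_params(theta = 2, alpha = rep(1, 6), beta = rep(0, 6),
                         omega_X = 0, omega_Y = 0, delta_X = 0, delta_Y = 0,
                         sigma_X = 1e-10, sigma_Y = 1e-10)
  set.seed(36)
  d <- simulate_dataset(p, G)
  e <- wme_with_ci(d, n_boot = 200, seed = 37)
  expect_equal(e$point, 2, tolerance = 1e-6)
  expect_lt(e$upper - e$lower, 1e-6)  # degenerate bootstrap
  expect_equal(e$level, 0.95)
  expect_error(wme_with_ci(d, n_boot = 50), "at least 100")
  # determinism given seed
  sim <- make_simple_dataset(300, 10, 0.35, seed = 38)
  e1 <- wme_with_ci(sim$data, n_boot = 200, seed = 5)
  e2 <- wme_with_ci(sim$data, n_boot = 200, seed = 5)
  expect_identical(e1[c("point", "lower", "upper")],
                   e2[c("point", "lower", "upper")])
})

test_that("parametric summary-level bootstrap matches the point definition", {
  sim <- make_simple_dataset(2000, 10, 0.35, seed = 46)
  s <- per_instrument_associations(sim$data)
  r <- ratio_estimates(s)
  e <- wme_parametric_ci(s, n_boot = 400, seed = 47)
  expect_equal(e$point, weighted_median(r$ratios, r$weights))
  expect_true(e$lower <= e$point && e$point <= e$upper)
  e2 <- wme_parametric_ci(s, n_boot = 400, seed = 47)
  expect_identical(e[c("lower", "upper")], e2[c("lower", "upper")])
})

test_that("WME point estimate is consistent with a valid instrument majority", {
  # strong independent instruments, 40% balanced pleiotropy
  spec <- table1_scenario(11)
  set.seed(39)
  G <- simulate_genotypes(20000, 60, seed = 40)
  est <- vapply(1:25, function(k) {
    p <- draw_structural_params(spec, "alternative")
    d <- simulate_dataset(p, G)
    r <- ratio_estimates(per_instrument_associations(d))
    weighted_median(r$ratios, r$weights)
  }, 0)
  expect_lt(abs(mean(est) - 0.35), 0.02)
})

test_that("Egger regression recovers exact fits and recodes signs", {
  s <- data.frame(variant_id = letters[1:4],
                  beta_X = c(0.2, 0.5, 1.0, 1.5), se_X = rep(0.1, 4),
                  beta_Y = 0.35 * c(0.2, 0.5, 1.0, 1.5), se_Y = rep(0.1, 4))
  e <- suppressWarnings(egger_regression(s))  # exact fit
  expect_equal(e$slope$point, 0.35, tolerance = 1e-10)
  expect_equal(e$intercept$point, 0, tolerance = 1e-10)

  # mixed-sign exposure associations on an exact line through the origin
  s2 <- data.frame(variant_id = letters[1:3],
                   beta_X = c(-1, 2, 1), se_X = rep(0.1, 3),
                   beta_Y = c(-2, 4, 2), se_Y = rep(0.1, 3))
  e2 <- suppressWarnings(egger_regression(s2))
  expect_equal(e2$slope$point, 2, tolerance = 1e-10)
  expect_equal(e2$intercept$point, 0, tolerance = 1e-10)

  # allele recoding of any instrument leaves the estimate unchanged
  sim <- make_simple_dataset(800, 12, 0.35, seed = 41)
  s3 <- per_instrument_associations(sim$data)
  e3 <- egger_regression(s3)
  s3f <- s3
  s3f$beta_X[4] <- -s3f$beta_X[4]; s3f$beta_Y[4] <- -s3f$beta_Y[4]
  e3f <- egger_regression(s3f)
  expect_equal(e3$slope$point, e3f$slope$point)
  expect_error(egger_regression(s3[1:2, ]), "at least 3")
})

test_that("Egger slope approximates the causal effect under balanced pleiotropy", {
  spec <- table1_scenario(3)
  spec$J <- 200L
  set.seed(42)
  G <- simulate_genotypes(5000, 200, seed = 43)
  p <- draw_structural_params(spec, "alternative")
  d <- simulate_dataset(p, G)
  e <- egger_regression(per_instrument_associations(d))
  expect_lt(abs(e$slope$point - 0.35), 0.05)
})

test_that("estimators are invariant to instrument ordering", {
  sim <- make_simple_dataset(400, 10, 0.35, seed = 44)
  d <- sim$data
  o <- sample(10)
  dp <- mr_data(Y = d$Y, X = d$X, Z = d$Z[, o])
  s <- per_instrument_associations(d); sp <- per_instrument_associations(dp)
  r <- ratio_estimates(s); rp <- ratio_estimates(sp)
  expect_equal(weighted_median(r$ratios, r$weights),
               weighted_median(rp$ratios, rp$weights))
  expect_equal(egger_regression(s)$slope$point,
               egger_regression(sp)$slope$point)
})

test_that("summary statistics round-trip through delimited text", {
  sim <- make_simple_dataset(200, 5, 0, seed = 45)
  s <- per_instrument_associations(sim$data)
  f <- tempfile(fileext = ".tsv")
  write_summary_stats(s, f)
  s2 <- read_summary_stats(f)
  expect_equal(s2$beta_X, s$beta_X, tolerance = 1e-12)
  expect_s3_class(s2, "instrument_summary")
})
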