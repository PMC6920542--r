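test_that("shrinkage weight is 1/(1+phi^2)", {
  expect_equal(shrinkage_weight(0), 1.0)
  expect_equal(shrinkage_weight(1), 0.5)
  expect_equal(shrinkage_weight(3), 0.1)
  expect_true(all(diff(shrinkage_weight(seq(0, 5, 0.5))) < 0))
  expect_error(shrinkage_weight(-1), "non-negative")
})

test_that("posterior summaries follow the pooled-draw definitions", {
  fit <- manual_posterior(list(theta = rep(2.5, 100)))
  s <- summarize_posterior(fit, "theta")
  expect_equal(s$mean, 2.5)
  expect_equal(s$lower, 2.5)
  expect_equal(s$upper, 2.5)

  set.seed(50)
  fit2 <- manual_posterior(list(x = rnorm(1e6)))
  s2 <- summarize_posterior(fit2, "x", level = 0.95)
  expect_lt(abs(s2$lower - (-1.96)), 0.01)
  expect_lt(abs(s2$upper - 1.96), 0.01)

  # draw-wise evaluation of derived expressions
  fit3 <- manual_posterior(list(theta2 = rep(c(0, 1), 50),
                                theta3 = rep(1, 100)))
  expect_equal(summarize_posterior(fit3, "theta2*theta3")$mean, 0.5)
  expect_error(summarize_posterior(fit3, "nope"), "unknown parameter")
})

test_that("prior-predictive draws follow the declared hierarchies", {
  expect_true(all(prior_predictive_beta(prior_spec("point_zero"), 4, 50)$beta == 0))

  set.seed(51)
  pl <- prior_predictive_beta(prior_spec("laplace", fix_tau = 1), 2, 1e5)
  # Laplace with scale tau = 1: median of |beta| is ln 2
  expect_lt(abs(mean(abs(pl$beta) > log(2)) - 0.5), 0.01)

  set.seed(52)
  ph <- prior_predictive_beta(prior_spec("horseshoe", fix_gamma = 1), 1, 1e5)
  ks <- suppressWarnings(ks.test(ph$kappa[, 1], pbeta, 0.5, 0.5))
  expect_lt(unname(ks$statistic), 0.01)
  expect_equal(ph$kappa, shrinkage_weight(ph$phi))
})

test_that("pleiotropy prior is independent of exposure-model parameters", {
  set.seed(53)
  n <- 1e5
  beta <- prior_predictive_beta(prior_spec("horseshoe"), 1, n)$beta[, 1]
  alpha <- rnorm(n, runif(n, -1, 1), abs(rnorm(n)))
  tau_x <- abs(rnorm(n))
  expect_lt(abs(cor(beta, alpha)), 0.02)
  expect_lt(abs(cor(beta, tau_x)), 0.02)
})

test_that("marginalized likelihood equals the latent-confounder likelihood", {
  G <- simulate_genotypes(5, 3, maf = 0.3, seed = 54)
  p <- structural_params(theta = 0.4, alpha = c(0.2, -0.1, 0.3),
                         beta = c(0, 0.05, -0.02), omega_X = 3.3,
                         omega_Y = 0.9, delta_X = -0.1, delta_Y = -0.12,
                         sigma_X = 0.1, sigma_Y = 0.3)
  set.seed(55)
  d <- simulate_dataset(p, G)
  l1 <- bayesmr:::single_loglik_marginal(p, d)
  l2 <- bayesmr:::single_loglik_latent(p, d)
  expect_lt(abs(l1 - l2) / abs(l1), 1e-6)
})

test_that("the sampler recovers the causal effect on pleiotropy-free data", {
  sim <- make_simple_dataset(1000, 20, 0.35, seed = 56)
  fit <- fit_single_exposure(sim$data, prior_spec("horseshoe"),
                             mcmc_control(chains = 2, warmup = 400,
                                          iter = 400, seed = 57))
  s <- summarize_posterior(fit, "theta")
  psd <- (s$upper - s$lower) / (2 * 1.96)
  expect_lt(abs(s$mean - 0.35), 3 * psd)
  expect_true(all(c("theta", "kappa[1]", "gamma") %in%
                    dimnames(fit$draws)[[3]]))
})

test_that("sampling is deterministic given the seed", {
  sim <- make_simple_dataset(300, 8, 0, seed = 58)
  ctl <- mcmc_control(chains = 1, warmup = 100, iter = 100, seed = 59)
  f1 <- fit_single_exposure(sim$data, prior_spec("horseshoe"), ctl)
  f2 <- fit_single_exposure(sim$data, prior_spec("horseshoe"), ctl)
  expect_identical(f1$draws, f2$draws)
})

test_that("kappa draws are recomputable from phi draws exactly", {
  sim <- make_simple_dataset(300, 6, 0, seed = 60)
  fit <- fit_single_exposure(sim$data, prior_spec("horseshoe"),
                             mcmc_control(chains = 1, warmup = 150,
                                          iter = 150, seed = 61))
  for (j in 1:6) {
    phi <- fit$draws[, 1, paste0("phi[", j, "]")]
    kap <- fit$draws[, 1, paste0("kappa[", j, "]")]
    expect_equal(kap, shrinkage_weight(phi), tolerance = 1e-12)
  }
})

test_that("forcing beta to zero narrows the causal-effect interval", {
  widths <- vapply(1:20, function(k) {
    sim <- make_simple_dataset(400, 15, 0.35, seed = 600 + k)
    ctl <- mcmc_control(chains = 1, warmup = 250, iter = 250, seed = 700 + k)
    w_h <- summarize_posterior(
      fit_single_exposure(sim$data, prior_spec("horseshoe"), ctl), "theta")
    w_p <- summarize_posterior(
      fit_single_exposure(sim$data, prior_spec("point_zero"), ctl), "theta")
    c(w_h$upper - w_h$lower, w_p$upper - w_p$lower)
  }, c(0, 0))
  expect_lt(mean(widths[2, ]), mean(widths[1, ]))
})

test_that("the horseshoe shrinks truly-zero pleiotropic effects selectively", {
  spec <- table1_scenario(1)  # mu_beta = 0.012, 40% pleiotropic
  set.seed(62)
  G <- simulate_genotypes(500, 60, seed = 63)
  gap <- vapply(1:20, function(k) {
    p <- draw_structural_params(spec, "null")
    # strengthen the pleiotropic signal so shrinkage behaviour is visible
    nz <- p$beta != 0
    p$beta[nz] <- sign(p$beta[nz] + 1e-12) * pmax(abs(p$beta[nz]), 0.05)
    d <- simulate_dataset(p, G)
    fit <- fit_single_exposure(d, prior_spec("horseshoe"),
                               mcmc_control(chains = 1, warmup = 300,
                                            iter = 300))
    bm <- vapply(1:60, function(j)
      mean(abs(fit$draws[, 1, paste0("beta[", j, "]")])), 0)
    mean(bm[nz]) - mean(bm[!nz])
  }, 0)
  expect_gt(mean(gap), 0)
})

test_that("the covariate-interaction variant recovers its parameters", {
  set.seed(64)
  J <- 20; n <- 2000
  G <- simulate_genotypes(n, J, seed = 65)
  alpha <- rnorm(J, -0.07, 0.2)
  W <- rbinom(n, 1, 0.5); U <- rnorm(n)
  X <- rnorm(n, 3.3 + drop(G$doses %*% alpha) + 0.1 * W - 0.1 * U, 0.1)
  Y <- rnorm(n, 0.9 + (0.35 - 0.14 * W) * X + 0.05 * W - 0.1 * U, 0.3)
  d <- mr_data(Y = Y, X = X, Z = G$doses, W = W)
  fit <- fit_single_exposure(d, prior_spec("horseshoe"),
                             mcmc_control(chains = 2, warmup = 400,
                                          iter = 400, seed = 66))
  s <- summarize_posterior(fit, "psi_YXW")
  psd <- (s$upper - s$lower) / (2 * 1.96)
  expect_lt(abs(s$mean - (-0.14)), 3 * psd)
  # male-stratum effect theta + psi_YXW as a derived quantity
  sm <- summarize_posterior(fit, "theta + psi_YXW")
  expect_lt(abs(sm$mean - 0.21), 3 * (sm$upper - sm$lower) / (2 * 1.96))
})

test_that("degenerate inputs are rejected with informative errors", {
  sim <- make_simple_dataset(50, 4, 0, seed = 67)
  d <- sim$data
  d$Z[, 2] <- 1L
  expect_error(fit_single_exposure(d), "constant dose column")
  expect_error(prior_spec("horseshoe", u_tau_x2 = -1), "positive")
  expect_warning(fit_single_exposure(
    make_simple_dataset(10, 15, 0, seed = 68)$data,
    mcmc = mcmc_control(chains = 1, warmup = 50, iter = 50, seed = 1)),
    "prior-dominated")
})
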