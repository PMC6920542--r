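test_that("moment solver round-trips through the path-tracing equations", {
  truth <- list(alpha1 = 0.6, alpha3 = 0.2, alpha2 = 0.5,
                theta2 = 0.5, theta1 = 0.3, theta3 = 0.4)
  rho <- with(truth, list(
    rho_X1I1 = alpha1, rho_X1I2 = alpha3,
    rho_I1X2 = alpha1 * theta2, rho_I2X2 = alpha2 + alpha3 * theta2,
    rho_I1Y = alpha1 * theta1 + alpha1 * theta2 * theta3,
    rho_I2Y = alpha3 * theta1 + (alpha3 * theta2 + alpha2) * theta3))
  sol <- moment_solve_no_pleiotropy(rho)
  expect_lt(max(abs(unlist(sol[names(truth)]) - unlist(truth))), 1e-12)
})

test_that("moment solver handles degenerate systems per the conditions", {
  base <- list(rho_X1I1 = 0.6, rho_X1I2 = 0.2, rho_I1X2 = 0,
               rho_I2X2 = 0.5, rho_I1Y = 0.18, rho_I2Y = 0.26)
  sol <- moment_solve_no_pleiotropy(base)
  expect_equal(sol$theta2, 0)  # alpha1 theta2 = 0 with alpha1 != 0
  base$rho_X1I1 <- 0
  expect_error(moment_solve_no_pleiotropy(base), "condition \\(i\\)")
  base$rho_X1I1 <- 0.6
  base$rho_I2X2 <- 0.2 * 0 # makes alpha2 = 0
  expect_error(moment_solve_no_pleiotropy(base), "condition \\(ii\\)")
  expect_error(moment_solve_no_pleiotropy(list(rho_X1I1 = 1)), "named")
})

test_that("derived effects are evaluated draw-wise, not mean-wise", {
  fit <- manual_posterior(list(theta1 = rep(0.3, 100),
                               theta2 = rep(0.5, 100),
                               theta3 = rep(0.4, 100)))
  de <- derived_effects(fit)
  expect_equal(de$mean[de$effect == "indirect"], 0.2)
  expect_equal(de$mean[de$effect == "total"], 0.5)

  # theta3 = 0 severs mediation
  fit0 <- manual_posterior(list(theta1 = rnorm(200, 0.3, 0.01),
                                theta2 = rnorm(200, 0.5, 0.01),
                                theta3 = rep(0, 200)))
  de0 <- derived_effects(fit0)
  expect_equal(de0$mean[de0$effect == "indirect"], 0)
  expect_equal(de0$mean[de0$effect == "total"],
               de0$mean[de0$effect == "direct"])

  # sign-mixing draws: mean indirect 0 although |indirect| = 1 draw-wise
  fitpm <- manual_posterior(list(theta1 = rep(0, 100),
                                 theta2 = rep(c(-1, 1), 50),
                                 theta3 = rep(1, 100)))
  depm <- derived_effects(fitpm)
  expect_equal(depm$mean[depm$effect == "indirect"], 0)
  expect_error(derived_effects(manual_posterior(list(theta1 = 1:5))),
               "theta2")
})

test_that("the mediation posterior recovers the path coefficients", {
  set.seed(70)
  G1 <- simulate_genotypes(5000, 3, maf = 0.3, seed = 71)
  G2 <- simulate_genotypes(5000, 3, maf = 0.3, seed = 72)
  mp <- mediation_params(theta1 = 0.3, theta2 = 0.5, theta3 = 0.4,
                         alpha1 = c(0.3, 0.4, 0.2), alpha2 = c(0.4, 0.3, 0.5),
                         alpha3 = c(0.1, 0, 0.05),
                         delta1 = -0.3, delta2 = -0.25, delta3 = -0.35,
                         sigma1 = 0.8, sigma2 = 0.7, sigmaY = 0.9)
  d <- simulate_mediation_dataset(mp, G1, G2)
  fit <- fit_mediation(d, prior_spec("horseshoe"),
                       mcmc_control(chains = 2, warmup = 1000, iter = 1000,
                                    seed = 73))
  for (p in c("theta1", "theta2", "theta3")) {
    s <- summarize_posterior(fit, p)
    psd <- (s$upper - s$lower) / (2 * 1.96)
    expect_lt(abs(s$mean - mp[[p]]), 3 * psd)
  }
})

test_that("a null mediated path yields indirect-effect intervals covering zero", {
  set.seed(74)
  hits <- 0L
  for (k in 1:10) {
    G1 <- simulate_genotypes(2000, 2, maf = 0.3, seed = 740 + k)
    G2 <- simulate_genotypes(2000, 2, maf = 0.3, seed = 770 + k)
    mp <- mediation_params(theta1 = 0.3, theta2 = 0.5, theta3 = 0,
                           alpha1 = c(0.3, 0.4), alpha2 = c(0.4, 0.3),
                           alpha3 = c(0.1, 0),
                           delta1 = -0.2, delta2 = -0.2, delta3 = -0.2,
                           sigma1 = 0.8, sigma2 = 0.7, sigmaY = 0.9)
    d <- simulate_mediation_dataset(mp, G1, G2)
    # long chains: the indirect-effect decomposition mixes slowly
    fit <- fit_mediation(d, prior_spec("horseshoe"),
                         mcmc_control(chains = 2, warmup = 1500, iter = 1500,
                                      seed = 800 + k))
    de <- derived_effects(fit)
    ind <- de[de$effect == "indirect", ]
    if (ind$lower <= 0 && 0 <= ind$upper) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("total effect agrees with a single-exposure analysis on I1", {
  set.seed(75)
  G1 <- simulate_genotypes(5000, 3, maf = 0.3, seed = 76)
  G2 <- simulate_genotypes(5000, 3, maf = 0.3, seed = 77)
  mp <- mediation_params(theta1 = 0.3, theta2 = 0.5, theta3 = 0.4,
                         alpha1 = c(0.3, 0.4, 0.2), alpha2 = c(0.4, 0.3, 0.5),
                         alpha3 = c(0, 0, 0),
                         delta1 = -0.3, delta2 = -0.25, delta3 = -0.35,
                         sigma1 = 0.8, sigma2 = 0.7, sigmaY = 0.9)
  d <- simulate_mediation_dataset(mp, G1, G2)
  fit <- fit_mediation(d, prior_spec("point_zero"),
                       mcmc_control(chains = 2, warmup = 1000, iter = 1000,
                                    seed = 78))
  tot <- summarize_posterior(fit, "theta1 + theta2*theta3")
  dse <- mr_data(Y = d$Y, X = d$X1, Z = d$I1)
  fit1 <- fit_single_exposure(dse, prior_spec("point_zero"),
                              mcmc_control(chains = 2, warmup = 500,
                                           iter = 500, seed = 79))
  th <- summarize_posterior(fit1, "theta")
  pooled_sd <- sqrt(((tot$upper - tot$lower) / 3.92)^2 +
                    ((th$upper - th$lower) / 3.92)^2)
  expect_lt(abs(tot$mean - th$mean), 2 * pooled_sd)
})

test_that("sequential-relevance screen flags null conditional associations", {
  set.seed(80)
  flagged_null <- 0L
  for (k in 1:10) {
    G1 <- simulate_genotypes(5000, 2, maf = 0.3, seed = 810 + k)
    G2 <- simulate_genotypes(5000, 1, maf = 0.3, seed = 840 + k)
    mp <- mediation_params(theta1 = 0.2, theta2 = 0.5, theta3 = 0.3,
                           alpha1 = c(0.1, 0), alpha2 = 0.4, alpha3 = 0.1,
                           sigma1 = 0.5, sigma2 = 0.5, sigmaY = 0.5)
    d <- simulate_mediation_dataset(mp, G1, G2)
    scr <- sequential_relevance(d)
    expect_false(scr$flagged[1])          # |alpha| = 0.1 at n = 5000: detected
    if (scr$flagged[2]) flagged_null <- flagged_null + 1L
  }
  expect_gte(flagged_null, 8L)            # power >= 0.8 to flag the null one
})

test_that("weak identification is surfaced in the fit flags", {
  set.seed(81)
  G1 <- simulate_genotypes(2000, 1, maf = 0.3, seed = 82)
  G2 <- simulate_genotypes(2000, 1, maf = 0.3, seed = 83)
  mp <- mediation_params(theta1 = 0.2, theta2 = 0.5, theta3 = 0.3,
                         alpha1 = 0, alpha2 = 0.4, alpha3 = 0.1,
                         sigma1 = 0.5, sigma2 = 0.5, sigmaY = 0.5)
  d <- simulate_mediation_dataset(mp, G1, G2)
  fit <- fit_mediation(d, prior_spec("point_zero"),
                       mcmc_control(chains = 1, warmup = 200, iter = 200,
                                    seed = 84))
  expect_true(any(grepl("weak identification", fit$flags)))
})

test_that("overlapping instrument sets are rejected", {
  G1 <- simulate_genotypes(100, 2, maf = 0.3, seed = 85)
  expect_warning(
    d <- mr_mediation_data(Y = rnorm(100), X1 = rnorm(100), X2 = rnorm(100),
                           I1 = G1$doses, I2 = G1$doses),
    "cross-set")
  expect_error(fit_mediation(d), "non-overlapping")
})
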