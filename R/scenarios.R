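# The 21 simulation scenarios: sample size, mean pleiotropic effect (a range
# for scenarios 14-21), SD of the instrument strengths, number of instruments
# and target mean pairwise LD between instruments.
.scenario_grid <- data.frame(
  scenario_id = 1:21,
  n_individuals = c(rep(500L, 17), rep(300L, 4)),
  mu_beta = c(0.012, 0.006, 0, -0.006, -0.012,
              0.012, 0, -0.012,
              0.012, 0.006, 0, -0.006, -0.012,
              rep(NA_real_, 8)),
  sigma_alpha = c(rep(0.02, 8), rep(1.0, 5), rep(0.02, 8)),
  J = c(rep(60L, 5), rep(20L, 3), rep(60L, 13)),
  target_r2 = c(rep(0, 13), 0.33, 0.54, 0.63, 0.70, 0.33, 0.53, 0.62, 0.70)
)

#' Scenario specification for the comparative simulation experiment
#'
#' Returns the configuration of one of the 21 simulation scenarios used to
#' benchmark the Bayesian model against the weighted median estimator:
#' sample size, mean pleiotropic effect \eqn{\mu_\beta} (drawn uniformly on
#' \eqn{\pm 0.012} per replicate in scenarios 14-21), the SD
#' \eqn{\sigma_\alpha} of the instrument strengths, the number of instruments
#' and the target mean pairwise LD (\eqn{R^2}). In scenarios 14-21 the
#' instrument-strength vector is sparsified (most components set to zero) and
#' every instrument carries a pleiotropic effect; in scenarios 1-13 a random
#' 40\% subset does.
#'
#' @param scenario_id Integer in 1..21.
#' @param pleiotropy_fraction Fraction of instruments with nonzero pleiotropic
#'   effect in scenarios 1-13 (default 0.40).
#' @param mu_alpha Mean instrument strength (default -0.07).
#' @param sigma_beta_within SD of the nonzero pleiotropic effect draws
#'   (default 0.05).
#' @param alpha_zero_fraction Fraction of instrument strengths set to zero in
#'   the sparse-strength scenarios 14-21 (default 0.8).
#' @param sigma_x_mean,sigma_y_mean Means of the sharp inverse-gamma laws for
#'   the residual SDs (defaults 0.1 and 0.3).
#' @param invgamma_shape Shape of those inverse-gamma laws (default 50).
#' @return An object of class `mr_scenario` (a list of the fields above plus
#'   `n_individuals`, `mu_beta`, `mu_beta_range`, `sigma_alpha`, `J`,
#'   `target_r2`, `alpha_sparse`).
#' @examples
#' table1_scenario(3)
#' @export
table1_scenario <- function(scenario_id, pleiotropy_fraction = 0.40,
                            mu_alpha = -0.07, sigma_beta_within = 0.05,
                            alpha_zero_fraction = 0.8,
                            sigma_x_mean = 0.1, sigma_y_mean = 0.3,
                            invgamma_shape = 50) {
  if (!is.numeric(scenario_id) || length(scenario_id) != 1L ||
      !scenario_id %in% 1:21)
    stop("'scenario_id' must be an integer in 1..21")
  row <- .scenario_grid[.scenario_grid$scenario_id == scenario_id, ]
  sparse <- scenario_id >= 14
  structure(list(
    scenario_id = as.integer(scenario_id),
    n_individuals = row$n_individuals,
    mu_beta = row$mu_beta,
    mu_beta_range = if (sparse) c(-0.012, 0.012) else NULL,
    sigma_alpha = row$sigma_alpha,
    J = row$J,
    target_r2 = row$target_r2,
    # every instrument is pleiotropic in the sparse-strength scenarios
    pleiotropy_fraction = if (sparse) 1 else pleiotropy_fraction,
    mu_alpha = mu_alpha,
    sigma_beta_within = sigma_beta_within,
    alpha_sparse = sparse,
    alpha_zero_fraction = if (sparse) alpha_zero_fraction else 0,
    sigma_x_mean = sigma_x_mean,
    sigma_y_mean = sigma_y_mean,
    invgamma_shape = invgamma_shape
  ), class = "mr_scenario")
}

#' @export
print.mr_scenario <- function(x, ...) {
  mb <- if (x$alpha_sparse)
    sprintf("U(%.3f, %.3f) per replicate", x$mu_beta_range[1], x$mu_beta_range[2])
  else sprintf("%.3f", x$mu_beta)
  cat(sprintf(paste0("Scenario %d: n = %d, J = %d, mu_beta = %s,\n",
                     "  sigma_alpha = %.2f, target LD R^2 = %.2f%s\n"),
              x$scenario_id, x$n_individuals, x$J, mb, x$sigma_alpha,
              x$target_r2,
              if (x$alpha_sparse)
                sprintf(", sparse alpha (%.0f%% zero)", 100 * x$alpha_zero_fraction)
              else ""))
  invisible(x)
}

# sigma ~ inverse-gamma(shape a, scale b) with mean b/(a-1)
rinvgamma_mean <- function(n, mean, shape) {
  (mean * (shape - 1)) / stats::rgamma(n, shape = shape, rate = 1)
}

#' Draw the true structural parameters of one replicate
#'
#' Samples the generative parameters of the linear structural-equation system
#' for a given scenario: instrument strengths
#' \eqn{\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)}, pleiotropic effects
#' \eqn{\beta_j \sim N(\mu_\beta, 0.05^2)} on a random subset (the rest
#' exactly zero), intercepts \eqn{\omega_X \sim N(3.3, 0.2^2)},
#' \eqn{\omega_Y \sim N(0.9, 0.2^2)}, confounder loadings
#' \eqn{\delta_X, \delta_Y \sim N(-0.1, 0.02^2)}, residual SDs from sharp
#' inverse-gamma laws, and \eqn{\theta} fixed by the regime (0 or 0.35). Uses
#' the current RNG state.
#'
#' @param spec An `mr_scenario` from [table1_scenario()] (fields may be
#'   modified before the call).
#' @param theta_regime `"null"` (\eqn{\theta = 0}) or `"alternative"`
#'   (\eqn{\theta = 0.35}).
#' @return An object of class `mr_params` with elements `theta`, `alpha`,
#'   `beta`, `omega_X`, `omega_Y`, `delta_X`, `delta_Y`, `sigma_X`, `sigma_Y`
#'   and the derived `tau_X`, `tau_Y`, `lambda`.
#' @export
draw_structural_params <- function(spec, theta_regime = c("null", "alternative")) {
  stopifnot(inherits(spec, "mr_scenario"))
  theta_regime <- match.arg(theta_regime)
  J <- spec$J
  alpha <- stats::rnorm(J, spec$mu_alpha, spec$sigma_alpha)
  if (spec$alpha_sparse && spec$alpha_zero_fraction > 0) {
    nzero <- round(spec$alpha_zero_fraction * J)
    alpha[sample.int(J, nzero)] <- 0
  }
  mu_beta <- if (spec$alpha_sparse)
    stats::runif(1, spec$mu_beta_range[1], spec$mu_beta_range[2])
  else spec$mu_beta
  beta <- numeric(J)
  npleio <- round(spec$pleiotropy_fraction * J)
  if (npleio > 0) {
    idx <- sample.int(J, npleio)
    beta[idx] <- stats::rnorm(npleio, mu_beta, spec$sigma_beta_within)
  }
  structural_params(
    theta = if (theta_regime == "null") 0 else 0.35,
    alpha = alpha, beta = beta,
    omega_X = stats::rnorm(1, 3.3, 0.2),
    omega_Y = stats::rnorm(1, 0.9, 0.2),
    delta_X = stats::rnorm(1, -0.1, 0.02),
    delta_Y = stats::rnorm(1, -0.1, 0.02),
    sigma_X = rinvgamma_mean(1, spec$sigma_x_mean, spec$invgamma_shape),
    sigma_Y = rinvgamma_mean(1, spec$sigma_y_mean, spec$invgamma_shape)
  )
}

#' Construct a structural parameter set
#'
#' @param theta Causal effect of X on Y.
#' @param alpha,beta Length-J instrument-exposure and pleiotropic effects.
#' @param omega_X,omega_Y Intercepts.
#' @param delta_X,delta_Y Confounder loadings.
#' @param sigma_X,sigma_Y Residual SDs (positive).
#' @return An `mr_params` list, including the derived quantities
#'   \eqn{\tau_X = \sqrt{\delta_X^2 + \sigma_X^2}},
#'   \eqn{\tau_Y = \sqrt{\delta_Y^2 + \sigma_Y^2}} and
#'   \eqn{\lambda = \delta_X \delta_Y}.
#' @export
structural_params <- function(theta, alpha, beta, omega_X, omega_Y,
                              delta_X, delta_Y, sigma_X, sigma_Y) {
  if (length(alpha) != length(beta))
    stop("'alpha' and 'beta' must have equal length")
  if (sigma_X <= 0 || sigma_Y <= 0) stop("residual SDs must be positive")
  structure(list(theta = theta, alpha = alpha, beta = beta,
                 omega_X = omega_X, omega_Y = omega_Y,
                 delta_X = delta_X, delta_Y = delta_Y,
                 sigma_X = sigma_X, sigma_Y = sigma_Y,
                 tau_X = sqrt(delta_X^2 + sigma_X^2),
                 tau_Y = sqrt(delta_Y^2 + sigma_Y^2),
                 lambda = delta_X * delta_Y),
            class = "mr_params")
}

#' Simulate individual-level (X, Y) data from the structural model
#'
#' Per individual: \eqn{U \sim N(0,1)},
#' \eqn{X \sim N(\omega_X + \sum_j \alpha_j Z_j + \delta_X U, \sigma_X^2)},
#' \eqn{Y \sim N(\omega_Y + \theta X + \sum_j \beta_j Z_j + \delta_Y U,
#' \sigma_Y^2)}. The latent confounder is retained in the output for
#' diagnostics only. Uses the current RNG state.
#'
#' @param params An `mr_params` object.
#' @param G An `mr_genotypes` object (or dose matrix) whose column count
#'   matches `length(params$alpha)`.
#' @return An object of class `mr_data`: list with `Y`, `X`, `Z`, `W`
#'   (NULL here) and `U`.
#' @export
simulate_dataset <- function(params, G) {
  stopifnot(inherits(params, "mr_params"))
  Z <- if (inherits(G, "mr_genotypes")) G$doses else as.matrix(G)
  J <- ncol(Z)
  if (length(params$alpha) != J)
    stop("length of alpha/beta does not match the number of variant columns")
  n <- nrow(Z)
  U <- stats::rnorm(n)
  X <- stats::rnorm(n, params$omega_X + drop(Z %*% params$alpha) +
                       params$delta_X * U, params$sigma_X)
  Y <- stats::rnorm(n, params$omega_Y + params$theta * X +
                       drop(Z %*% params$beta) + params$delta_Y * U,
                    params$sigma_Y)
  mr_data(Y = Y, X = X, Z = Z, U = U)
}

#' Construct a single-exposure dataset container
#'
#' @param Y Outcome vector.
#' @param X Exposure vector.
#' @param Z n x J allele-dose matrix (entries 0/1/2).
#' @param W Optional binary covariate (0/1), e.g. sex.
#' @param U Optional latent confounder (simulated data only; diagnostics).
#' @return An object of class `mr_data`.
#' @export
mr_data <- function(Y, X, Z, W = NULL, U = NULL) {
  Z <- as.matrix(Z)
  n <- length(Y)
  if (length(X) != n || nrow(Z) != n)
    stop("Y, X and Z must have matching lengths")
  if (!all(Z %in% c(0, 1, 2))) stop("Z entries must be allele doses in {0,1,2}")
  if (!is.null(W)) {
    if (length(W) != n) stop("W must have length n")
    if (!all(W %in% c(0, 1))) stop("W must be binary 0/1")
  }
  if (!is.null(U) && length(U) != n) stop("U must have length n")
  if (is.null(colnames(Z))) colnames(Z) <- paste0("Z", seq_len(ncol(Z)))
  structure(list(Y = as.numeric(Y), X = as.numeric(X), Z = Z,
                 W = if (is.null(W)) NULL else as.numeric(W),
                 U = if (is.null(U)) NULL else as.numeric(U)),
            class = "mr_data")
}

#' @export
print.mr_data <- function(x, ...) {
  cat(sprintf("MR dataset: n = %d, J = %d instruments%s%s\n",
              length(x$Y), ncol(x$Z),
              if (!is.null(x$W)) ", covariate W" else "",
              if (!is.null(x$U)) ", latent U retained" else ""))
  invisible(x)
}

#' Construct the parameter set of the two-exposure mediation model
#'
#' Parameters of the three-equation system in which exposure `X1` affects a
#' second exposure `X2` (effect `theta2`), both affect the outcome (`theta1`
#' direct, `theta3` from X2), instruments split into non-overlapping sets I1
#' (length J1, strengths `alpha1` on X1, pleiotropy `beta3` on X2 and `beta1`
#' on Y) and I2 (length J2, strengths `alpha2` on X2, cross-effects `alpha3`
#' on X1, pleiotropy `beta2` on Y), with a shared standardized confounder
#' loading on the three equations through `delta1`, `delta2`, `delta3`.
#'
#' @param theta1,theta2,theta3 Direct X1->Y, X1->X2 and X2->Y effects.
#' @param alpha1,beta1,beta3 Length-J1 coefficient vectors of the I1 set.
#' @param alpha2,alpha3,beta2 Length-J2 coefficient vectors of the I2 set.
#' @param omega1,omega2,omegaY Intercepts.
#' @param delta1,delta2,delta3 Confounder loadings.
#' @param sigma1,sigma2,sigmaY Residual SDs (positive).
#' @return An object of class `mr_mediation_params`.
#' @export
mediation_params <- function(theta1, theta2, theta3,
                             alpha1, alpha2, alpha3,
                             beta1 = 0 * alpha1, beta2 = 0 * alpha2,
                             beta3 = 0 * alpha1,
                             omega1 = 0, omega2 = 0, omegaY = 0,
                             delta1 = 0, delta2 = 0, delta3 = 0,
                             sigma1 = 1, sigma2 = 1, sigmaY = 1) {
  J1 <- length(alpha1); J2 <- length(alpha2)
  if (length(alpha3) != J2) stop("'alpha3' must have length J2")
  if (length(beta1) != J1 || length(beta3) != J1)
    stop("'beta1' and 'beta3' must have length J1")
  if (length(beta2) != J2) stop("'beta2' must have length J2")
  if (sigma1 <= 0 || sigma2 <= 0 || sigmaY <= 0)
    stop("residual SDs must be positive")
  structure(list(theta1 = theta1, theta2 = theta2, theta3 = theta3,
                 alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
                 beta1 = beta1, beta2 = beta2, beta3 = beta3,
                 omega1 = omega1, omega2 = omega2, omegaY = omegaY,
                 delta1 = delta1, delta2 = delta2, delta3 = delta3,
                 sigma1 = sigma1, sigma2 = sigma2, sigmaY = sigmaY,
                 J1 = J1, J2 = J2),
            class = "mr_mediation_params")
}

#' Simulate a two-exposure mediation dataset
#'
#' Forward-simulates (X1, X2, Y) from the three-equation mediation system
#' with a shared standardized confounder; the instrument sets I1 and I2 are
#' independent by construction (separate genotype draws).
#'
#' @param params An `mr_mediation_params` object.
#' @param G1,G2 Genotype objects/matrices for the I1 (J1 columns) and I2
#'   (J2 columns) instrument sets.
#' @return An object of class `mr_mediation_data`: list with `Y`, `X1`, `X2`,
#'   `I1`, `I2` and the latent `U`.
#' @export
simulate_mediation_dataset <- function(params, G1, G2) {
  stopifnot(inherits(params, "mr_mediation_params"))
  I1 <- if (inherits(G1, "mr_genotypes")) G1$doses else as.matrix(G1)
  I2 <- if (inherits(G2, "mr_genotypes")) G2$doses else as.matrix(G2)
  colnames(I1) <- paste0("I1.", seq_len(ncol(I1)))
  colnames(I2) <- paste0("I2.", seq_len(ncol(I2)))
  if (ncol(I1) != params$J1 || ncol(I2) != params$J2)
    stop("genotype column counts must match (J1, J2)")
  if (nrow(I1) != nrow(I2)) stop("I1 and I2 must have the same number of rows")
  n <- nrow(I1)
  U <- stats::rnorm(n)
  X1 <- stats::rnorm(n, params$omega1 + drop(I1 %*% params$alpha1) +
                        drop(I2 %*% params$alpha3) + params$delta1 * U,
                     params$sigma1)
  X2 <- stats::rnorm(n, params$omega2 + params$theta2 * X1 +
                        drop(I1 %*% params$beta3) + drop(I2 %*% params$alpha2) +
                        params$delta2 * U, params$sigma2)
  Y  <- stats::rnorm(n, params$omegaY + params$theta1 * X1 +
                        params$theta3 * X2 + drop(I1 %*% params$beta1) +
                        drop(I2 %*% params$beta2) + params$delta3 * U,
                     params$sigmaY)
  mr_mediation_data(Y = Y, X1 = X1, X2 = X2, I1 = I1, I2 = I2, U = U)
}

#' Construct a mediation dataset container
#'
#' @param Y,X1,X2 Outcome and exposure vectors.
#' @param I1,I2 Dose matrices of the two non-overlapping instrument sets.
#' @param U Optional latent confounder (simulated data only).
#' @return An object of class `mr_mediation_data`.
#' @export
mr_mediation_data <- function(Y, X1, X2, I1, I2, U = NULL) {
  I1 <- as.matrix(I1); I2 <- as.matrix(I2)
  n <- length(Y)
  if (length(X1) != n || length(X2) != n || nrow(I1) != n || nrow(I2) != n)
    stop("all fields must have matching lengths")
  if (!all(I1 %in% c(0, 1, 2)) || !all(I2 %in% c(0, 1, 2)))
    stop("dose entries must lie in {0,1,2}")
  if (is.null(colnames(I1))) colnames(I1) <- paste0("I1.", seq_len(ncol(I1)))
  if (is.null(colnames(I2))) colnames(I2) <- paste0("I2.", seq_len(ncol(I2)))
  # warn on non-negligible empirical cross-set LD (sets assumed independent)
  v1 <- apply(I1, 2, stats::var); v2 <- apply(I2, 2, stats::var)
  if (all(v1 > 0) && all(v2 > 0)) {
    cross_r2 <- mean(stats::cor(I1, I2)^2)
    if (cross_r2 > 0.05)
      warning(sprintf("mean cross-set r^2 = %.3f exceeds 0.05; I1 and I2 are assumed independent",
                      cross_r2))
  }
  structure(list(Y = as.numeric(Y), X1 = as.numeric(X1), X2 = as.numeric(X2),
                 I1 = I1, I2 = I2,
                 U = if (is.null(U)) NULL else as.numeric(U)),
            class = "mr_mediation_data")
}

#' @export
print.mr_mediation_data <- function(x, ...) {
  cat(sprintf("Mediation dataset: n = %d, J1 = %d, J2 = %d instruments\n",
              length(x$Y), ncol(x$I1), ncol(x$I2)))
  invisible(x)
}
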