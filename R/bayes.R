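#' Prior specification for the Bayesian MR models
#'
#' The pleiotropic effects \eqn{\beta_j} receive, a priori independently of
#' the exposure-model parameters (the instrument-effects-orthogonality
#' condition), one of three priors: the horseshoe hierarchy
#' \eqn{\beta_j | \phi_j \sim N(0, \phi_j^2)},
#' \eqn{\phi_j \sim Cauchy^+(0, \gamma)}, \eqn{\gamma \sim Cauchy^+(0, 1)};
#' a Laplace (double-exponential) prior with variance \eqn{2\tau^2} and
#' \eqn{\tau \sim Cauchy^+(0, 1)}; or the point mass at zero of a standard IV
#' analysis. Instrument strengths get a hierarchical
#' \eqn{\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)} prior with flat
#' hyperpriors; \eqn{\theta}, intercepts and confounder loadings are flat,
#' residual SDs flat on the positive reals, optionally bounded.
#'
#' @param beta_prior One of `"horseshoe"`, `"laplace"`, `"point_zero"`.
#' @param u_tau_x2 Optional upper bound on
#'   \eqn{\tau_X^2 = \delta_X^2 + \sigma_X^2} (default `Inf`).
#' @param theta_bounds Optional finite bounds for \eqn{\theta}
#'   (default unbounded).
#' @param alpha_sd_fixed SD of the fixed `N(0, sd^2)` prior used for the
#'   instrument strengths when the hierarchy is unavailable (J < 2).
#' @param fix_gamma,fix_tau Optionally fix the global shrinkage scale in
#'   prior-predictive draws (sampling always infers it).
#' @return An object of class `mr_prior`.
#' @export
prior_spec <- function(beta_prior = c("horseshoe", "laplace", "point_zero"),
                       u_tau_x2 = Inf, theta_bounds = c(-Inf, Inf),
                       alpha_sd_fixed = 10, fix_gamma = NULL, fix_tau = NULL) {
  beta_prior <- match.arg(beta_prior)
  if (u_tau_x2 <= 0) stop("'u_tau_x2' must be positive")
  if (length(theta_bounds) != 2L || theta_bounds[1] > theta_bounds[2])
    stop("'theta_bounds' must be an ordered pair")
  structure(list(beta_prior = beta_prior, u_tau_x2 = u_tau_x2,
                 theta_bounds = theta_bounds, alpha_sd_fixed = alpha_sd_fixed,
                 fix_gamma = fix_gamma, fix_tau = fix_tau),
            class = "mr_prior")
}

#' Sampler configuration
#'
#' @param chains Number of chains (default 4).
#' @param warmup Adaptation/burn-in sweeps per chain (default 1000).
#' @param iter Post-warmup sweeps kept per chain (default 1000).
#' @param thin Thinning interval (default 1).
#' @param seed Optional integer seed (chains are drawn sequentially from one
#'   seeded stream, so results are reproducible).
#' @param n_sigma_mh Metropolis refreshes of the confounder-loading block per
#'   sweep (default 3).
#' @param ridge Enable the equivalence-class move along the
#'   \eqn{\theta' = \theta + \lambda/\tau_X^2} direction (default TRUE).
#' @param init_jitter Relative scale of the random initial-value jitter;
#'   increase for overdispersed initials.
#' @return An object of class `mr_mcmc`.
#' @export
mcmc_control <- function(chains = 4, warmup = 1000, iter = 1000, thin = 1,
                         seed = NULL, n_sigma_mh = 3, ridge = TRUE,
                         init_jitter = 0.1) {
  stopifnot(chains >= 1, warmup >= 0, iter >= 1, thin >= 1)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter), thin = as.integer(thin),
                 seed = seed, n_sigma_mh = as.integer(n_sigma_mh),
                 ridge = isTRUE(ridge), init_jitter = init_jitter),
            class = "mr_mcmc")
}

#' Horseshoe shrinkage weight
#'
#' \eqn{\kappa = 1/(1 + \phi^2)}: near 1 the corresponding pleiotropic effect
#' is shrunk to zero, near 0 it is left (almost) unshrunk.
#'
#' @param phi Non-negative local scale(s).
#' @return Value(s) in (0, 1].
#' @export
shrinkage_weight <- function(phi) {
  if (any(phi < 0)) stop("'phi' must be non-negative")
  1 / (1 + phi^2)
}

.prior_code <- function(prior) {
  match(prior$beta_prior, c("horseshoe", "laplace", "point_zero")) - 1L
}

# initial values from least squares, with per-chain relative jitter
.init_single <- function(x, y, Wx, Wy, jitter) {
  n <- length(x)
  ax <- stats::lm.fit(Wx, x)
  gy <- stats::lm.fit(Wy, y)
  a0 <- ax$coefficients; g0 <- gy$coefficients
  a0[is.na(a0)] <- 0; g0[is.na(g0)] <- 0
  rx <- ax$residuals; ry <- gy$residuals
  lam0 <- mean(rx * ry)
  tx2 <- max(stats::var(rx), 1e-6); ty2 <- max(stats::var(ry), 1e-6)
  dx0 <- -sqrt(min(abs(lam0) + 1e-4, 0.5 * tx2))
  dy0 <- lam0 / dx0
  if (dy0^2 > 0.5 * ty2) dy0 <- sign(dy0) * sqrt(0.5 * ty2)
  jit <- function(v, s) v * (1 + s * stats::rnorm(length(v))) +
    s * 0.01 * stats::rnorm(length(v))
  list(a = jit(a0, jitter), g = jit(g0, jitter),
       delta_x = jit(dx0, jitter), delta_y = jit(dy0, jitter),
       sigma_x = sqrt(max(tx2 - dx0^2, 1e-6)) * exp(jitter * stats::rnorm(1)),
       sigma_y = sqrt(max(ty2 - dy0^2, 1e-6)) * exp(jitter * stats::rnorm(1)),
       mu_alpha = 0, sigma_alpha = 0.1)
}

#' Fit the single-exposure Bayesian MR model
#'
#' Samples the joint posterior of the marginalized structural model: given
#' doses \eqn{Z_i}, the pair \eqn{(X_i, Y_i)} is bivariate normal with means
#' \eqn{(\omega_X + \alpha' Z_i, \; \omega_Y + \theta X_i + \beta' Z_i)} and
#' error covariance
#' \eqn{[[\delta_X^2 + \sigma_X^2, \delta_X\delta_Y], [\delta_X\delta_Y,
#' \delta_Y^2 + \sigma_Y^2]]} — the latent standardized confounder is
#' integrated out analytically, never sampled. With a binary covariate `W`
#' present the mean structure gains \eqn{\psi_{XW} W} in the exposure
#' equation and \eqn{\psi_{YW} W + \psi_{YXW} W X} in the outcome equation
#' (the covariate-interaction variant), so the causal effect is \eqn{\theta}
#' at `W = 0` and \eqn{\theta + \psi_{YXW}} at `W = 1`. No sign recoding of
#' instruments is performed.
#'
#' Sampling uses a blocked Gibbs scheme with conjugate Gaussian and
#' inverse-gamma updates, an adaptive Metropolis block for
#' \eqn{(\delta_X, \delta_Y, \sigma_X, \sigma_Y)} and a Metropolis move along
#' the observationally equivalent direction
#' \eqn{\theta' = \theta + \lambda/\tau_X^2} that only the shrinkage prior on
#' \eqn{\beta} constrains.
#'
#' @param data An `mr_data` object.
#' @param prior An `mr_prior` from [prior_spec()].
#' @param mcmc An `mr_mcmc` from [mcmc_control()].
#' @param interaction With `W` present, include the `W x X` interaction term
#'   \eqn{\psi_{YXW}} (default TRUE); main covariate effects are always
#'   included when `W` is present.
#' @return An `mr_posterior` object: draws array (iterations x chains x
#'   parameters), diagnostics data frame (split-Rhat, effective sample size),
#'   and Metropolis acceptance rates.
#' @export
fit_single_exposure <- function(data, prior = prior_spec(),
                                mcmc = mcmc_control(), interaction = TRUE) {
  stopifnot(inherits(data, "mr_data"))
  Z <- as.matrix(data$Z)
  n <- nrow(Z); J <- ncol(Z)
  if (any(apply(Z, 2, stats::var) == 0)) stop("constant dose column in Z")
  if (n < J) warning(sprintf("n = %d < J = %d: the fit is prior-dominated", n, J))
  has_w <- !is.null(data$W)
  use_int <- has_w && isTRUE(interaction)
  point_zero <- prior$beta_prior == "point_zero"

  Wx <- cbind(1, Z, if (has_w) data$W)
  Wy <- cbind(1, data$X, if (!point_zero) Z,
              if (has_w) data$W, if (use_int) data$W * data$X)
  alpha_idx <- seq_len(J)                         # 0-based in C++: cols 1..J
  wxw_idx <- if (has_w) J + 1L else -1L
  Jb <- if (point_zero) 0L else J
  beta_idx <- if (point_zero) integer(0) else 1L + seq_len(J)
  yw_idx <- if (has_w) 1L + Jb + 1L else -1L
  yxw_idx <- if (use_int) 1L + Jb + 2L else -1L

  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)
  chains <- vector("list", mcmc$chains)
  acc_sigma <- numeric(mcmc$chains)
  for (ch in seq_len(mcmc$chains)) {
    init <- .init_single(data$X, data$Y, Wx, Wy, mcmc$init_jitter)
    res <- gibbs_single_cpp(data$X, data$Y, Wx, Wy,
                            alpha_idx, wxw_idx, 1L, as.integer(beta_idx),
                            yw_idx, yxw_idx,
                            .prior_code(prior), J >= 2, prior$alpha_sd_fixed,
                            prior$u_tau_x2,
                            prior$theta_bounds[1], prior$theta_bounds[2],
                            mcmc$warmup, mcmc$iter, mcmc$thin, init,
                            mcmc$n_sigma_mh, mcmc$ridge)
    chains[[ch]] <- res$draws
    acc_sigma[ch] <- res$accept_sigma
  }

  par_names <- c("theta", "omega_X", "omega_Y", "delta_X", "delta_Y",
                 "sigma_X", "sigma_Y", "tau_X", "tau_Y", "lambda",
                 "mu_alpha", "sigma_alpha",
                 paste0("alpha[", seq_len(J), "]"),
                 paste0("beta[", seq_len(J), "]"))
  if (prior$beta_prior == "horseshoe")
    par_names <- c(par_names, "gamma", paste0("phi[", seq_len(J), "]"),
                   paste0("kappa[", seq_len(J), "]"))
  if (prior$beta_prior == "laplace") par_names <- c(par_names, "tau_beta")
  if (has_w) par_names <- c(par_names, "psi_XW", "psi_YW")
  if (use_int) par_names <- c(par_names, "psi_YXW")

  mr_posterior(chains, par_names,
               model = "single_exposure", prior = prior, mcmc = mcmc,
               accept = list(sigma = acc_sigma))
}

# ---- posterior container ------------------------------------------------

#' Construct a posterior-draws container
#'
#' @param chains List of per-chain draw matrices (iterations x parameters).
#' @param par_names Parameter names.
#' @param model,prior,mcmc,accept Metadata stored alongside the draws.
#' @return An `mr_posterior` with a 3-d draws array and a diagnostics table.
#' @keywords internal
mr_posterior <- function(chains, par_names, model, prior = NULL, mcmc = NULL,
                         accept = NULL) {
  n_iter <- nrow(chains[[1]])
  arr <- array(NA_real_, c(n_iter, length(chains), length(par_names)),
               dimnames = list(NULL, NULL, par_names))
  for (ch in seq_along(chains)) arr[, ch, ] <- chains[[ch]]
  diag <- data.frame(parameter = par_names,
                     rhat = vapply(par_names, function(p)
                       split_rhat(arr[, , p, drop = FALSE]), 0),
                     ess = vapply(par_names, function(p)
                       ess_draws(arr[, , p, drop = FALSE]), 0),
                     row.names = NULL)
  flags <- character(0)
  for (p in intersect(c("theta", "theta1", "theta2", "theta3"), par_names)) {
    r <- diag$rhat[diag$parameter == p]
    if (length(r) == 1 && is.finite(r) && r > 1.05)
      flags <- c(flags, sprintf("split-Rhat for %s exceeds 1.05", p))
  }
  structure(list(draws = arr, diagnostics = diag, model = model,
                 prior = prior, mcmc = mcmc, accept = accept, flags = flags),
            class = "mr_posterior")
}

#' @export
print.mr_posterior <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("Posterior draws (%s model): %d iterations x %d chains x %d parameters\n",
              x$model, d[1], d[2], d[3]))
  heads <- intersect(c("theta", "theta1", "theta2", "theta3"),
                     dimnames(x$draws)[[3]])
  for (p in heads) print(summarize_posterior(x, p), digits = 4)
  if (length(x$flags)) cat("Flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

# split-Rhat on an iterations x chains x 1 array
split_rhat <- function(a) {
  n <- dim(a)[1]
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  m <- cbind(a[seq_len(half), , 1], a[half + seq_len(half), , 1])
  W <- mean(apply(m, 2, stats::var))
  B <- half * stats::var(colMeans(m))
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

ess_draws <- function(a) {
  sum(apply(a[, , 1, drop = FALSE], 2, function(v) coda::effectiveSize(v)))
}

#' Summarize a posterior quantity
#'
#' Posterior mean and central credible interval of a parameter or of a
#' derived expression evaluated draw-wise (e.g. `"theta2*theta3"`), from the
#' pooled post-warmup draws. Derived expressions may reference any scalar
#' parameter by name (bracketed names via backticks).
#'
#' @param samples An `mr_posterior`.
#' @param parameter Parameter name or expression string.
#' @param level Credible level (default 0.95).
#' @return A one-row data frame: `parameter`, `mean`, `lower`, `upper`,
#'   `level`, `rhat`, `ess`.
#' @export
summarize_posterior <- function(samples, parameter, level = 0.95) {
  stopifnot(inherits(samples, "mr_posterior"), level > 0, level < 1)
  nm <- dimnames(samples$draws)[[3]]
  n_chain <- dim(samples$draws)[2]
  if (parameter %in% nm) {
    per_chain <- lapply(seq_len(n_chain), function(ch)
      samples$draws[, ch, parameter])
  } else {
    expr <- tryCatch(parse(text = parameter)[[1]],
                     error = function(e) stop("unknown parameter or unparsable expression: ",
                                              parameter))
    vars <- all.vars(expr)
    if (!all(vars %in% nm))
      stop("unknown parameter(s): ", paste(setdiff(vars, nm), collapse = ", "))
    per_chain <- lapply(seq_len(n_chain), function(ch) {
      env <- list2env(stats::setNames(
        lapply(vars, function(v) samples$draws[, ch, v]), vars))
      eval(expr, env)
    })
  }
  pooled <- unlist(per_chain)
  qs <- stats::quantile(pooled, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  arr <- array(unlist(per_chain), c(length(per_chain[[1]]), n_chain, 1))
  data.frame(parameter = parameter, mean = mean(pooled),
             lower = qs[1], upper = qs[2], level = level,
             rhat = split_rhat(arr), ess = ess_draws(arr))
}

#' Forward draws from the pleiotropy prior
#'
#' Prior-predictive draws of the pleiotropic-effect vector \eqn{\beta} under
#' the declared shrinkage hierarchy, independent across instruments. For the
#' horseshoe, the induced shrinkage weights \eqn{\kappa_j = 1/(1+\phi_j^2)}
#' follow a Beta(1/2, 1/2) law when the global scale is fixed at 1.
#'
#' @param prior An `mr_prior`.
#' @param J Number of instruments.
#' @param n_draws Number of prior draws (>= 1).
#' @return A list with matrix `beta` (n_draws x J) and, for the horseshoe,
#'   `phi`, `kappa` and the vector `gamma`; for the Laplace, the scale vector
#'   `tau`.
#' @export
prior_predictive_beta <- function(prior, J, n_draws) {
  stopifnot(inherits(prior, "mr_prior"), n_draws >= 1, J >= 1)
  if (prior$beta_prior == "point_zero")
    return(list(beta = matrix(0, n_draws, J)))
  if (prior$beta_prior == "horseshoe") {
    gamma <- if (is.null(prior$fix_gamma)) abs(stats::rcauchy(n_draws))
             else rep(prior$fix_gamma, n_draws)
    phi <- abs(matrix(stats::rcauchy(n_draws * J), n_draws, J)) * gamma
    beta <- matrix(stats::rnorm(n_draws * J), n_draws, J) * phi
    return(list(beta = beta, phi = phi, kappa = shrinkage_weight(phi),
                gamma = gamma))
  }
  tau <- if (is.null(prior$fix_tau)) abs(stats::rcauchy(n_draws))
         else rep(prior$fix_tau, n_draws)
  # Laplace with variance 2 tau^2, i.e. scale parameter tau
  u <- matrix(stats::runif(n_draws * J) - 0.5, n_draws, J)
  beta <- -tau * sign(u) * log(1 - 2 * abs(u))
  list(beta = beta, tau = tau)
}
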