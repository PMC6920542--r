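# Log-likelihood of the single-exposure structural model, in two forms that
# are mathematically identical: the marginalized bivariate-normal form used
# by the sampler, and the latent-confounder form with U integrated out
# numerically (kept as an independent cross-check of the marginalization).

# marginalized form: (X, Y) | Z bivariate normal, error covariance
# [[tau_X^2, lambda], [lambda, tau_Y^2]]
single_loglik_marginal <- function(params, data) {
  Z <- as.matrix(data$Z)
  A <- data$X - params$omega_X - drop(Z %*% params$alpha)
  B <- data$Y - params$omega_Y - params$theta * data$X -
    drop(Z %*% params$beta)
  tx2 <- params$delta_X^2 + params$sigma_X^2
  ty2 <- params$delta_Y^2 + params$sigma_Y^2
  lam <- params$delta_X * params$delta_Y
  det <- tx2 * ty2 - lam^2
  n <- length(A)
  -n * log(2 * pi) - n / 2 * log(det) -
    0.5 * sum(ty2 * A^2 - 2 * lam * A * B + tx2 * B^2) / det
}

# latent form: product over i of  int N(X_i | . + delta_X u, sigma_X^2)
#                                  N(Y_i | . + delta_Y u, sigma_Y^2) phi(u) du
single_loglik_latent <- function(params, data, rel.tol = 1e-10) {
  Z <- as.matrix(data$Z)
  mx <- params$omega_X + drop(Z %*% params$alpha)
  my <- params$omega_Y + params$theta * data$X + drop(Z %*% params$beta)
  ll <- 0
  for (i in seq_along(data$X)) {
    f <- function(u)
      stats::dnorm(data$X[i], mx[i] + params$delta_X * u, params$sigma_X) *
      stats::dnorm(data$Y[i], my[i] + params$delta_Y * u, params$sigma_Y) *
      stats::dnorm(u)
    ll <- ll + log(stats::integrate(f, -10, 10, rel.tol = rel.tol)$value)
  }
  ll
}
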