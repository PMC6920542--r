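#' Closed-form identification of the mediation model without pleiotropy
#'
#' In the scalar-instrument, standardized, pleiotropy-free case the six
#' instrument-involving correlations identify all path coefficients by
#' path tracing: \eqn{\rho_{X_1 I_1} = \alpha_1},
#' \eqn{\rho_{X_1 I_2} = \alpha_3}; then
#' \eqn{\rho_{I_1 X_2} = \alpha_1\theta_2} and
#' \eqn{\rho_{I_2 X_2} = \alpha_2 + \alpha_3\theta_2} give
#' \eqn{(\alpha_2, \theta_2)}; finally
#' \eqn{\rho_{I_1 Y} = \alpha_1\theta_1 + \alpha_1\theta_2\theta_3} and
#' \eqn{\rho_{I_2 Y} = \alpha_3\theta_1 + (\alpha_3\theta_2 +
#' \alpha_2)\theta_3} give \eqn{(\theta_1, \theta_3)}; the determinant of the
#' last system is \eqn{\alpha_1\alpha_2}. Used as an oracle against the
#' posterior fit.
#'
#' @param correlations Named vector/list with elements `rho_X1I1`,
#'   `rho_X1I2`, `rho_I1X2`, `rho_I2X2`, `rho_I1Y`, `rho_I2Y`.
#' @param tol Singularity tolerance for the system determinants.
#' @return List with `alpha1`, `alpha3`, `alpha2`, `theta2`, `theta1`,
#'   `theta3`.
#' @export
moment_solve_no_pleiotropy <- function(correlations, tol = 1e-8) {
  r <- as.list(correlations)
  need <- c("rho_X1I1", "rho_X1I2", "rho_I1X2", "rho_I2X2", "rho_I1Y", "rho_I2Y")
  if (!all(need %in% names(r)))
    stop("correlations must be named: ", paste(need, collapse = ", "))
  alpha1 <- r$rho_X1I1
  if (abs(alpha1) < tol)
    stop("singular system: condition (i) fails (alpha1 = 0)")
  alpha3 <- r$rho_X1I2
  theta2 <- r$rho_I1X2 / alpha1
  alpha2 <- r$rho_I2X2 - alpha3 * theta2
  if (abs(alpha1 * alpha2) < tol)
    stop("singular system: condition (ii) fails (alpha2 = 0)")
  M <- rbind(c(alpha1, alpha1 * theta2),
             c(alpha3, alpha3 * theta2 + alpha2))
  th <- solve(M, c(r$rho_I1Y, r$rho_I2Y))
  list(alpha1 = alpha1, alpha3 = alpha3, alpha2 = alpha2,
       theta2 = theta2, theta1 = th[1], theta3 = th[2])
}

#' Moment estimates of the mediation effects from data
#'
#' Standardizes the variables, applies the path-tracing solver to the sample
#' correlations (scalar instruments) and maps the causal effects back to the
#' original scale via SD ratios. Valid when the pleiotropic vectors are zero.
#'
#' @param data An `mr_mediation_data` with J1 = J2 = 1.
#' @return List with `theta1`, `theta2`, `theta3` on the original scale and
#'   the standardized solution in `standardized`.
#' @export
mediation_moment_estimates <- function(data) {
  stopifnot(inherits(data, "mr_mediation_data"))
  if (ncol(data$I1) != 1L || ncol(data$I2) != 1L)
    stop("the moment solver requires scalar instruments (J1 = J2 = 1)")
  i1 <- data$I1[, 1]; i2 <- data$I2[, 1]
  rho <- list(rho_X1I1 = stats::cor(data$X1, i1),
              rho_X1I2 = stats::cor(data$X1, i2),
              rho_I1X2 = stats::cor(i1, data$X2),
              rho_I2X2 = stats::cor(i2, data$X2),
              rho_I1Y = stats::cor(i1, data$Y),
              rho_I2Y = stats::cor(i2, data$Y))
  sol <- moment_solve_no_pleiotropy(rho)
  s1 <- stats::sd(data$X1); s2 <- stats::sd(data$X2); sy <- stats::sd(data$Y)
  list(theta1 = sol$theta1 * sy / s1,
       theta2 = sol$theta2 * s2 / s1,
       theta3 = sol$theta3 * sy / s2,
       standardized = sol)
}

#' Sequential-relevance diagnostic
#'
#' Reports, per instrument, the conditional association backing the
#' mediation model's relevance condition: each I1 component with X1 given
#' the remaining instruments, and each I2 component with X2 given X1 and the
#' remaining instruments. A diagnostic report, never an automatic filter.
#'
#' @param data An `mr_mediation_data`.
#' @param alpha_level Flagging threshold on the per-instrument p-value
#'   (default 0.05).
#' @return Data frame with columns `instrument`, `set`, `estimate`, `se`,
#'   `t`, `p`, `flagged`.
#' @export
sequential_relevance <- function(data, alpha_level = 0.05) {
  stopifnot(inherits(data, "mr_mediation_data"))
  Iall <- cbind(data$I1, data$I2)
  f1 <- stats::lm(data$X1 ~ Iall)
  f2 <- stats::lm(data$X2 ~ data$X1 + Iall)
  s1 <- summary(f1)$coefficients
  s2 <- summary(f2)$coefficients
  J1 <- ncol(data$I1); J2 <- ncol(data$I2)
  rows1 <- s1[1 + seq_len(J1), , drop = FALSE]
  rows2 <- s2[2 + J1 + seq_len(J2), , drop = FALSE]
  out <- data.frame(
    instrument = c(colnames(data$I1), colnames(data$I2)),
    set = rep(c("I1", "I2"), c(J1, J2)),
    estimate = c(rows1[, 1], rows2[, 1]),
    se = c(rows1[, 2], rows2[, 2]),
    t = c(rows1[, 3], rows2[, 3]),
    p = c(rows1[, 4], rows2[, 4]),
    row.names = NULL)
  out$flagged <- out$p > alpha_level
  out
}

# ---- Gibbs sampler ------------------------------------------------------

# per-beta-vector horseshoe (parameter-expanded) state update; returns the
# new state and the prior precisions for the vector
.hs_update <- function(state, beta) {
  J <- length(beta)
  for (j in seq_len(J)) {
    state$eta2[j] <- (1 / state$nu[j] + beta[j]^2 / (2 * state$gamma2)) /
      stats::rgamma(1, 1)
    state$nu[j] <- (1 + 1 / state$eta2[j]) / stats::rgamma(1, 1)
  }
  sb <- sum(beta^2 / state$eta2)
  state$gamma2 <- (1 / state$xi + sb / 2) / stats::rgamma(1, (J + 1) / 2)
  state$xi <- (1 + 1 / state$gamma2) / stats::rgamma(1, 1)
  state$prec <- 1 / (state$gamma2 * state$eta2)
  state
}

.lap_update <- function(state, beta) {
  J <- length(beta)
  for (j in seq_len(J)) {
    ab <- max(abs(beta[j]), 1e-8)
    mu <- 1 / (sqrt(state$tau2) * ab)
    z <- stats::rnorm(1); z2 <- z^2; lam <- 1 / state$tau2
    xw <- mu + mu^2 * z2 / (2 * lam) -
      mu / (2 * lam) * sqrt(4 * mu * lam * z2 + mu^2 * z2^2)
    if (xw <= 0 || !is.finite(xw)) xw <- 1e-12
    inv <- if (stats::runif(1) <= mu / (mu + xw)) xw else mu^2 / xw
    state$v[j] <- 1 / max(inv, 1e-12)
  }
  state$tau2 <- (1 / state$zeta + sum(state$v) / 2) /
    stats::rgamma(1, J + 0.5)
  state$zeta <- (1 + 1 / state$tau2) / stats::rgamma(1, 1)
  state$prec <- 1 / state$v
  state
}

.mvn_prec_r <- function(P, b) {
  P <- (P + t(P)) / 2
  diag(P) <- diag(P) + 1e-10 * (1 + max(diag(P)))
  R <- chol(P)
  m <- backsolve(R, forwardsolve(t(R), b))
  drop(m + backsolve(R, stats::rnorm(length(b))))
}

# hierarchical-normal prior update for an alpha vector; returns mu, sigma
.alpha_hyper <- function(alpha, sigma_alpha) {
  J <- length(alpha)
  mu <- mean(alpha) + stats::rnorm(1) * sigma_alpha / sqrt(J)
  S <- sum((alpha - mu)^2)
  sig2 <- (S / 2) / stats::rgamma(1, (J - 1) / 2)
  list(mu = mu, sigma = max(sqrt(sig2), 1e-6))
}

#' Fit the two-exposure Bayesian mediation model
#'
#' Samples the posterior of the three-equation system (X1; X2 given X1; Y
#' given both), with the shared standardized confounder marginalized into a
#' trivariate error covariance \eqn{\delta\delta' + diag(\sigma^2)}, and the
#' declared shrinkage prior imposed independently on each pleiotropic vector
#' (`beta1`, `beta2`, `beta3`). Instrument strengths get hierarchical normal
#' priors per vector (a fixed wide normal when a set is scalar); intercepts,
#' causal effects and loadings are flat. The sampler mirrors the
#' single-exposure one: conjugate Gaussian blocks per equation, adaptive
#' Metropolis for \eqn{(\delta, \sigma)}, and per-equation equivalence-class
#' moves along the directions that trade causal effects against confounding.
#'
#' @param data An `mr_mediation_data`; the I1/I2 column sets must be disjoint.
#' @param prior An `mr_prior`.
#' @param mcmc An `mr_mcmc`.
#' @return An `mr_posterior` with parameters `theta1`, `theta2`, `theta3`,
#'   intercepts, loadings, residual SDs and all coefficient vectors.
#'   Weak sequential relevance (per the conditional-association screen) is
#'   reported in `$flags`.
#' @export
fit_mediation <- function(data, prior = prior_spec(), mcmc = mcmc_control()) {
  stopifnot(inherits(data, "mr_mediation_data"))
  if (length(intersect(colnames(data$I1), colnames(data$I2))))
    stop("instrument sets I1 and I2 must be non-overlapping")
  J1 <- ncol(data$I1); J2 <- ncol(data$I2)
  n <- length(data$Y)
  point_zero <- prior$beta_prior == "point_zero"
  hs <- prior$beta_prior == "horseshoe"

  # master Gram matrix over [1, X1, X2, Y, I1, I2]
  Tm <- cbind(1, data$X1, data$X2, data$Y, data$I1, data$I2)
  G <- crossprod(Tm)
  i1c <- 4 + seq_len(J1); i2c <- 4 + J1 + seq_len(J2)
  iW1 <- c(1L, i1c, i2c)                              # (omega1, alpha1, alpha3)
  iW2 <- if (point_zero) c(1L, 2L, i2c) else c(1L, 2L, i1c, i2c)
  iW3 <- if (point_zero) c(1L, 2L, 3L) else c(1L, 2L, 3L, i1c, i2c)
  p1 <- length(iW1); p2 <- length(iW2); p3 <- length(iW3)
  # coefficient positions
  a1_alpha1 <- 1 + seq_len(J1); a1_alpha3 <- 1 + J1 + seq_len(J2)
  a2_theta2 <- 2L
  a2_beta3 <- if (point_zero) integer(0) else 2 + seq_len(J1)
  a2_alpha2 <- if (point_zero) 2 + seq_len(J2) else 2 + J1 + seq_len(J2)
  a3_theta1 <- 2L; a3_theta3 <- 3L
  a3_beta1 <- if (point_zero) integer(0) else 3 + seq_len(J1)
  a3_beta2 <- if (point_zero) integer(0) else 3 + J1 + seq_len(J2)

  G11 <- G[iW1, iW1]; G22 <- G[iW2, iW2]; G33 <- G[iW3, iW3]
  G12 <- G[iW1, iW2]; G13 <- G[iW1, iW3]; G23 <- G[iW2, iW3]

  q12 <- function(ia, ib, aa, bb, ya, yb)
    G[ya, yb] - sum(aa * G[ia, yb]) - sum(bb * G[ib, ya]) +
      drop(t(aa) %*% G[ia, ib] %*% bb)
  resid_stats <- function(a1v, a2v, a3v) {
    S <- matrix(0, 3, 3)
    S[1, 1] <- q12(iW1, iW1, a1v, a1v, 2, 2)
    S[2, 2] <- q12(iW2, iW2, a2v, a2v, 3, 3)
    S[3, 3] <- q12(iW3, iW3, a3v, a3v, 4, 4)
    S[1, 2] <- S[2, 1] <- q12(iW1, iW2, a1v, a2v, 2, 3)
    S[1, 3] <- S[3, 1] <- q12(iW1, iW3, a1v, a3v, 2, 4)
    S[2, 3] <- S[3, 2] <- q12(iW2, iW3, a2v, a3v, 3, 4)
    S
  }
  cond_coefs <- function(S) {
    c21 <- S[2, 1] / S[1, 1]
    cc <- solve(S[1:2, 1:2], S[1:2, 3])
    list(c21 = c21, c31 = cc[1], c32 = cc[2])
  }
  tri_loglik <- function(Sig, S) {
    dt <- det(Sig)
    if (dt <= 0) return(-Inf)
    -n / 2 * log(dt) - 0.5 * sum(solve(Sig) * S)
  }
  lp_beta <- function(b, prec) if (length(b)) -0.5 * sum(b^2 * prec) else 0

  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)
  n_total <- mcmc$warmup + mcmc$iter * mcmc$thin

  par_names <- c("theta1", "theta2", "theta3", "omega1", "omega2", "omegaY",
                 "delta1", "delta2", "delta3", "sigma1", "sigma2", "sigmaY",
                 paste0("alpha1[", seq_len(J1), "]"),
                 paste0("alpha2[", seq_len(J2), "]"),
                 paste0("alpha3[", seq_len(J2), "]"),
                 paste0("beta1[", seq_len(J1), "]"),
                 paste0("beta2[", seq_len(J2), "]"),
                 paste0("beta3[", seq_len(J1), "]"))

  chains <- vector("list", mcmc$chains)
  acc_sigma <- numeric(mcmc$chains)
  for (ch in seq_len(mcmc$chains)) {
    # least-squares initial values with per-chain jitter
    f1 <- stats::lm.fit(Tm[, iW1, drop = FALSE], data$X1)
    f2 <- stats::lm.fit(Tm[, iW2, drop = FALSE], data$X2)
    f3 <- stats::lm.fit(Tm[, iW3, drop = FALSE], data$Y)
    jit <- function(v) v * (1 + mcmc$init_jitter * stats::rnorm(length(v))) +
      0.01 * mcmc$init_jitter * stats::rnorm(length(v))
    a1 <- jit(ifelse(is.na(f1$coefficients), 0, f1$coefficients))
    a2 <- jit(ifelse(is.na(f2$coefficients), 0, f2$coefficients))
    a3 <- jit(ifelse(is.na(f3$coefficients), 0, f3$coefficients))
    R3 <- stats::cov(cbind(f1$residuals, f2$residuals, f3$residuals))
    del <- c(-0.1, -0.1, -0.1) * (1 + mcmc$init_jitter * stats::rnorm(3))
    sig <- sqrt(pmax(diag(R3) - del^2, diag(R3) / 2))

    hs1 <- list(eta2 = rep(1, J1), nu = rep(1, J1), gamma2 = 1, xi = 1,
                v = rep(1, J1), tau2 = 1, zeta = 1, prec = rep(1, J1))
    hs2 <- list(eta2 = rep(1, J2), nu = rep(1, J2), gamma2 = 1, xi = 1,
                v = rep(1, J2), tau2 = 1, zeta = 1, prec = rep(1, J2))
    hs3 <- list(eta2 = rep(1, J1), nu = rep(1, J1), gamma2 = 1, xi = 1,
                v = rep(1, J1), tau2 = 1, zeta = 1, prec = rep(1, J1))
    hyp <- list(a1 = list(mu = 0, sigma = 0.1), a2 = list(mu = 0, sigma = 0.1),
                a3 = list(mu = 0, sigma = 0.1))
    mh_logstep <- 0; comp_logstep <- 0
    mh_tries <- 0; mh_acc <- 0
    draws <- matrix(NA_real_, mcmc$iter, length(par_names))
    krow <- 0L

    for (it in seq_len(n_total)) {
      Sig <- tcrossprod(del) + diag(sig^2)
      s1sq <- Sig[1, 1]
      c21 <- Sig[2, 1] / Sig[1, 1]
      s2sq <- Sig[2, 2] - Sig[2, 1]^2 / Sig[1, 1]
      cc <- solve(Sig[1:2, 1:2], Sig[1:2, 3])
      s3sq <- Sig[3, 3] - sum(Sig[3, 1:2] * cc)
      c31 <- cc[1]; c32 <- cc[2]

      # ---- a1 block ----
      D1 <- numeric(p1); m1 <- numeric(p1)
      pr1 <- if (J1 >= 2) 1 / hyp$a1$sigma^2 else 1 / prior$alpha_sd_fixed^2
      pr3 <- if (J2 >= 2) 1 / hyp$a3$sigma^2 else 1 / prior$alpha_sd_fixed^2
      D1[a1_alpha1] <- pr1; m1[a1_alpha1] <- if (J1 >= 2) hyp$a1$mu else 0
      D1[a1_alpha3] <- pr3; m1[a1_alpha3] <- if (J2 >= 2) hyp$a3$mu else 0
      W1u2 <- G[iW1, 3] - G12 %*% a2 - c21 * G[iW1, 2]
      W1u3 <- G[iW1, 4] - G13 %*% a3 - c31 * G[iW1, 2] -
        c32 * (G[iW1, 3] - G12 %*% a2)
      P <- (1 / s1sq + c21^2 / s2sq + c31^2 / s3sq) * G11 + diag(D1, p1)
      b <- G[iW1, 2] / s1sq - (c21 / s2sq) * W1u2 - (c31 / s3sq) * W1u3 +
        D1 * m1
      a1 <- .mvn_prec_r(P, b)
      if (J1 >= 2) hyp$a1 <- .alpha_hyper(a1[a1_alpha1], hyp$a1$sigma)
      if (J2 >= 2) hyp$a3 <- .alpha_hyper(a1[a1_alpha3], hyp$a3$sigma)

      # ---- a2 block ----
      W2E1 <- G[iW2, 2] - t(G12) %*% a1
      D2 <- numeric(p2); m2 <- numeric(p2)
      pr2 <- if (J2 >= 2) 1 / hyp$a2$sigma^2 else 1 / prior$alpha_sd_fixed^2
      D2[a2_alpha2] <- pr2; m2[a2_alpha2] <- if (J2 >= 2) hyp$a2$mu else 0
      if (!point_zero) D2[a2_beta3] <- hs3$prec
      W2u <- G[iW2, 4] - G23 %*% a3 - c31 * W2E1 - c32 * G[iW2, 3]
      P <- (1 / s2sq + c32^2 / s3sq) * G22 + diag(D2, p2)
      b <- (G[iW2, 3] - c21 * W2E1) / s2sq - (c32 / s3sq) * W2u + D2 * m2
      a2 <- .mvn_prec_r(P, b)
      if (J2 >= 2) hyp$a2 <- .alpha_hyper(a2[a2_alpha2], hyp$a2$sigma)

      # ---- a3 block ----
      W3E1 <- G[iW3, 2] - t(G13) %*% a1
      W3E2 <- G[iW3, 3] - t(G23) %*% a2
      D3 <- numeric(p3)
      if (!point_zero) { D3[a3_beta1] <- hs1$prec; D3[a3_beta2] <- hs2$prec }
      P <- G33 / s3sq + diag(D3, p3)
      b <- (G[iW3, 4] - c31 * W3E1 - c32 * W3E2) / s3sq
      a3 <- .mvn_prec_r(P, b)

      # ---- shrinkage hierarchies ----
      if (!point_zero) {
        upd <- if (hs) .hs_update else .lap_update
        hs1 <- upd(hs1, a3[a3_beta1])
        hs2 <- upd(hs2, a3[a3_beta2])
        hs3 <- upd(hs3, a2[a2_beta3])
      }

      # ---- residual sufficient statistics (3x3) ----
      S3 <- resid_stats(a1, a2, a3)

      # ---- (delta, sigma) compensated Metropolis ----
      # A proposal changing the conditional-error regression coefficients
      # (c21; c31, c32) shifts the downstream equation coefficients along the
      # observational-equivalence directions so the conditional means are
      # preserved wherever coefficients exist (everywhere under shrinkage
      # priors; partially under point_zero, where the exact likelihood ratio
      # absorbs the difference).
      cc0 <- cond_coefs(Sig)
      alpha1v <- a1[a1_alpha1]; alpha3v <- a1[a1_alpha3]
      cur <- tri_loglik(Sig, S3) + sum(log(sig))
      # two alternating kernels: plain (coefficients fixed) then compensated
      n_inner <- mcmc$n_sigma_mh * (1 + as.integer(mcmc$ridge))
      for (m in seq_len(n_inner)) {
        use_comp <- mcmc$ridge && m > mcmc$n_sigma_mh
        step <- exp(if (use_comp) comp_logstep else mh_logstep)
        delp <- del + step * 0.02 * stats::rnorm(3)
        sigp <- sig * exp(step * 0.1 * stats::rnorm(3))
        Sigp <- tcrossprod(delp) + diag(sigp^2)
        ccp <- cond_coefs(Sigp)
        if (use_comp) {
          d21 <- ccp$c21 - cc0$c21
          a2p <- a2
          a2p[a2_theta2] <- a2[a2_theta2] - d21
          a2p[1] <- a2[1] + d21 * a1[1]
          if (length(a2_beta3)) a2p[a2_beta3] <- a2[a2_beta3] + d21 * alpha1v
          a2p[a2_alpha2] <- a2[a2_alpha2] + d21 * alpha3v
          d1 <- cc0$c31 - cc0$c32 * d21 - ccp$c31
          d2 <- cc0$c32 - ccp$c32
          a3p <- a3
          a3p[1] <- a3[1] - d1 * a1[1] - d2 * a2p[1]
          a3p[a3_theta1] <- a3[a3_theta1] + d1 - d2 * a2p[a2_theta2]
          a3p[a3_theta3] <- a3[a3_theta3] + d2
          if (length(a3_beta1))
            a3p[a3_beta1] <- a3[a3_beta1] - d1 * alpha1v -
              d2 * a2p[a2_beta3]
          if (length(a3_beta2))
            a3p[a3_beta2] <- a3[a3_beta2] - d1 * alpha3v -
              d2 * a2p[a2_alpha2]
        } else {
          a2p <- a2; a3p <- a3
        }
        S3p <- if (use_comp) resid_stats(a1, a2p, a3p) else S3
        lp <- tri_loglik(Sigp, S3p) + sum(log(sigp)) +
          lp_beta(a2p[a2_beta3], hs3$prec) - lp_beta(a2[a2_beta3], hs3$prec) +
          lp_beta(a3p[a3_beta1], hs1$prec) - lp_beta(a3[a3_beta1], hs1$prec) +
          lp_beta(a3p[a3_beta2], hs2$prec) - lp_beta(a3[a3_beta2], hs2$prec) +
          lp_beta(a2p[a2_alpha2] - m2[a2_alpha2], rep(pr2, J2)) -
          lp_beta(a2[a2_alpha2] - m2[a2_alpha2], rep(pr2, J2))
        apr <- min(1, exp(lp - cur))
        mh_tries <- mh_tries + 1
        if (is.finite(apr) && stats::runif(1) < apr) {
          del <- delp; sig <- sigp; a2 <- a2p; a3 <- a3p; S3 <- S3p
          Sig <- Sigp; cc0 <- ccp
          cur <- tri_loglik(Sig, S3) + sum(log(sig))
          mh_acc <- mh_acc + 1
        }
        if (it <= mcmc$warmup) {
          if (use_comp) comp_logstep <- comp_logstep + (apr - 0.3) / it^0.6
          else mh_logstep <- mh_logstep + (apr - 0.3) / it^0.6
        }
      }
      # global sign flip of the loadings (likelihood-invariant, symmetric)
      if (stats::runif(1) < 0.5) del <- -del

      if (it > mcmc$warmup && (it - mcmc$warmup - 1) %% mcmc$thin == 0 &&
          krow < mcmc$iter) {
        krow <- krow + 1L
        draws[krow, ] <- c(a3[a3_theta1], a2[a2_theta2], a3[a3_theta3],
                           a1[1], a2[1], a3[1], del, sig,
                           a1[a1_alpha1],
                           a2[a2_alpha2],
                           a1[a1_alpha3],
                           if (point_zero) rep(0, J1) else a3[a3_beta1],
                           if (point_zero) rep(0, J2) else a3[a3_beta2],
                           if (point_zero) rep(0, J1) else a2[a2_beta3])
      }
    }
    chains[[ch]] <- draws
    acc_sigma[ch] <- mh_acc / max(mh_tries, 1)
  }

  fit <- mr_posterior(chains, par_names, model = "mediation", prior = prior,
                      mcmc = mcmc, accept = list(sigma = acc_sigma))
  scr <- sequential_relevance(data)
  if (any(scr$flagged))
    fit$flags <- c(fit$flags,
                   sprintf("weak identification: %s not conditionally associated (p > 0.05)",
                           paste(scr$instrument[scr$flagged], collapse = ", ")))
  fit$relevance <- scr
  fit
}

#' Posterior direct, indirect and total effects
#'
#' Draw-wise evaluation (then summarization) of the direct effect
#' \eqn{\theta_1}, the indirect effect \eqn{\theta_2\theta_3} and the total
#' effect \eqn{\theta_1 + \theta_2\theta_3}, preserving posterior dependence
#' among the path coefficients.
#'
#' @param samples An `mr_posterior` from [fit_mediation()].
#' @param level Credible level (default 0.95).
#' @return Data frame with rows `direct`, `indirect`, `total`.
#' @export
derived_effects <- function(samples, level = 0.95) {
  stopifnot(inherits(samples, "mr_posterior"))
  nm <- dimnames(samples$draws)[[3]]
  if (!all(c("theta1", "theta2", "theta3") %in% nm))
    stop("samples must contain theta1, theta2, theta3")
  out <- rbind(summarize_posterior(samples, "theta1", level),
               summarize_posterior(samples, "theta2*theta3", level),
               summarize_posterior(samples, "theta1 + theta2*theta3", level))
  out$effect <- c("direct", "indirect", "total")
  out[, c("effect", setdiff(names(out), "effect"))]
}
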