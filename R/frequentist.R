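# Centered sufficient statistics for marginal (one-instrument-at-a-time) OLS
# of a response on each dose column: slope and standard error per column.
marginal_ols <- function(Z, y) {
  n <- nrow(Z)
  zbar <- colMeans(Z)
  Szz <- colSums(Z^2) - n * zbar^2
  Szy <- colSums(Z * y) - n * zbar * mean(y)
  Syy <- sum(y^2) - n * mean(y)^2
  slope <- Szy / Szz
  rss <- pmax(Syy - slope * Szy, 0)
  se <- sqrt(rss / (n - 2) / Szz)
  list(slope = slope, se = se, Szz = Szz)
}

#' Per-instrument marginal associations
#'
#' Simple OLS (with intercept) of the exposure and of the outcome on each
#' instrument separately: the \eqn{\hat\beta_{Xj}} and \eqn{\hat\beta_{Yj}}
#' slopes, with their standard errors, that feed the ratio, weighted median
#' and Egger estimators.
#'
#' @param data An `mr_data` object (or list with `X`, `Y`, `Z`).
#' @return A data frame of class `instrument_summary` with columns
#'   `variant_id`, `beta_X`, `se_X`, `beta_Y`, `se_Y`.
#' @export
per_instrument_associations <- function(data) {
  Z <- as.matrix(data$Z)
  n <- nrow(Z)
  if (n < 3) stop("at least 3 individuals are required")
  v <- apply(Z, 2, stats::var)
  if (any(v == 0))
    stop(sprintf("constant dose column: %s",
                 paste(colnames(Z)[v == 0], collapse = ", ")))
  ox <- marginal_ols(Z, data$X)
  oy <- marginal_ols(Z, data$Y)
  out <- data.frame(variant_id = colnames(Z),
                    beta_X = unname(ox$slope), se_X = unname(ox$se),
                    beta_Y = unname(oy$slope), se_Y = unname(oy$se),
                    stringsAsFactors = FALSE)
  class(out) <- c("instrument_summary", "data.frame")
  out
}

#' Per-instrument ratio (IV) estimates and weights
#'
#' Each instrument contributes the ratio estimate
#' \eqn{\hat\beta_{Yj}/\hat\beta_{Xj}} of the causal effect; weights are the
#' first-order inverse-variance weights \eqn{\hat\beta_{Xj}^2 / se_{Yj}^2}.
#'
#' @param s An `instrument_summary`.
#' @return A list with `ratios` and `weights` (length-J vectors).
#' @export
ratio_estimates <- function(s) {
  if (any(s$beta_X == 0)) stop("zero exposure association: ratio undefined")
  list(ratios = s$beta_Y / s$beta_X, weights = s$beta_X^2 / s$se_Y^2)
}

#' Interpolated weighted median
#'
#' Sorts the values, forms standardized cumulative weights
#' \eqn{p_j = (S_{j-1} + w_j/2)/S_J} and linearly interpolates the sorted
#' values at \eqn{p = 0.5}. With equal weights this is the usual
#' interpolation-based median; the estimator is consistent for the causal
#' effect when at least half of the total weight lies on valid instruments.
#'
#' @param values Numeric vector.
#' @param weights Positive weights, same length.
#' @return The weighted median.
#' @examples
#' weighted_median(c(1, 2, 3), rep(1, 3))
#' @export
weighted_median <- function(values, weights) {
  if (length(values) == 0L) stop("empty input")
  if (length(weights) != length(values)) stop("lengths differ")
  if (any(weights <= 0)) stop("weights must be positive")
  o <- order(values)
  v <- values[o]; w <- weights[o]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (length(v) == 1L) return(v)
  if (0.5 <= p[1]) return(v[1])
  if (0.5 >= p[length(p)]) return(v[length(v)])
  stats::approx(p, v, xout = 0.5, ties = "ordered")$y
}

# Bootstrap WME machinery: multinomial resample counts + sufficient-statistic
# recomputation of all marginal slopes/SEs, vectorized across resamples.
boot_wme <- function(X, Y, Z, n_boot) {
  n <- nrow(Z); J <- ncol(Z)
  Q <- cbind(X, X^2, Y, Y^2, Z, Z^2, Z * X, Z * Y)
  est <- numeric(n_boot)
  todo <- n_boot
  redraws <- 0L
  filled <- 0L
  while (todo > 0) {
    C <- stats::rmultinom(todo, n, rep.int(1, n))
    S <- crossprod(Q, C)                  # (4 + 4J) x todo
    sx <- S[1, ]; sy <- S[3, ]
    sz  <- S[4 + seq_len(J), , drop = FALSE]
    sz2 <- S[4 + J + seq_len(J), , drop = FALSE]
    szx <- S[4 + 2 * J + seq_len(J), , drop = FALSE]
    szy <- S[4 + 3 * J + seq_len(J), , drop = FALSE]
    Szz <- sz2 - sz^2 / n
    Szx <- szx - sweep(sz, 2, sx / n, "*")
    Szy <- szy - sweep(sz, 2, sy / n, "*")
    Syy <- S[4, ] - sy^2 / n
    ok <- colSums(Szz <= 0) == 0
    slope_x <- Szx / Szz
    slope_y <- Szy / Szz
    ok <- ok & colSums(slope_x == 0) == 0
    rss <- sweep(-slope_y * Szy, 2, Syy, "+")
    se2_y <- pmax(rss, 0) / (n - 2) / Szz
    wts <- slope_x^2 / se2_y
    ok <- ok & colSums(!is.finite(wts) | wts <= 0) == 0
    keep <- which(ok)
    for (k in keep) {
      filled <- filled + 1L
      est[filled] <- weighted_median(slope_y[, k] / slope_x[, k], wts[, k])
    }
    redraws <- redraws + (todo - length(keep))
    todo <- todo - length(keep)
  }
  list(est = est, redraws = redraws)
}

#' Weighted median estimate with percentile bootstrap interval
#'
#' Point estimate: weighted median of the per-instrument ratio estimates on
#' the full data. Interval: percentile bootstrap over individual-level
#' resamples, recomputing the marginal associations, ratios and weighted
#' median in each resample. Degenerate resamples (a constant dose column or a
#' zero exposure slope) are redrawn and counted.
#'
#' @param data An `mr_data` object.
#' @param n_boot Number of bootstrap resamples (at least 100; default 1000).
#' @param level Nominal coverage (default 0.95).
#' @param seed Optional seed for reproducibility.
#' @return An `mr_estimate` list: `point`, `lower`, `upper`, `level`,
#'   `method`, plus the redraw count and a flag when the point falls outside
#'   the interval.
#' @export
wme_with_ci <- function(data, n_boot = 1000, level = 0.95, seed = NULL) {
  if (n_boot < 100) stop("'n_boot' must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  s <- per_instrument_associations(data)
  r <- ratio_estimates(s)
  point <- weighted_median(r$ratios, r$weights)
  bb <- boot_wme(data$X, data$Y, as.matrix(data$Z), n_boot)
  qs <- stats::quantile(bb$est, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  out <- structure(list(point = point, lower = qs[1], upper = qs[2],
                        level = level, method = "WME",
                        n_boot = n_boot, redraws = bb$redraws,
                        point_outside = point < qs[1] || point > qs[2]),
                   class = "mr_estimate")
  if (out$point_outside)
    warning("bootstrap percentile interval does not contain the point estimate")
  out
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s estimate: %.4f  [%.4f, %.4f] (%.0f%% interval)\n",
              x$method, x$point, x$lower, x$upper, 100 * x$level))
  invisible(x)
}

#' Weighted median estimate from summary statistics, parametric bootstrap
#'
#' Summary-level alternative to [wme_with_ci()] for two-sample-style input:
#' each resample redraws the per-instrument association estimates from
#' \eqn{N(\hat\beta, se^2)}, recomputes ratios, weights and the weighted
#' median, and the interval is the percentile interval of the resampled
#' estimates.
#'
#' @param s An `instrument_summary`.
#' @param n_boot Number of parametric resamples (at least 100; default 1000).
#' @param level Nominal coverage (default 0.95).
#' @param seed Optional seed.
#' @return An `mr_estimate`.
#' @export
wme_parametric_ci <- function(s, n_boot = 1000, level = 0.95, seed = NULL) {
  if (n_boot < 100) stop("'n_boot' must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  r <- ratio_estimates(s)
  point <- weighted_median(r$ratios, r$weights)
  J <- nrow(s)
  est <- vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(J, s$beta_X, s$se_X)
    by <- stats::rnorm(J, s$beta_Y, s$se_Y)
    ok <- bx != 0
    weighted_median(by[ok] / bx[ok], bx[ok]^2 / s$se_Y[ok]^2)
  }, 0)
  qs <- stats::quantile(est, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  structure(list(point = point, lower = qs[1], upper = qs[2], level = level,
                 method = "WME (parametric bootstrap)", n_boot = n_boot,
                 redraws = 0L,
                 point_outside = point < qs[1] || point > qs[2]),
            class = "mr_estimate")
}

#' Egger regression on per-instrument associations
#'
#' Jointly flips the sign of \eqn{(\hat\beta_{Xj}, \hat\beta_{Yj})} wherever
#' \eqn{\hat\beta_{Xj} < 0} (so all exposure associations are non-negative),
#' then fits weighted least squares of \eqn{\hat\beta_{Yj}} on
#' \eqn{\hat\beta_{Xj}} with intercept and weights \eqn{1/se_{Yj}^2}. The
#' slope estimates the causal effect; a nonzero intercept indicates
#' directional pleiotropy. Intervals use t quantiles with J - 2 df.
#'
#' @param s An `instrument_summary` (J >= 3 rows).
#' @param level Nominal interval level (default 0.95).
#' @return List with `mr_estimate` elements `slope` and `intercept`.
#' @export
egger_regression <- function(s, level = 0.95) {
  J <- nrow(s)
  if (J < 3) stop("Egger regression requires at least 3 instruments")
  flip <- ifelse(s$beta_X < 0, -1, 1)
  bx <- s$beta_X * flip
  by <- s$beta_Y * flip
  if (stats::var(bx) == 0)
    stop("singular design: no variation in exposure associations after recoding")
  fit <- stats::lm(by ~ bx, weights = 1 / s$se_Y^2)
  ci <- stats::confint(fit, level = level)
  est <- stats::coef(fit)
  mk <- function(i, label) structure(
    list(point = unname(est[i]), lower = ci[i, 1], upper = ci[i, 2],
         level = level, method = label),
    class = "mr_estimate")
  list(slope = mk(2, "Egger slope"), intercept = mk(1, "Egger intercept"))
}

#' Read / write two-sample-style summary statistics
#'
#' Tab-separated table with columns `variant_id`, `beta_X`, `se_X`, `beta_Y`,
#' `se_Y`, accepted as input by the frequentist estimators.
#'
#' @param s An `instrument_summary`.
#' @param path File path.
#' @return `read_summary_stats` returns an `instrument_summary`.
#' @export
write_summary_stats <- function(s, path) {
  utils::write.table(as.data.frame(s), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_stats
#' @export
read_summary_stats <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "beta_X", "se_X", "beta_Y", "se_Y")
  if (!all(need %in% names(d)))
    stop("summary file must have columns: ", paste(need, collapse = ", "))
  d <- d[, need]
  if (any(d$se_X <= 0) || any(d$se_Y <= 0)) stop("standard errors must be positive")
  class(d) <- c("instrument_summary", "data.frame")
  d
}
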