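#' Simulate allele-dose genotype matrices with controlled LD
#'
#' Generates an n x J matrix of minor-allele counts (0/1/2) at specified
#' minor-allele frequencies, with an average pairwise squared correlation
#' (linkage disequilibrium, LD) close to `target_r2`. Doses are obtained by
#' double-thresholding a latent Gaussian vector with exchangeable correlation
#' (single-factor copula) at the Hardy-Weinberg quantiles, so each column is
#' marginally Hardy-Weinberg distributed. The latent correlation is calibrated
#' to the requested mean dose-scale r-squared analytically, via
#' bivariate-normal rectangle probabilities.
#'
#' @param n Number of individuals (rows), at least 2.
#' @param J Number of variants (columns), at least 1.
#' @param maf_range Interval within (0, 0.5] from which minor-allele
#'   frequencies are drawn uniformly. Ignored when `maf` is supplied.
#' @param maf Optional fixed minor-allele frequency vector (length 1 or J).
#' @param target_r2 Desired mean pairwise r-squared of dose columns, in [0, 1).
#' @param seed Optional integer seed; when supplied the result is a
#'   deterministic function of the arguments.
#' @return An object of class `mr_genotypes`: a list with elements `doses`
#'   (n x J integer matrix), `mafs`, `achieved_r2` (realized mean pairwise
#'   r-squared) and `latent_rho` (calibrated copula correlation).
#' @examples
#' G <- simulate_genotypes(200, 10, maf = 0.3, target_r2 = 0, seed = 1)
#' table(G$doses)
#' @export
simulate_genotypes <- function(n, J, maf_range = c(0.1, 0.4), maf = NULL,
                               target_r2 = 0, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("'n' must be a single number >= 2")
  if (!is.numeric(J) || length(J) != 1L || J < 1)
    stop("'J' must be a single number >= 1")
  if (!is.numeric(target_r2) || length(target_r2) != 1L ||
      target_r2 < 0 || target_r2 >= 1)
    stop("'target_r2' must lie in [0, 1)")
  if (is.null(maf)) {
    if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
        maf_range[1] > maf_range[2])
      stop("'maf_range' must be an interval within (0, 0.5]")
  } else {
    if (any(maf <= 0) || any(maf > 0.5))
      stop("'maf' values must lie in (0, 0.5]")
    if (!length(maf) %in% c(1L, J))
      stop("'maf' must have length 1 or J")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n); J <- as.integer(J)

  mafs <- if (is.null(maf)) stats::runif(J, maf_range[1], maf_range[2])
          else rep_len(as.numeric(maf), J)

  rho <- if (J >= 2L) calibrate_latent_rho(target_r2, mafs) else 0
  doses <- draw_dose_copula(n, mafs, rho)

  achieved <- if (J >= 2L) mean_pairwise_r2(doses) else NA_real_
  structure(list(doses = doses, mafs = mafs, achieved_r2 = achieved,
                 latent_rho = rho),
            class = "mr_genotypes")
}

#' @export
print.mr_genotypes <- function(x, ...) {
  cat(sprintf("Allele-dose genotypes: %d individuals x %d variants\n",
              nrow(x$doses), ncol(x$doses)))
  cat(sprintf("  MAF range [%.3f, %.3f]; mean pairwise r^2 = %s (latent rho = %.3f)\n",
              min(x$mafs), max(x$mafs),
              ifelse(is.na(x$achieved_r2), "NA", sprintf("%.3f", x$achieved_r2)),
              x$latent_rho))
  invisible(x)
}

# Latent single-factor Gaussian copula doses: T_j = sqrt(rho) F + sqrt(1-rho) E_j,
# dose_j = 1(T_j > t1_j) + 1(T_j > t2_j) with thresholds at the HWE quantiles.
draw_dose_copula <- function(n, mafs, rho) {
  J <- length(mafs)
  p0 <- (1 - mafs)^2
  p1 <- 2 * mafs * (1 - mafs)
  t1 <- stats::qnorm(p0)
  t2 <- stats::qnorm(p0 + p1)
  if (rho > 0) {
    f <- stats::rnorm(n)
    Tm <- sqrt(rho) * f + sqrt(1 - rho) * matrix(stats::rnorm(n * J), n, J)
  } else {
    Tm <- matrix(stats::rnorm(n * J), n, J)
  }
  D <- (sweep(Tm, 2, t1, ">") + sweep(Tm, 2, t2, ">"))
  storage.mode(D) <- "integer"
  dimnames(D) <- list(NULL, paste0("Z", seq_len(J)))
  D
}

# P(T1 > a, T2 > b) for standard bivariate normal with correlation rho,
# by 1-D quadrature: int_a^Inf phi(t) Phi((rho t - b)/sqrt(1-rho^2)) dt.
biv_upper_rect <- function(a, b, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(a, lower.tail = FALSE) *
                               stats::pnorm(b, lower.tail = FALSE))
  lo <- max(a, -9); hi <- 9
  if (lo >= hi) return(0)
  tt <- seq(lo, hi, length.out = 801L)
  ft <- stats::dnorm(tt) * stats::pnorm((rho * tt - b) / sqrt(1 - rho^2))
  h <- tt[2] - tt[1]
  # Simpson's rule (801 points -> even number of panels)
  w <- rep(c(4, 2), length.out = length(tt) - 2L)
  h / 3 * (ft[1] + ft[length(ft)] + sum(w * ft[2:(length(ft) - 1L)]))
}

# Expected dose-scale correlation^2 between two copula columns.
dose_pair_r2 <- function(rho, m1, m2) {
  th <- function(m) stats::qnorm(c((1 - m)^2, (1 - m)^2 + 2 * m * (1 - m)))
  a <- th(m1); b <- th(m2)
  e12 <- 0
  for (k in 1:2) for (l in 1:2) e12 <- e12 + biv_upper_rect(a[k], b[l], rho)
  cov12 <- e12 - 4 * m1 * m2
  (cov12 / sqrt(2 * m1 * (1 - m1) * 2 * m2 * (1 - m2)))^2
}

# Monotone calibration of the exchangeable latent correlation to the target
# mean pairwise dose r^2 (averaged over a subset of column pairs).
calibrate_latent_rho <- function(target_r2, mafs, max_pairs = 30L) {
  if (target_r2 <= 0) return(0)
  J <- length(mafs)
  pairs <- utils::combn(J, 2L)
  if (ncol(pairs) > max_pairs)
    pairs <- pairs[, round(seq(1, ncol(pairs), length.out = max_pairs)), drop = FALSE]
  mean_r2 <- function(rho) {
    mean(apply(pairs, 2L, function(p) dose_pair_r2(rho, mafs[p[1]], mafs[p[2]])))
  }
  if (mean_r2(0.999) < target_r2)
    stop("'target_r2' is not attainable for these allele frequencies")
  stats::uniroot(function(r) mean_r2(r) - target_r2, c(0, 0.999),
                 tol = 1e-4)$root
}

#' Mean pairwise squared correlation of dose columns
#'
#' Arithmetic mean of squared Pearson correlations over all unordered column
#' pairs; the summary used to report linkage disequilibrium between
#' instruments. Zero-variance columns are excluded from the pairing with a
#' warning.
#'
#' @param G An `mr_genotypes` object or a numeric matrix with at least 2
#'   columns.
#' @return A value in [0, 1].
#' @export
mean_pairwise_r2 <- function(G) {
  M <- if (inherits(G, "mr_genotypes")) G$doses else as.matrix(G)
  if (ncol(M) < 2L) stop("at least 2 columns are required")
  v <- apply(M, 2L, stats::var)
  if (any(v == 0)) {
    warning(sprintf("excluding %d zero-variance column(s) from r^2 pairs",
                    sum(v == 0)))
    M <- M[, v > 0, drop = FALSE]
    if (ncol(M) < 2L) stop("fewer than 2 non-constant columns")
  }
  C <- stats::cor(M)
  mean(C[upper.tri(C)]^2)
}

#' Write / read a delimited-text dosage matrix
#'
#' Tab-separated individuals x variants table with a header row of variant
#' IDs; entries are allele doses in \{0, 1, 2\}. The round trip through
#' `write_dosage()` and `read_dosage()` is exact.
#'
#' @param G An `mr_genotypes` object or a dose matrix.
#' @param path File path.
#' @return `read_dosage` returns an integer dose matrix with variant-ID
#'   column names.
#' @export
write_dosage <- function(G, path) {
  M <- if (inherits(G, "mr_genotypes")) G$doses else as.matrix(G)
  utils::write.table(M, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage
#' @export
read_dosage <- function(path) {
  M <- as.matrix(utils::read.delim(path, check.names = FALSE))
  bad <- which(!(M %in% c(0L, 1L, 2L)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(M))
    stop(sprintf("dose outside {0,1,2} at row %d, column %d", rc[1], rc[2]))
  }
  storage.mode(M) <- "integer"
  M
}
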