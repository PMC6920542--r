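# Brute-force weighted-median oracle: build the interpolated weighted CDF
# p(v) directly and invert it at 1/2 by root finding, independently of the
# production implementation (which inverts by interpolating v against p).
wm_oracle <- function(values, weights) {
  o <- order(values)
  v <- values[o]
  w <- weights[o]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (length(v) == 1L || p[1] >= 0.5) return(v[1])
  if (p[length(p)] <= 0.5) return(v[length(v)])
  cdf <- stats::approxfun(v, p, rule = 2, ties = "ordered")
  stats::uniroot(function(x) cdf(x) - 0.5, range(v), tol = 1e-13)$root
}

# small beta-zero dataset from the structural model with known parameters
make_simple_dataset <- function(n, J, theta, seed, sigma_alpha = 0.2,
                                maf = NULL) {
  set.seed(seed)
  G <- simulate_genotypes(n, J, maf = maf, seed = seed + 1)
  p <- structural_params(theta = theta,
                         alpha = stats::rnorm(J, -0.07, sigma_alpha),
                         beta = rep(0, J),
                         omega_X = 3.3, omega_Y = 0.9,
                         delta_X = -0.1, delta_Y = -0.1,
                         sigma_X = 0.1, sigma_Y = 0.3)
  list(data = simulate_dataset(p, G), params = p, G = G)
}

# posterior container with hand-specified draws, for summary-operation tests
manual_posterior <- function(draws_list) {
  nm <- names(draws_list)
  n <- length(draws_list[[1]])
  chains <- list(matrix(unlist(draws_list), nrow = n, ncol = length(nm)))
  bayesmr:::mr_posterior(chains, nm, model = "manual")
}
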