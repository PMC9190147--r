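# Brute-force oracles used across the suite.

# Mixture pmf by direct (non-log) evaluation, for normalization and moment
# checks at desk scale.
pmf_brute <- function(y, mu1, mu2, pi) {
  pi * dpois(y, mu1) + (1 - pi) * dpois(y, mu2)
}

# Mean and variance by truncated summation of the pmf.
moments_brute <- function(mu1, mu2, pi, y_max = 300) {
  y <- 0:y_max
  p <- pmf_brute(y, mu1, mu2, pi)
  m <- sum(y * p)
  v <- sum(y^2 * p) - m^2
  list(mu = m, var = v)
}

# Direct latent-class mixture log-likelihood (the oracle the marginalized
# form must reproduce once mu2 is substituted).
loglik_direct <- function(y, mu1, mu2, pi) {
  sum(log(pi * dpois(y, mu1) + (1 - pi) * dpois(y, mu2)))
}

# Random valid parameter/data draw for the oracle-equivalence sweeps:
# intercept + one binary covariate, parameters kept inside the mu2 > 0
# region by construction (component-1 intercept below the marginal one).
draw_valid_case <- function(n = 200) {
  beta <- c(runif(1, 0.5, 1.5), runif(1, -0.4, 0.4))
  alpha <- c(beta[1] - runif(1, 0.5, 1.2), runif(1, -0.3, 0.3))
  tau <- runif(1, -1, 1)
  x <- rbinom(n, 1, 0.5)
  X <- cbind(1, x)
  params <- mpp_params(beta, alpha, tau)
  sim <- simulate_counts(X, X, params)
  list(params = params, y = sim$y, X = X, Z = X)
}
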