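test_that("mixture log-pmf matches hand-computable cases and rejects bad input", {
  # mixture of two identical Poisson(1) laws is Poisson(1)
  expect_equal(mixture_log_pmf(0, 1, 1, 0.5), -1)
  # pi = 1: pure component-1 Poisson
  expect_equal(mixture_log_pmf(0, 2, 5, 1), -2)
  expect_error(mixture_log_pmf(-1, 1, 1, 0.5), "non-negative")
  expect_error(mixture_log_pmf(1.5, 1, 1, 0.5), "integer")
  expect_error(mixture_log_pmf(1, -1, 1, 0.5), "positive")
  expect_error(mixture_log_pmf(1, 1, 1, 0), "\\(0, 1\\]")
})

test_that("mixture pmf is normalized on a parameter grid", {
  expect_equal(sum(exp(mixture_log_pmf(0:200, 1, 5, 0.3))), 1,
               tolerance = 1e-10)
  grid <- expand.grid(mu1 = c(0.5, 2, 10), mu2 = c(1, 7, 25),
                      pi = c(0.1, 0.5, 0.9))
  for (i in seq_len(nrow(grid))) {
    y_max <- ceiling(max(grid$mu1[i], grid$mu2[i]) + 30 *
                       sqrt(max(grid$mu1[i], grid$mu2[i])))
    total <- sum(exp(mixture_log_pmf(0:y_max, grid$mu1[i], grid$mu2[i],
                                     grid$pi[i])))
    expect_equal(total, 1, tolerance = 1e-10)
  }
  # log-space contract: large counts and rates stay finite
  expect_true(is.finite(mixture_log_pmf(1000, 1000, 900, 0.4)))
})

test_that("marginalized substitution recovers mu2 and round-trips", {
  expect_equal(mu2_from_marginal(2, 1, 0.5), 3)
  expect_equal(mu2_from_marginal(2, 1, 1e-12), 2, tolerance = 1e-9)
  expect_error(mu2_from_marginal(1, 4, 0.5), "outside the model's support")
  expect_error(mu2_from_marginal(2, 1, 0), "strictly inside")
  set.seed(11)
  for (i in 1:25) {
    mu <- runif(1, 0.5, 10); pi <- runif(1, 0.05, 0.95)
    mu1 <- runif(1, 0, mu / pi) # guarantees mu2 > 0
    mu2 <- mu2_from_marginal(mu, mu1, pi)
    expect_equal(pi * mu1 + (1 - pi) * mu2, mu, tolerance = 1e-12)
  }
})

test_that("closed-form marginal moments agree with brute-force pmf moments", {
  m <- marginal_moments(3, 3, 0.7)
  expect_equal(m$mu, 3)
  expect_equal(m$var, 3)
  m <- marginal_moments(1, 3, 0.5)
  expect_equal(m$mu, 2)
  expect_equal(m$var, 3)
  grid <- expand.grid(mu1 = c(0.5, 2, 6), mu2 = c(1, 7, 12),
                      pi = c(0.1, 0.3, 0.8))
  for (i in seq_len(nrow(grid))) {
    m <- marginal_moments(grid$mu1[i], grid$mu2[i], grid$pi[i])
    o <- moments_brute(grid$mu1[i], grid$mu2[i], grid$pi[i])
    expect_equal(m$mu, o$mu, tolerance = 1e-8)
    expect_equal(m$var, o$var, tolerance = 1e-8)
    expect_gte(m$var, m$mu) # overdispersion is never negative
  }
})

test_that("eta equals the implied component-2 mean", {
  # intercept-only: beta0 = log 2, alpha0 = 0, tau = 0 => mu2 = 2*2 - 1 = 3
  p <- mpp_params(log(2), 0, 0)
  expect_equal(eta_mpp(p, 1, 1), 3)
  expect_equal(eta_mpp(p, 1, 1),
               mu2_from_marginal(2, 1, 0.5) * (1 + exp(0)) * (1 - p$pi))
  # pi -> 0 limit: eta -> exp(x'beta)
  p <- mpp_params(c(1, 0.5), c(0.2, 0.1), -30)
  X <- cbind(1, c(0, 1))
  expect_equal(eta_mpp(p, X, X), exp(X %*% c(1, 0.5))[, 1],
               tolerance = 1e-10)
  # identity eta = (1 + e^tau)(1 - pi) mu2 on random draws
  set.seed(21)
  for (i in 1:20) {
    cs <- draw_valid_case(n = 10)
    pars <- cs$params
    mu <- exp(cs$X %*% pars$beta)[, 1]
    mu1 <- exp(cs$Z %*% pars$alpha)[, 1]
    mu2 <- mu2_from_marginal(mu, mu1, pars$pi)
    expect_equal(eta_mpp(pars, cs$X, cs$Z),
                 (1 + exp(pars$tau)) * (1 - pars$pi) * mu2,
                 tolerance = 1e-10)
  }
  # sign equivalence: mu2 <= 0 exactly when eta <= 0
  p_bad <- mpp_params(0, 2, 0) # mu2 = 2 - e^2 < 0
  expect_lt(eta_mpp(p_bad, 1, 1), 0)
})

test_that("marginalized log-likelihood equals the latent-class oracle", {
  # n = 1, y = 0, both components Poisson(1), pi = 1/2
  p <- mpp_params(0, 0, 0)
  expect_equal(as.numeric(marginalized_loglik(p, 0, matrix(1), matrix(1))),
               -1)
  set.seed(31)
  for (i in 1:20) {
    cs <- draw_valid_case(n = 200)
    pars <- cs$params
    mu <- exp(cs$X %*% pars$beta)[, 1]
    mu1 <- exp(cs$Z %*% pars$alpha)[, 1]
    mu2 <- mu2_from_marginal(mu, mu1, pars$pi)
    ll <- marginalized_loglik(pars, cs$y, cs$X, cs$Z)
    expect_true(attr(ll, "valid"))
    expect_equal(as.numeric(ll), loglik_direct(cs$y, mu1, mu2, pars$pi),
                 tolerance = 1e-8)
    expect_equal(as.numeric(ll),
                 sum(mixture_log_pmf(cs$y, mu1, mu2, pars$pi)),
                 tolerance = 1e-10)
  }
})

test_that("pi -> 0 reduces the likelihood to a single Poisson", {
  set.seed(41)
  x <- rbinom(150, 1, 0.5)
  X <- cbind(1, x)
  beta <- c(1.2, -0.3)
  y <- rpois(150, exp(X %*% beta))
  p <- mpp_params(beta, c(0.5, 0), -30)
  ll <- as.numeric(marginalized_loglik(p, y, X, X))
  ll_pois <- sum(dpois(y, exp(X %*% beta)[, 1], log = TRUE))
  expect_equal(ll, ll_pois, tolerance = 1e-6)
  # pi -> 1: single Poisson with the component-1 mean
  p1 <- mpp_params(beta, beta, 30)
  ll1 <- as.numeric(marginalized_loglik(p1, y, X, X))
  expect_equal(ll1, ll_pois, tolerance = 1e-6)
})

test_that("invalid parameter regions return the penalized value, not an error", {
  p_bad <- mpp_params(0, 2, 0)
  y <- c(0, 1, 2)
  X <- matrix(1, 3, 1)
  ll <- marginalized_loglik(p_bad, y, X, X)
  expect_false(attr(ll, "valid"))
  eta <- eta_mpp(p_bad, X, X)
  expect_equal(as.numeric(ll), -1e10 - sum(pmax(0, -eta)))
  # penalty grows with the violation so a line search can retreat
  p_worse <- mpp_params(0, 3, 0)
  expect_lt(as.numeric(marginalized_loglik(p_worse, y, X, X)),
            as.numeric(ll))
})
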