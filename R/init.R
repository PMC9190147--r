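#' EM starting values from the latent-class Poisson-Poisson mixture
#'
#' Fits the two-component latent-class Poisson mixture with log-linear
#' component means (both components regressed on `Z`) and a free mixing
#' weight, by expectation-maximization. The E-step computes posterior class
#' probabilities from the current component pmfs; the M-step runs
#' responsibility-weighted Poisson regressions and sets the mixing weight to
#' the mean responsibility. Responsibilities are initialized by splitting
#' subjects at the outcome median, so the default run is deterministic.
#' After convergence, component 1 is the component with the smaller fitted
#' intercept, and `tau = logit(pi)` with `pi` clamped to \[0.01, 0.99\]
#' (starting values only; the final fit is unclamped).
#'
#' @param y Non-negative integer counts.
#' @param Z Component design matrix (intercept first).
#' @param tol Convergence tolerance on the relative change of the
#'   observed-data log-likelihood (default 1e-8).
#' @param max_iter Maximum EM iterations (default 500). Non-convergence
#'   returns the best iterate with a warning, not an error.
#' @param random_start If `TRUE`, initialize responsibilities uniformly at
#'   random instead of by the median split.
#' @param seed Optional seed, used only when `random_start = TRUE`.
#' @return A list: `alpha` (component-1 coefficients), `tau`, `pi`, `trace`
#'   (an `em_trace` with `loglik_path`, `responsibilities`, `iterations`,
#'   `converged`), and `coef2` (component-2 coefficients, diagnostics only).
#' @export
em_poisson_mixture <- function(y, Z, tol = 1e-8, max_iter = 500L,
                               random_start = FALSE, seed = NULL) {
  check_counts(y)
  Z <- rbind_if_vector(Z, 1L)
  stopifnot(nrow(Z) == length(y), max_iter >= 1L)
  n <- length(y)
  if (random_start) {
    if (!is.null(seed)) set.seed(seed)
    r1 <- stats::runif(n)
  } else {
    r1 <- as.numeric(y <= stats::median(y))
    # degenerate split (all counts equal): nudge to keep both components alive
    if (all(r1 == 1) || all(r1 == 0)) r1 <- rep(0.5, n)
  }

  wpois <- function(w) {
    # responsibility-weighted Poisson regression; tiny floor keeps glm.fit
    # happy when a component is nearly empty
    w <- pmax(w, 1e-10)
    fit <- suppressWarnings(
      stats::glm.fit(Z, y, weights = w, family = stats::poisson())
    )
    fit$coefficients
  }

  loglik_path <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  coef1 <- coef2 <- NULL
  pi <- mean(r1)
  for (it in seq_len(max_iter)) {
    # M-step
    coef1 <- wpois(r1)
    coef2 <- wpois(1 - r1)
    pi <- mean(r1)
    pi_e <- min(max(pi, 1e-12), 1 - 1e-12)
    mu1 <- drop(exp(Z %*% coef1))
    mu2 <- drop(exp(Z %*% coef2))
    # E-step + observed-data log-likelihood
    l1 <- log(pi_e) + stats::dpois(y, mu1, log = TRUE)
    l2 <- log(1 - pi_e) + stats::dpois(y, mu2, log = TRUE)
    den <- logsumexp2(l1, l2)
    r1 <- exp(l1 - den)
    ll <- sum(den)
    loglik_path <- c(loglik_path, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged) {
    warning("EM did not converge in ", max_iter, " iterations; ",
            "returning the last iterate.", call. = FALSE)
  }

  # label rule: component 1 has the smaller fitted intercept
  if (coef1[1L] > coef2[1L]) {
    tmp <- coef1; coef1 <- coef2; coef2 <- tmp
    pi <- 1 - pi
    r1 <- 1 - r1
  }
  if (pi < 0.01 || pi > 0.99) {
    warning(sprintf(
      "EM mixing proportion %.4f outside [0.01, 0.99]; clamped for starting values.",
      pi), call. = FALSE)
    pi <- min(max(pi, 0.01), 0.99)
  }
  trace <- structure(
    list(loglik_path = loglik_path,
         responsibilities = cbind(comp1 = r1, comp2 = 1 - r1),
         iterations = length(loglik_path), converged = converged),
    class = "em_trace"
  )
  list(alpha = unname(coef1), tau = stats::qlogis(pi), pi = pi,
       trace = trace, coef2 = unname(coef2))
}

#' Marginalized zero-inflated Poisson starting values for beta
#'
#' Fits a ZIP model in its marginal-mean parameterization: structural-zero
#' probability `psi` with an intercept-only logit (`logit(psi) = gamma0`) and
#' marginal mean `nu_i = (1 - psi) * lambda_i` with `log(nu_i) = x_i'beta`,
#' so `beta` acts on the overall mean just as in the mixture model. The
#' likelihood is maximized by quasi-Newton (BFGS) over `(gamma0, beta)`. With
#' no zero counts in the data, the ZIP zero mass is not identified and plain
#' Poisson regression coefficients are returned with a warning.
#'
#' @param y Non-negative integer counts.
#' @param X Marginal-mean design matrix (intercept first).
#' @param tol Relative function-convergence tolerance (default 1e-9).
#' @param max_iter Maximum BFGS iterations (default 500).
#' @return A list: `beta` (the marginal-mean coefficients), `gamma0`, `psi`,
#'   `loglik`, `converged`, `fallback` (`TRUE` when the Poisson fallback was
#'   used).
#' @export
fit_mzip <- function(y, X, tol = 1e-9, max_iter = 500L) {
  check_counts(y)
  X <- rbind_if_vector(X, 1L)
  stopifnot(nrow(X) == length(y))
  pois <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::poisson())
  )
  beta0 <- pois$coefficients
  if (!any(y == 0)) {
    warning("no zero counts: structural-zero mass is not identified; ",
            "returning plain Poisson regression coefficients.",
            call. = FALSE)
    return(list(beta = unname(beta0), gamma0 = -Inf, psi = 0,
                loglik = sum(stats::dpois(y, exp(drop(X %*% beta0)),
                                          log = TRUE)),
                converged = TRUE, fallback = TRUE))
  }

  is0 <- y == 0
  negll <- function(theta) {
    g0 <- theta[1L]
    beta <- theta[-1L]
    psi <- stats::plogis(g0)
    nu <- exp(drop(X %*% beta))
    lam <- nu / (1 - psi)
    ll <- numeric(length(y))
    # P(0) = psi + (1 - psi) e^{-lambda}, in log space
    ll[is0] <- logsumexp2(rep(log(psi), sum(is0)),
                          log1p(-psi) - lam[is0])
    ll[!is0] <- log1p(-psi) + stats::dpois(y[!is0], lam[!is0], log = TRUE)
    s <- sum(ll)
    if (!is.finite(s)) 1e12 else -s
  }
  # start gamma0 at the observed excess of zeros over the Poisson fit
  p0_obs <- mean(is0)
  p0_pois <- mean(exp(-pois$fitted.values))
  psi_start <- min(max((p0_obs - p0_pois) / max(1 - p0_pois, 1e-6), 0.02), 0.9)
  opt <- stats::optim(
    c(stats::qlogis(psi_start), beta0), negll, method = "BFGS",
    control = list(maxit = max_iter, reltol = tol)
  )
  list(beta = unname(opt$par[-1L]), gamma0 = opt$par[1L],
       psi = stats::plogis(opt$par[1L]), loglik = -opt$value,
       converged = opt$convergence == 0L, fallback = FALSE)
}

#' Combined starting values for the marginalized mixture fit
#'
#' `(tau, alpha)` from [em_poisson_mixture()] on the latent-class mixture and
#' `beta` from [fit_mzip()], as an [mpp_params] object. If the combination
#' implies a non-positive component-2 mean on some rows, the component-1
#' intercept is stepped down (in 0.25 decrements, up to 20 times) until the
#' start is valid; the marginal-mean part is never altered.
#'
#' @param y,X,Z Outcome and design matrices as in [marginalized_loglik()].
#' @param ... Passed to [em_poisson_mixture()].
#' @return An [mpp_params] starting value with attribute `em_trace`.
#' @export
mpp_start <- function(y, X, Z, ...) {
  em <- em_poisson_mixture(y, Z, ...)
  mz <- fit_mzip(y, X)
  start <- mpp_params(beta = mz$beta, alpha = em$alpha, tau = em$tau)
  for (k in seq_len(20L)) {
    if (all(eta_mpp(start, X, Z) > 0)) break
    start$alpha[1L] <- start$alpha[1L] - 0.25
  }
  if (any(eta_mpp(start, X, Z) <= 0)) {
    stop("could not construct a valid starting value (component-2 mean ",
         "non-positive); consider a simpler component model.", call. = FALSE)
  }
  attr(start, "em_trace") <- em$trace
  start
}
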