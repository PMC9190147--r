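#' Parameter set for the marginalized Poisson-Poisson mixture
#'
#' Bundles the three parameter blocks of the MPois-Pois model: `beta`, the
#' coefficients of the log marginal mean (`log(mu) = x'beta`); `alpha`, the
#' coefficients of the log component-1 mean (`log(mu1) = z'alpha`); and `tau`,
#' the logit of the mixing proportion `pi = exp(tau) / (1 + exp(tau))`, the
#' probability of latent component 1.
#'
#' @param beta Numeric vector of marginal-mean coefficients (first entry is
#'   the intercept).
#' @param alpha Numeric vector of component-1 coefficients.
#' @param tau Scalar, logit of the mixing proportion.
#' @return An object of class `mpp_params`: a named list with elements
#'   `beta`, `alpha`, `tau` and derived `pi`.
#' @examples
#' mpp_params(beta = c(1.36, -0.11), alpha = c(1.0, -0.11), tau = 0.447)
#' @export
mpp_params <- function(beta, alpha, tau) {
  beta <- as.numeric(beta)
  alpha <- as.numeric(alpha)
  tau <- as.numeric(tau)
  if (length(tau) != 1L || !is.finite(tau)) {
    stop("`tau` must be a single finite number.", call. = FALSE)
  }
  if (!all(is.finite(beta)) || !all(is.finite(alpha))) {
    stop("`beta` and `alpha` must be finite.", call. = FALSE)
  }
  structure(
    list(beta = beta, alpha = alpha, tau = tau, pi = stats::plogis(tau)),
    class = "mpp_params"
  )
}

#' @export
print.mpp_params <- function(x, ...) {
  cat("MPois-Pois parameters\n")
  cat("  beta :", format(x$beta, digits = 4), "\n")
  cat("  alpha:", format(x$alpha, digits = 4), "\n")
  cat(sprintf("  tau  : %.4f  (pi = %.4f)\n", x$tau, x$pi))
  invisible(x)
}

# Stable log(1 + exp(x)).
log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# Numerically stable log(sum(exp(.))) along rows of a two-column matrix.
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  # both -Inf: log(0 + 0) = -Inf without NaN from exp(-Inf - -Inf)
  out <- m + log(exp(a - m) + exp(b - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

check_counts <- function(y) {
  if (!is.numeric(y) || any(!is.finite(y)) || any(y < 0) ||
      any(y != floor(y))) {
    stop("counts must be finite non-negative integers.", call. = FALSE)
  }
  invisible(y)
}

#' Log-probability mass of the two-component Poisson mixture
#'
#' Evaluates `log[pi * Pois(y; mu1) + (1 - pi) * Pois(y; mu2)]` with the sum
#' taken in log space (log-sum-exp), so counts and rates into the thousands do
#' not overflow.
#'
#' @param y Non-negative integer count(s).
#' @param mu1,mu2 Positive component means (recycled against `y`).
#' @param pi Mixing proportion in (0, 1]; the weight of component 1.
#' @return Log-probabilities, same length as the recycled arguments.
#' @examples
#' mixture_log_pmf(0, mu1 = 1, mu2 = 1, pi = 0.5) # log P(Y = 0) = -1
#' @export
mixture_log_pmf <- function(y, mu1, mu2, pi) {
  check_counts(y)
  if (any(mu1 <= 0) || any(mu2 <= 0)) {
    stop("`mu1` and `mu2` must be positive.", call. = FALSE)
  }
  if (any(pi <= 0) || any(pi > 1)) {
    stop("`pi` must lie in (0, 1].", call. = FALSE)
  }
  l1 <- log(pi) + stats::dpois(y, mu1, log = TRUE)
  if (all(pi == 1)) return(l1)
  l2 <- log1p(-pi) + stats::dpois(y, mu2, log = TRUE)
  logsumexp2(l1, l2)
}

#' Recover the component-2 mean from the marginal mean
#'
#' The marginalized parameterization replaces the component-2 mean by
#' `mu2 = (mu - pi * mu1) / (1 - pi)`, so that `mu` is the population mean
#' `E(Y) = pi * mu1 + (1 - pi) * mu2`. The combination is only admissible when
#' the implied `mu2` is positive.
#'
#' @param mu Positive marginal mean.
#' @param mu1 Positive component-1 mean.
#' @param pi Mixing proportion strictly inside (0, 1).
#' @return The implied component-2 mean (vectorized).
#' @examples
#' mu2_from_marginal(mu = 2, mu1 = 1, pi = 0.5) # 3
#' @export
mu2_from_marginal <- function(mu, mu1, pi) {
  if (any(pi <= 0) || any(pi >= 1)) {
    stop("`pi` must lie strictly inside (0, 1).", call. = FALSE)
  }
  mu2 <- (mu - pi * mu1) / (1 - pi)
  if (any(mu2 <= 0)) {
    bad <- which(mu2 <= 0)
    stop(sprintf(
      "implied mu2 <= 0 at position(s) %s: the parameter combination lies outside the model's support.",
      paste(utils::head(bad, 5L), collapse = ", ")
    ), call. = FALSE)
  }
  mu2
}

#' Marginal moments of the two-component Poisson mixture
#'
#' @param mu1,mu2 Positive component means.
#' @param pi Mixing proportion in \[0, 1\].
#' @return A tibble with columns `mu` (marginal mean `pi*mu1 + (1-pi)*mu2`),
#'   `mu1`, `mu2`, and `var` (`mu + pi*(1-pi)*(mu1 - mu2)^2`); the variance
#'   always exceeds the mean unless the components coincide (overdispersion).
#' @examples
#' marginal_moments(mu1 = 1, mu2 = 3, pi = 0.5) # mu = 2, var = 3
#' @export
marginal_moments <- function(mu1, mu2, pi) {
  if (any(mu1 <= 0) || any(mu2 <= 0)) {
    stop("`mu1` and `mu2` must be positive.", call. = FALSE)
  }
  if (any(pi < 0) || any(pi > 1)) {
    stop("`pi` must lie in [0, 1].", call. = FALSE)
  }
  mu <- pi * mu1 + (1 - pi) * mu2
  tibble::tibble(
    mu = mu, mu1 = mu1, mu2 = mu2,
    var = mu + pi * (1 - pi) * (mu1 - mu2)^2
  )
}

#' The eta function of the marginalized likelihood
#'
#' `eta = exp(x'beta) * (1 + exp(tau)) - exp(tau) * exp(z'alpha)`. Because
#' `1 - pi = 1 / (1 + exp(tau))`, eta is exactly the component-2 mean implied
#' by the marginalized substitution, and the model is valid at a design row
#' precisely when eta is positive there.
#'
#' @param params An [mpp_params] object.
#' @param X Marginal-mean design matrix (or a single row as a vector).
#' @param Z Component-1 design matrix conformable with `params$alpha`.
#' @return Numeric vector of eta values, one per design row.
#' @export
eta_mpp <- function(params, X, Z) {
  X <- rbind_if_vector(X, length(params$beta))
  Z <- rbind_if_vector(Z, length(params$alpha))
  et <- exp(params$tau)
  drop(exp(X %*% params$beta) * (1 + et) - et * exp(Z %*% params$alpha))
}

rbind_if_vector <- function(M, p) {
  if (is.null(dim(M))) M <- matrix(M, ncol = p)
  M
}

# Penalized value used when any eta_i <= 0: large negative, decreasing in the
# total constraint violation so line searches retreat smoothly.
penalized_loglik <- function(eta) {
  -1e10 - sum(pmax(0, -eta))
}

#' Marginalized log-likelihood of the MPois-Pois model
#'
#' Evaluates the observed-data log-likelihood
#' `sum_i log{ (1 + e^tau)^{-1} (y_i!)^{-1} [ e^tau e^{-mu1_i} mu1_i^{y_i}
#'   + e^{-eta_i} eta_i^{y_i} ] }`, with the bracket computed by log-sum-exp.
#' When every `eta_i` is positive this equals the latent-class mixture
#' log-likelihood at `(pi, mu1_i, mu2_i = eta_i)`. Parameter sets with any
#' `eta_i <= 0` lie outside the model's support; instead of raising an error
#' the function returns a large negative penalized value (`-1e10` minus the
#' total violation) so that unconstrained quasi-Newton searches back away.
#'
#' @param params An [mpp_params] object.
#' @param y Non-negative integer counts.
#' @param X Marginal-mean design matrix, `length(y)` rows, intercept first.
#' @param Z Component-1 design matrix, `length(y)` rows.
#' @return A single number with attribute `valid` (`TRUE` when all
#'   `eta_i > 0`).
#' @export
marginalized_loglik <- function(params, y, X, Z) {
  check_counts(y)
  X <- rbind_if_vector(X, length(params$beta))
  Z <- rbind_if_vector(Z, length(params$alpha))
  stopifnot(nrow(X) == length(y), nrow(Z) == length(y))
  tau <- params$tau
  za <- drop(Z %*% params$alpha)
  eta <- drop(exp(X %*% params$beta) * (1 + exp(tau)) - exp(tau + za))
  if (any(eta <= 0)) {
    return(structure(penalized_loglik(eta), valid = FALSE))
  }
  # log of the bracket: LSE(tau - e^{za} + y*za, -eta + y*log(eta))
  l1 <- tau - exp(za) + y * za
  l2 <- -eta + y * log(eta)
  ll <- sum(logsumexp2(l1, l2) - log1pexp(tau) - lgamma(y + 1))
  structure(ll, valid = TRUE)
}
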