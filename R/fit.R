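#' Control settings for the mixture fit
#'
#' @param reltol Relative function-convergence tolerance of the BFGS search
#'   (default 1e-9).
#' @param maxit Maximum BFGS iterations (default 1000).
#' @param em_tol,em_maxit Convergence settings of the EM initialization.
#' @return A list of class `mpp_control`.
#' @export
mpp_control <- function(reltol = 1e-9, maxit = 1000L,
                        em_tol = 1e-8, em_maxit = 500L) {
  structure(list(reltol = reltol, maxit = maxit,
                 em_tol = em_tol, em_maxit = em_maxit),
            class = "mpp_control")
}

# theta <-> params packing
theta_pack <- function(params) c(params$beta, params$alpha, params$tau)
theta_unpack <- function(theta, p1, p2) {
  mpp_params(beta = theta[seq_len(p1)],
             alpha = theta[p1 + seq_len(p2)],
             tau = theta[p1 + p2 + 1L])
}

#' Fit the marginalized Poisson-Poisson mixture model
#'
#' Maximizes the marginalized likelihood over `(beta, alpha, tau)` jointly by
#' quasi-Newton (BFGS with numerical gradients). Starting values come from
#' [mpp_start()] (EM for `tau`/`alpha`, MZIP for `beta`) unless supplied.
#' Standard errors are square roots of the diagonal of the inverse observed
#' information (central-difference numerical Hessian).
#'
#' @param data A data frame, one row per subject, complete cases only.
#' @param formula Model formula for the marginal mean, e.g.
#'   `anc_visits ~ study_continuity + residence`. Exponentiated coefficients
#'   are incidence density ratios for the population mean.
#' @param component_formula Optional one-sided formula for the component-1
#'   mean; by default the component shares the marginal covariates.
#' @param starts Optional [mpp_params] starting value; must satisfy
#'   `eta_i > 0` on every row.
#' @param control An [mpp_control()] list.
#' @return An object of class `mpp_fit` with `tidy()`, `glance()`,
#'   `autoplot()` and `print()` methods. Key elements: `params` (estimates as
#'   [mpp_params]), `se`, `vcov`, `loglik`, `aic`, `converged`,
#'   `validity_violations` (rows with non-positive `eta` at the optimum;
#'   must be 0 for a valid fit), `start`, `em_trace`.
#' @examples
#' sim <- simulate_bdhs(n = 400, seed = 7)
#' fit <- fit_mpp(sim, anc_visits ~ residence + media_exposure)
#' glance(fit)
#' @export
fit_mpp <- function(data, formula, component_formula = NULL, starts = NULL,
                    control = mpp_control()) {
  des <- mpp_design(data, formula, component_formula)
  if (is.null(des$y)) stop("`formula` needs an outcome.", call. = FALSE)
  fit <- fit_mpp_design(des$y, des$X, des$Z, starts = starts,
                        control = control)
  fit$terms <- des$terms
  fit$xlevels <- des$xlevels
  fit$assign <- des$assign
  fit$formula <- formula
  fit
}

# Core fit on (y, X, Z); used directly by simulation studies to skip the
# model-frame machinery.
fit_mpp_design <- function(y, X, Z, starts = NULL, control = mpp_control()) {
  p1 <- ncol(X); p2 <- ncol(Z)
  if (is.null(starts)) {
    starts <- mpp_start(y, X, Z, tol = control$em_tol,
                        max_iter = control$em_maxit)
  }
  if (any(eta_mpp(starts, X, Z) <= 0)) {
    stop("starting values imply a non-positive component-2 mean.",
         call. = FALSE)
  }
  negll <- function(theta) {
    -as.numeric(marginalized_loglik(theta_unpack(theta, p1, p2), y, X, Z))
  }
  opt <- stats::optim(theta_pack(starts), negll, method = "BFGS",
                      control = list(maxit = control$maxit,
                                     reltol = control$reltol))
  theta_hat <- opt$par
  params <- theta_unpack(theta_hat, p1, p2)
  names(params$beta) <- colnames(X)
  names(params$alpha) <- colnames(Z)
  ll <- marginalized_loglik(params, y, X, Z)
  violations <- sum(eta_mpp(params, X, Z) <= 0)
  if (violations > 0) {
    stop("the optimum lies in the penalized region (", violations,
         " rows with non-positive component-2 mean); re-initialize with ",
         "different starting values.", call. = FALSE)
  }
  hess <- num_hessian(function(th) -negll(th), theta_hat)
  sev <- observed_information_se(hessian = hess)
  k <- p1 + p2 + 1L
  theta_names <- c(colnames(X), paste0("alpha:", colnames(Z)), "tau")
  structure(
    list(
      params = params,
      theta = stats::setNames(theta_hat, theta_names),
      se = stats::setNames(sev$se, theta_names),
      vcov = sev$vcov,
      loglik = as.numeric(ll),
      aic = -2 * as.numeric(ll) + 2 * k,
      n_params = k,
      n_obs = length(y),
      converged = opt$convergence == 0L,
      validity_violations = violations,
      model_name = "MPois-Pois",
      start = starts,
      start_loglik = as.numeric(marginalized_loglik(starts, y, X, Z)),
      em_trace = attr(starts, "em_trace"),
      optim_counts = opt$counts,
      y = y, X = X, Z = Z
    ),
    class = "mpp_fit"
  )
}

# Central-difference Hessian with per-coordinate step h_j = max(1e-5,
# 1e-5 * |theta_j|).
num_hessian <- function(f, theta) {
  p <- length(theta)
  h <- pmax(1e-5, 1e-5 * abs(theta))
  H <- matrix(NA_real_, p, p)
  f0 <- f(theta)
  shift <- function(i, s) {
    th <- theta; th[i] <- th[i] + s; th
  }
  for (j in seq_len(p)) {
    H[j, j] <- (f(shift(j, h[j])) - 2 * f0 + f(shift(j, -h[j]))) / h[j]^2
    if (j < p) {
      for (k in (j + 1L):p) {
        tpp <- theta; tpp[j] <- tpp[j] + h[j]; tpp[k] <- tpp[k] + h[k]
        tpm <- theta; tpm[j] <- tpm[j] + h[j]; tpm[k] <- tpm[k] - h[k]
        tmp <- theta; tmp[j] <- tmp[j] - h[j]; tmp[k] <- tmp[k] + h[k]
        tmm <- theta; tmm[j] <- tmm[j] - h[j]; tmm[k] <- tmm[k] - h[k]
        H[j, k] <- H[k, j] <-
          (f(tpp) - f(tpm) - f(tmp) + f(tmm)) / (4 * h[j] * h[k])
      }
    }
  }
  H
}

#' Standard errors from the observed information
#'
#' Inverts the negative Hessian of the log-likelihood at the optimum and
#' takes square roots of the diagonal. Supply either `loglik_fn` plus
#' `theta_hat` (the Hessian is computed by central differences with step
#' `max(1e-5, 1e-5 * |theta|)`) or a precomputed `hessian`. A
#' non-positive-definite information matrix yields a warning and `NaN`
#' standard errors for the affected components.
#'
#' @param loglik_fn Log-likelihood function of the full parameter vector.
#' @param theta_hat Parameter vector at the optimum.
#' @param hessian Optional precomputed Hessian of the log-likelihood.
#' @return A list with `se` and `vcov`.
#' @export
observed_information_se <- function(loglik_fn = NULL, theta_hat = NULL,
                                    hessian = NULL) {
  if (is.null(hessian)) {
    stopifnot(!is.null(loglik_fn), !is.null(theta_hat))
    hessian <- num_hessian(loglik_fn, theta_hat)
  }
  info <- -hessian
  vcov <- tryCatch(solve(info), error = function(e) NULL)
  p <- nrow(info)
  if (is.null(vcov) || any(diag(vcov) <= 0)) {
    warning("observed information is not positive definite; ",
            "NaN standard errors for affected components.", call. = FALSE)
    if (is.null(vcov)) vcov <- matrix(NaN, p, p)
  }
  d <- diag(vcov)
  se <- ifelse(is.finite(d) & d > 0, sqrt(pmax(d, 0)), NaN)
  list(se = se, vcov = vcov)
}

#' Mixing proportion on the probability scale
#'
#' Back-transforms `tau` and its standard error to the mixing proportion
#' `pi = plogis(tau)` with the delta-method standard error
#' `se_pi = pi * (1 - pi) * se_tau`, plus the Wald z statistic `pi / se_pi`
#' and its two-sided normal p-value, matching the reporting convention of the
#' fitted-model table's mixing-proportion row.
#'
#' @param tau_hat Estimated logit of the mixing proportion.
#' @param se_tau Its standard error (positive).
#' @return A tibble with `pi_hat`, `se_pi`, `z`, `p`.
#' @examples
#' mixing_proportion(0, 0.4) # pi = 0.5, se = 0.1
#' @export
mixing_proportion <- function(tau_hat, se_tau) {
  stopifnot(se_tau > 0)
  pi_hat <- stats::plogis(tau_hat)
  se_pi <- pi_hat * (1 - pi_hat) * se_tau
  z <- pi_hat / se_pi
  tibble::tibble(pi_hat = pi_hat, se_pi = se_pi, z = z,
                 p = 2 * stats::pnorm(-abs(z)))
}

#' Poisson and negative binomial baselines
#'
#' Log-linear Poisson regression and NB2 negative binomial regression on the
#' same marginal-mean formula, reported on the same log-likelihood/AIC scale
#' as the mixture fit so the three models are directly comparable. If the NB
#' dispersion estimate diverges (equidispersion), the Poisson fit is returned
#' with a warning.
#'
#' @param data A data frame, complete cases only.
#' @param formula Model formula as in [fit_mpp()].
#' @return An object of class `count_fit`: coefficients, `se`, `loglik`,
#'   `aic` (`-2 loglik + 2 k`, with `k` counting the NB dispersion), `fit`
#'   (the underlying `glm`), `model_name`.
#' @export
fit_poisson <- function(data, formula) {
  g <- stats::glm(formula, data = data, family = stats::poisson())
  as_count_fit(g, "Poisson", extra_params = 0L)
}

#' @rdname fit_poisson
#' @export
fit_negbin <- function(data, formula) {
  g <- tryCatch(
    suppressWarnings(MASS::glm.nb(formula, data = data)),
    error = function(e) NULL
  )
  if (is.null(g) || !is.finite(g$theta) || g$theta > 1e5) {
    warning("negative binomial dispersion diverged (equidispersion); ",
            "falling back to Poisson.", call. = FALSE)
    return(fit_poisson(data, formula))
  }
  as_count_fit(g, "Negative binomial", extra_params = 1L)
}

as_count_fit <- function(g, name, extra_params) {
  ll <- as.numeric(stats::logLik(g))
  k <- length(stats::coef(g)) + extra_params
  structure(
    list(
      coefficients = stats::coef(g),
      se = sqrt(diag(stats::vcov(g))),
      loglik = ll, aic = -2 * ll + 2 * k, n_params = k,
      n_obs = stats::nobs(g), converged = g$converged %||% TRUE,
      model_name = name, fit = g
    ),
    class = "count_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mpp_fit <- function(x, ...) {
  cat("Marginalized Poisson-Poisson mixture fit\n")
  cat(sprintf("  n = %d, logLik = %.2f, AIC = %.1f, converged: %s\n",
              x$n_obs, x$loglik, x$aic, x$converged))
  pr <- mixing_proportion(x$params$tau, x$se[length(x$se)])
  cat(sprintf("  mixing proportion: %.3f (SE %.3f)\n", pr$pi_hat, pr$se_pi))
  cat("\nMarginal-mean coefficients (IDR = exp(estimate)):\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @export
print.count_fit <- function(x, ...) {
  cat(sprintf("%s regression: n = %d, logLik = %.2f, AIC = %.1f\n",
              x$model_name, x$n_obs, x$loglik, x$aic))
  invisible(x)
}

#' Tidy the mixture fit
#'
#' Broom-style coefficient table. `component = "marginal"` (default) returns
#' the marginal-mean block `beta`, whose exponentials are incidence density
#' ratios; `"component"` the component-1 block `alpha`; `"mixing"` the
#' mixing-proportion row on the probability scale; `"all"` the full
#' parameter vector on the estimation scale.
#'
#' @param x An `mpp_fit`.
#' @param component Which block to return.
#' @param conf.int,conf.level Wald interval switches (normal quantile).
#' @param exponentiate If `TRUE`, report `exp(estimate)` (IDR) and
#'   exponentiated interval bounds; standard errors stay on the log scale.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value` and, with `conf.int`, `conf.low`/`conf.high`.
#' @method tidy mpp_fit
#' @export
tidy.mpp_fit <- function(x, component = c("marginal", "component", "mixing",
                                          "all"),
                         conf.int = TRUE, conf.level = 0.95,
                         exponentiate = FALSE, ...) {
  component <- match.arg(component)
  p1 <- length(x$params$beta)
  p2 <- length(x$params$alpha)
  idx <- switch(component,
    marginal = seq_len(p1),
    component = p1 + seq_len(p2),
    all = seq_len(p1 + p2 + 1L),
    mixing = p1 + p2 + 1L
  )
  if (component == "mixing") {
    pr <- mixing_proportion(x$params$tau, x$se[idx])
    out <- tibble::tibble(
      term = "pi", estimate = pr$pi_hat, std.error = pr$se_pi,
      statistic = pr$z, p.value = pr$p
    )
    if (conf.int) {
      zq <- stats::qnorm(1 - (1 - conf.level) / 2)
      out$conf.low <- out$estimate - zq * out$std.error
      out$conf.high <- out$estimate + zq * out$std.error
    }
    return(out)
  }
  est <- x$theta[idx]
  se <- x$se[idx]
  out <- tibble::tibble(
    term = names(x$theta)[idx],
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * stats::pnorm(-abs(unname(est / se)))
  )
  if (conf.int) {
    zq <- stats::qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - zq * out$std.error
    out$conf.high <- out$estimate + zq * out$std.error
  }
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    if (conf.int) {
      out$conf.low <- exp(out$conf.low)
      out$conf.high <- exp(out$conf.high)
    }
  }
  out
}

#' Glance at the mixture fit
#'
#' @param x An `mpp_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `logLik`, `AIC`, `n_params`, `nobs`, `pi`,
#'   `pi_se`, `converged`, `validity_violations`.
#' @method glance mpp_fit
#' @export
glance.mpp_fit <- function(x, ...) {
  pr <- mixing_proportion(x$params$tau, x$se[length(x$se)])
  tibble::tibble(
    logLik = x$loglik, AIC = x$aic, n_params = x$n_params, nobs = x$n_obs,
    pi = pr$pi_hat, pi_se = pr$se_pi,
    converged = x$converged, validity_violations = x$validity_violations
  )
}

#' @method tidy count_fit
#' @export
tidy.count_fit <- function(x, conf.int = TRUE, conf.level = 0.95,
                           exponentiate = FALSE, ...) {
  est <- x$coefficients
  se <- x$se
  out <- tibble::tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * stats::pnorm(-abs(unname(est / se)))
  )
  if (conf.int) {
    zq <- stats::qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - zq * out$std.error
    out$conf.high <- out$estimate + zq * out$std.error
  }
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    if (conf.int) {
      out$conf.low <- exp(out$conf.low)
      out$conf.high <- exp(out$conf.high)
    }
  }
  out
}

#' @method glance count_fit
#' @export
glance.count_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, AIC = x$aic, n_params = x$n_params,
                 nobs = x$n_obs, converged = x$converged)
}

#' Forest plot of incidence density ratios
#'
#' Plots `exp(beta)` with 95% Wald intervals for every non-intercept
#' marginal-mean coefficient, on a log-scaled axis with a reference line at
#' IDR = 1.
#'
#' @param object An `mpp_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mpp_fit
#' @export
autoplot.mpp_fit <- function(object, ...) {
  td <- tidy(object, exponentiate = TRUE)
  td <- td[td$term != "(Intercept)", , drop = FALSE]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$term,
                                                      .data$estimate))) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Incidence density ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
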