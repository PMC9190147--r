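#' Incidence density ratio
#'
#' The multiplicative change in the marginal mean per one-unit change of a
#' covariate: `exp(beta)`.
#'
#' @param beta Marginal-mean coefficient(s).
#' @return `exp(beta)`, unrounded; round to 3 decimals for display.
#' @examples
#' idr(-0.112) # 0.894 to 3 decimals
#' @export
idr <- function(beta) {
  stopifnot(all(is.finite(beta)))
  exp(beta)
}

#' Wald confidence interval
#'
#' `estimate +/- z * se` with the normal quantile (1.96 at 95%).
#'
#' @param est Estimate(s).
#' @param se Standard error(s), non-negative.
#' @param level Confidence level (default 0.95).
#' @return A tibble with `low` and `high`.
#' @examples
#' wald_ci(-0.112, 0.030) # (-0.171, -0.053) to 3 decimals
#' @export
wald_ci <- function(est, se, level = 0.95) {
  stopifnot(all(se >= 0))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(low = est - zq * se, high = est + zq * se)
}

#' Percent change in the marginal mean
#'
#' `(exp(beta) - 1) * 100`, the signed percent difference in the incidence
#' rate relative to the reference level.
#'
#' @param beta Coefficient(s).
#' @return Signed percent(s), unrounded.
#' @examples
#' percent_change(-0.112) # -10.6: "10.6% lower"
#' @export
percent_change <- function(beta) {
  stopifnot(all(is.finite(beta)))
  (exp(beta) - 1) * 100
}

#' Render a percent change as prose
#'
#' @param beta Coefficient(s).
#' @param digits Decimals (default 1).
#' @return Strings such as `"10.6% lower"` or `"24.1% higher"`.
#' @export
format_percent_change <- function(beta, digits = 1) {
  pc <- round(percent_change(beta), digits)
  dplyr::case_when(
    pc < 0 ~ sprintf("%.*f%% lower", digits, -pc),
    pc > 0 ~ sprintf("%.*f%% higher", digits, pc),
    .default = sprintf("%.*f%%", digits, 0)
  )
}

#' Coefficient table with incidence density ratios
#'
#' Builds the reporting table of the fitted mixture model: rows grouped by
#' covariate with the reference level interleaved as a `(ref)` row, the
#' estimate, SE, Wald z, two-sided p, 95% CI on the coefficient scale (the
#' CI is not exponentiated), the IDR `exp(beta)`, significance stars, and a
#' final mixing-proportion row on the probability scale with its
#' delta-method SE. z statistics are computed from unrounded internals.
#'
#' @param fit An `mpp_fit` from [fit_mpp()] (must have converged).
#' @return A tibble with columns `variable`, `level`, `estimate`,
#'   `std.error`, `statistic`, `p.value`, `conf.low`, `conf.high`, `idr`,
#'   `stars`; reference rows carry `NA` numerics.
#' @examples
#' sim <- simulate_bdhs(n = 400, seed = 3)
#' fit <- fit_mpp(sim, anc_visits ~ residence)
#' idr_table(fit)
#' @export
idr_table <- function(fit) {
  stopifnot(inherits(fit, "mpp_fit"))
  if (!fit$converged) {
    stop("fit did not converge (", paste(names(fit$optim_counts),
                                         fit$optim_counts, collapse = ", "),
         " optimizer evaluations); refusing to render a report.",
         call. = FALSE)
  }
  td <- tidy(fit, component = "marginal")
  labels <- attr(fit$terms, "term.labels")
  rows <- list(tibble::tibble(
    variable = "(Intercept)", level = NA_character_,
    estimate = td$estimate[1], std.error = td$std.error[1],
    statistic = td$statistic[1], p.value = td$p.value[1],
    conf.low = td$conf.low[1], conf.high = td$conf.high[1],
    idr = NA_real_, stars = significance_stars(td$p.value[1])
  ))
  for (j in seq_along(labels)) {
    v <- labels[j]
    idx <- which(fit$assign == j)
    lv <- fit$xlevels[[v]]
    ref_row <- tibble::tibble(
      variable = v, level = paste(lv[1], "(ref)"),
      estimate = NA_real_, std.error = NA_real_, statistic = NA_real_,
      p.value = NA_real_, conf.low = NA_real_, conf.high = NA_real_,
      idr = NA_real_, stars = ""
    )
    lev_rows <- tibble::tibble(
      variable = v,
      level = sub(paste0("^", v), "", td$term[idx], fixed = FALSE),
      estimate = td$estimate[idx], std.error = td$std.error[idx],
      statistic = td$statistic[idx], p.value = td$p.value[idx],
      conf.low = td$conf.low[idx], conf.high = td$conf.high[idx],
      idr = idr(td$estimate[idx]),
      stars = significance_stars(td$p.value[idx])
    )
    rows[[j + 1L]] <- dplyr::bind_rows(ref_row, lev_rows)
  }
  pr <- tidy(fit, component = "mixing")
  rows[[length(rows) + 1L]] <- tibble::tibble(
    variable = "Mixing proportion", level = "pi",
    estimate = pr$estimate, std.error = pr$std.error,
    statistic = pr$statistic, p.value = pr$p.value,
    conf.low = NA_real_, conf.high = NA_real_, idr = NA_real_,
    stars = significance_stars(pr$p.value)
  )
  dplyr::bind_rows(rows)
}

#' AIC comparison of candidate models
#'
#' @param ... Fitted models (`mpp_fit` or `count_fit`), optionally named.
#' @return A tibble sorted by AIC: `model`, `loglik`, `n_params`, `aic`,
#'   `delta_aic`.
#' @examples
#' sim <- simulate_bdhs(n = 400, seed = 4)
#' f <- anc_visits ~ residence + media_exposure
#' compare_fits(fit_poisson(sim, f), fit_negbin(sim, f))
#' @export
compare_fits <- function(...) {
  fits <- list(...)
  out <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(model = f$model_name, loglik = f$loglik,
                   n_params = f$n_params, aic = f$aic)
  })
  out <- dplyr::arrange(out, .data$aic)
  dplyr::mutate(out, delta_aic = .data$aic - min(.data$aic))
}

#' Read an analysis dataset from CSV with complete-case filtering
#'
#' Reads a one-header-row CSV, keeps the declared outcome and covariate
#' columns, drops every row with a missing value in any declared column (the
#' complete-case rule), and converts covariates to factors with the declared
#' reference level first. Undeclared level values are an error.
#'
#' @param path CSV path.
#' @param outcome Name of the count column (default `"anc_visits"`).
#' @param covariates Named list: covariate name to character vector of its
#'   levels, reference first (a list of [covariate_spec]s also works).
#' @return A tibble of complete cases with attribute `n_excluded`, the
#'   number of dropped rows.
#' @export
read_anc_data <- function(path, outcome = "anc_visits", covariates) {
  if (all(vapply(covariates, inherits, TRUE, "covariate_spec"))) {
    covariates <- stats::setNames(
      lapply(covariates, `[[`, "levels"),
      vapply(covariates, `[[`, "", "name")
    )
  }
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  need <- c(outcome, names(covariates))
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  raw <- raw[need]
  keep <- stats::complete.cases(raw)
  n_excluded <- sum(!keep)
  out <- raw[keep, ]
  out[[outcome]] <- as.numeric(out[[outcome]])
  check_counts(out[[outcome]])
  for (v in names(covariates)) {
    lv <- covariates[[v]]
    bad <- setdiff(unique(out[[v]]), lv)
    if (length(bad)) {
      stop(sprintf("undeclared level(s) in `%s`: %s", v,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    out[[v]] <- factor(out[[v]], levels = lv)
  }
  out <- tibble::as_tibble(out)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Serialize a fit to JSON
#'
#' Writes estimates, standard errors, log-likelihood, AIC and convergence
#' metadata; readable back with `jsonlite::read_json()`.
#'
#' @param fit An `mpp_fit` or `count_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  if (inherits(fit, "mpp_fit")) {
    obj <- list(
      model = fit$model_name,
      estimates = as.list(fit$theta),
      se = as.list(fit$se),
      loglik = fit$loglik, aic = fit$aic,
      n_params = fit$n_params, n_obs = fit$n_obs,
      converged = fit$converged,
      validity_violations = fit$validity_violations
    )
  } else {
    obj <- list(
      model = fit$model_name,
      estimates = as.list(fit$coefficients),
      se = as.list(fit$se),
      loglik = fit$loglik, aic = fit$aic,
      n_params = fit$n_params, n_obs = fit$n_obs,
      converged = fit$converged
    )
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
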