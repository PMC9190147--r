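#' Specification of one categorical covariate
#'
#' Describes a covariate for the synthetic generator: its column name, its
#' levels (the first level is the reference used for dummy coding), and the
#' marginal sampling proportions of the levels.
#'
#' @param name Column name.
#' @param levels Character vector of at least two level labels; the first is
#'   the reference level.
#' @param probabilities Sampling proportions, one per level, each in
#'   \[0, 1\] and summing to 1 (within 1e-9).
#' @return An object of class `covariate_spec`.
#' @examples
#' covariate_spec("residence", c("rural", "urban"), c(0.657, 0.343))
#' @export
covariate_spec <- function(name, levels, probabilities) {
  levels <- as.character(levels)
  probabilities <- as.numeric(probabilities)
  if (length(levels) < 2L) {
    stop("a covariate needs at least 2 levels.", call. = FALSE)
  }
  if (anyDuplicated(levels)) {
    stop("covariate levels must be distinct.", call. = FALSE)
  }
  if (length(probabilities) != length(levels)) {
    stop("`probabilities` must have one entry per level.", call. = FALSE)
  }
  if (any(probabilities < 0) || any(probabilities > 1)) {
    stop("`probabilities` must lie in [0, 1].", call. = FALSE)
  }
  if (abs(sum(probabilities) - 1) > 1e-9) {
    stop("`probabilities` must sum to 1.", call. = FALSE)
  }
  structure(
    list(name = name, levels = levels, reference = levels[1L],
         probabilities = probabilities),
    class = "covariate_spec"
  )
}

#' Default covariate specifications emulating the BDHS 2017-18 sample
#'
#' Nine categorical covariates of antenatal-care use among recently delivered
#' women, with marginal proportions matching the published percent
#' distribution of the survey sample (n = 4941): study continuity status,
#' residence, media exposure, mother's age at birth, spousal age difference,
#' decision participation, beating-justification count, wealth tertile, and
#' birth order. Each spec lists the reference level first, matching the
#' reference categories of the fitted model.
#'
#' @return A named list of [covariate_spec] objects.
#' @export
bdhs_covariate_specs <- function() {
  specs <- list(
    covariate_spec("study_continuity",
                   c("continued", "not_continued_ge10", "drop_outed"),
                   c(0.112, 0.123, 0.765)),
    covariate_spec("residence", c("rural", "urban"), c(0.657, 0.343)),
    covariate_spec("media_exposure", c("no", "yes"), c(0.458, 0.542)),
    covariate_spec("age_at_birth", c("20-29", "<20", ">=30"),
                   c(0.570, 0.279, 0.151)),
    covariate_spec("spousal_age_diff",
                   c("1-5", "non-positive", "6-10", ">10"),
                   c(0.324, 0.011, 0.425, 0.240)),
    covariate_spec("decision_participation", c("none", "1-2", "all_3"),
                   c(0.151, 0.302, 0.547)),
    covariate_spec("beating_justified", c("not_at_all", "1-2", "3-5"),
                   c(0.821, 0.143, 0.036)),
    covariate_spec("wealth_index", c("poor", "middle", "rich"),
                   c(0.369, 0.321, 0.310)),
    covariate_spec("birth_order", c("1", "2", "3", ">=4"),
                   c(0.379, 0.328, 0.172, 0.121))
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Default true parameters of the BDHS-like data-generating process
#'
#' Marginal-mean coefficients equal to the published adjusted estimates for
#' the ANC-visit count model, mixing proportion on the logit scale
#' (`tau = logit(0.61)`), and component-1 coefficients sharing the marginal
#' slopes with intercept 1.0 (a low-utilization latent class with baseline
#' mean `e^1 ~ 2.7`, below the baseline marginal mean `e^1.359 ~ 3.9`, which
#' keeps the implied component-2 mean positive on every covariate profile).
#'
#' @return An [mpp_params] object whose `beta`/`alpha` names match the design
#'   columns produced by [bdhs_covariate_specs()].
#' @export
bdhs_true_params <- function() {
  beta <- c(
    "(Intercept)" = 1.359,
    "study_continuitynot_continued_ge10" = -0.112,
    "study_continuitydrop_outed" = -0.225,
    "residenceurban" = 0.113,
    "media_exposureyes" = 0.218,
    "age_at_birth<20" = -0.080,
    "age_at_birth>=30" = 0.052,
    "spousal_age_diffnon-positive" = 0.228,
    "spousal_age_diff6-10" = -0.002,
    "spousal_age_diff>10" = 0.011,
    "decision_participation1-2" = 0.002,
    "decision_participationall_3" = 0.021,
    "beating_justified1-2" = -0.126,
    "beating_justified3-5" = -0.128,
    "wealth_indexmiddle" = 0.129,
    "wealth_indexrich" = 0.216,
    "birth_order2" = -0.075,
    "birth_order3" = -0.116,
    "birth_order>=4" = -0.369
  )
  alpha <- beta
  alpha[["(Intercept)"]] <- 1.0
  p <- mpp_params(beta = beta, alpha = alpha, tau = stats::qlogis(0.61))
  names(p$beta) <- names(beta)
  names(p$alpha) <- names(beta)
  p
}

#' Classify a woman's study continuity status
#'
#' Three analysis categories built from years of schooling and whether study
#' continued after marriage: `drop_outed` for fewer than 10 years of
#' schooling; among women with at least 10 years, `continued` if study
#' continued after marriage and `not_continued_ge10` otherwise.
#'
#' @param years_schooling Non-negative integer vector.
#' @param attended_school_before_marriage Logical vector (recorded for
#'   completeness; the three analysis categories do not depend on it).
#' @param continued_after_marriage Logical vector.
#' @return Factor with levels `continued`, `not_continued_ge10`,
#'   `drop_outed` (reference first).
#' @examples
#' classify_study_continuity(c(12, 10, 8), TRUE, c(TRUE, FALSE, TRUE))
#' @export
classify_study_continuity <- function(years_schooling,
                                      attended_school_before_marriage,
                                      continued_after_marriage) {
  if (any(!is.finite(years_schooling)) || any(years_schooling < 0)) {
    stop("`years_schooling` must be non-negative.", call. = FALSE)
  }
  n <- length(years_schooling)
  attended_school_before_marriage <-
    rep_len(as.logical(attended_school_before_marriage), n)
  continued_after_marriage <- rep_len(as.logical(continued_after_marriage), n)
  out <- ifelse(
    years_schooling < 10, "drop_outed",
    ifelse(continued_after_marriage, "continued", "not_continued_ge10")
  )
  factor(out, levels = c("continued", "not_continued_ge10", "drop_outed"))
}

#' Assign wealth tertiles from wealth-index scores
#'
#' Subjects are ranked by score and split into three groups with sizes as
#' equal as possible; the lowest third is `poor`, then `middle`, then `rich`.
#' Ties are broken by order of appearance, so the assignment is deterministic
#' and depends on the scores only through their ranks.
#'
#' @param scores Numeric vector of wealth-index factor scores.
#' @return Factor of the same length with levels `poor`, `middle`, `rich`.
#' @examples
#' assign_wealth_tertile(c(0.3, -1.2, 2.1, 0.0, 0.9, -0.4))
#' @export
assign_wealth_tertile <- function(scores) {
  if (length(scores) == 0L) {
    stop("`scores` must be non-empty.", call. = FALSE)
  }
  n <- length(scores)
  r <- rank(scores, ties.method = "first")
  cut(r, breaks = c(0, round(n / 3), round(2 * n / 3), n),
      labels = c("poor", "middle", "rich"))
}

#' Sample a table of categorical covariates
#'
#' Each covariate is drawn independently from its [covariate_spec]
#' proportions. The same seed always reproduces the same table.
#'
#' @param n Number of subjects.
#' @param specs List of [covariate_spec] objects (default: the BDHS-like set).
#' @param seed Optional integer seed.
#' @return A tibble of factors, one column per spec, reference level first.
#' @export
simulate_covariates <- function(n, specs = bdhs_covariate_specs(),
                                seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  bad <- !vapply(specs, inherits, TRUE, "covariate_spec")
  if (any(bad)) {
    stop("`specs` must be a list of covariate_spec objects.", call. = FALSE)
  }
  cols <- purrr::map(specs, function(s) {
    factor(sample(s$levels, n, replace = TRUE, prob = s$probabilities),
           levels = s$levels)
  })
  names(cols) <- vapply(specs, `[[`, "", "name")
  tibble::as_tibble(cols)
}

#' Simulate counts from the MPois-Pois data-generating process
#'
#' Per subject, a latent class is drawn: class 1 with probability
#' `pi = plogis(tau)`, in which case `y ~ Poisson(mu1_i)` with
#' `log(mu1_i) = z_i'alpha`; otherwise `y ~ Poisson(mu2_i)` with
#' `mu2_i = (mu_i - pi * mu1_i) / (1 - pi)` and `log(mu_i) = x_i'beta`, so
#' that the mean of `y` given `x_i` is exactly `exp(x_i'beta)`.
#'
#' @param X Marginal-mean design matrix (intercept first).
#' @param Z Component-1 design matrix, same number of rows.
#' @param params An [mpp_params] object; every implied `mu2_i` must be
#'   positive, otherwise an error names the offending rows.
#' @param seed Optional integer seed.
#' @return A tibble with columns `y` (the count) and `latent_class`
#'   (1 or 2, for diagnostics only; never used by the fitting functions).
#' @export
simulate_counts <- function(X, Z, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- rbind_if_vector(X, length(params$beta))
  Z <- rbind_if_vector(Z, length(params$alpha))
  stopifnot(nrow(X) == nrow(Z))
  n <- nrow(X)
  pi <- params$pi
  mu <- drop(exp(X %*% params$beta))
  mu1 <- drop(exp(Z %*% params$alpha))
  mu2 <- mu2_from_marginal(mu, mu1, pi)
  latent <- 2L - stats::rbinom(n, 1L, pi) # 1 w.p. pi, else 2
  y <- stats::rpois(n, ifelse(latent == 1L, mu1, mu2))
  tibble::tibble(y = y, latent_class = latent)
}

#' Simulate a BDHS-like dataset of ANC visit counts
#'
#' Draws covariates from their marginal proportions and counts from the
#' MPois-Pois process at the supplied true parameters. The output has one row
#' per woman: the covariate columns, the outcome `anc_visits`, and the
#' diagnostic `latent_class` column.
#'
#' @param n Sample size (default 4941, the size of the emulated survey
#'   analysis sample).
#' @param specs List of [covariate_spec]s; defaults to
#'   [bdhs_covariate_specs()].
#' @param params True [mpp_params]; `beta`/`alpha` must be named by the
#'   design columns implied by `specs`. Defaults to [bdhs_true_params()].
#' @param seed Optional integer seed.
#' @return A tibble; write it with [write_dataset()] if a CSV is needed.
#' @examples
#' sim <- simulate_bdhs(n = 500, seed = 1)
#' dplyr::count(sim, study_continuity)
#' @export
simulate_bdhs <- function(n = 4941, specs = bdhs_covariate_specs(),
                          params = bdhs_true_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  covs <- simulate_covariates(n, specs, seed = NULL)
  rhs <- stats::reformulate(names(covs))
  des <- mpp_design(covs, rhs)
  beta <- align_coefs(params$beta, colnames(des$X), "beta")
  alpha <- align_coefs(params$alpha, colnames(des$Z), "alpha")
  pars <- mpp_params(beta, alpha, params$tau)
  draws <- simulate_counts(des$X, des$Z, pars, seed = NULL)
  dplyr::mutate(covs, anc_visits = draws$y, latent_class = draws$latent_class)
}

align_coefs <- function(coefs, cols, what) {
  if (is.null(names(coefs))) {
    if (length(coefs) != length(cols)) {
      stop(sprintf("`%s` has %d entries but the design has %d columns.",
                   what, length(coefs), length(cols)), call. = FALSE)
    }
    return(as.numeric(coefs))
  }
  missing <- setdiff(cols, names(coefs))
  if (length(missing)) {
    stop(sprintf("`%s` is missing coefficients for: %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  as.numeric(coefs[cols])
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file must provide `n`, a mandatory `seed`, a `covariates` list (each
#' with `name`, `levels`, `probabilities`), and `params` with named `beta`,
#' named `alpha`, and scalar `tau`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of class `sim_config` with elements `n`, `seed`, `specs`,
#'   `params`, directly usable by [simulate_from_config()].
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  for (field in c("n", "seed", "covariates", "params")) {
    if (is.null(raw[[field]])) {
      stop(sprintf("config is missing required field `%s`.", field),
           call. = FALSE)
    }
  }
  specs <- purrr::map(raw$covariates, function(cv) {
    covariate_spec(cv$name, cv$levels, cv$probabilities)
  })
  names(specs) <- vapply(specs, `[[`, "", "name")
  params <- mpp_params(
    beta = unlist(raw$params$beta),
    alpha = unlist(raw$params$alpha),
    tau = raw$params$tau
  )
  names(params$beta) <- names(unlist(raw$params$beta))
  names(params$alpha) <- names(unlist(raw$params$alpha))
  structure(
    list(n = as.integer(raw$n), seed = as.integer(raw$seed),
         specs = specs, params = params),
    class = "sim_config"
  )
}

#' Simulate a dataset from a configuration object
#'
#' @param config A `sim_config` from [read_sim_config()].
#' @return A tibble as in [simulate_bdhs()].
#' @export
simulate_from_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  simulate_bdhs(n = config$n, specs = config$specs, params = config$params,
                seed = config$seed)
}

#' Write a simulated dataset to CSV
#'
#' One header row; covariate columns plus `anc_visits` and `latent_class`.
#'
#' @param data Tibble from [simulate_bdhs()] (or any data frame).
#' @param path Output path.
#' @return `data`, invisibly.
#' @export
write_dataset <- function(data, path) {
  readr::write_csv(data, path)
  invisible(data)
}
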