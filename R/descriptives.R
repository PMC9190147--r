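#' Per-level summary of a count outcome
#'
#' For each level of a grouping variable: sample size, percent of subjects,
#' mean count, standard error (`sd / sqrt(n)`, `n - 1` denominator), and
#' normal 95% confidence interval (`mean +/- 1.96 * SE`). A level with a
#' single subject gets `NA` for the SE and interval, with a warning.
#'
#' @param y Non-negative counts.
#' @param group Level labels, one per subject (factor or character).
#' @param variable Name to record in the `variable` column.
#' @param conf.level Confidence level (normal quantile; default 0.95).
#' @return A tibble with columns `variable`, `level`, `n`, `pct`, `mean`,
#'   `se`, `ci_low`, `ci_high`.
#' @examples
#' group_summary(c(4, 6, 2, 3), c("a", "a", "b", "b"))
#' @export
group_summary <- function(y, group, variable = deparse(substitute(group)),
                          conf.level = 0.95) {
  check_counts(y)
  stopifnot(length(y) == length(group))
  if (anyNA(group)) stop("every subject needs a level.", call. = FALSE)
  group <- if (is.factor(group)) droplevels(group) else factor(group)
  zq <- stats::qnorm(1 - (1 - conf.level) / 2)
  out <- tibble::tibble(y = y, level = group) |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$y),
      se = stats::sd(.data$y) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      variable = variable,
      pct = 100 * .data$n / sum(.data$n),
      ci_low = .data$mean - zq * .data$se,
      ci_high = .data$mean + zq * .data$se,
      level = as.character(.data$level)
    ) |>
    dplyr::select("variable", "level", "n", "pct", "mean", "se",
                  "ci_low", "ci_high")
  if (any(out$n == 1L)) {
    warning("level(s) with a single subject: SE and CI undefined.",
            call. = FALSE)
  }
  out
}

#' One-way ANOVA (or pooled t-test) across levels
#'
#' Classical equal-variance one-way analysis of variance of the counts across
#' the levels of a grouping variable. With exactly two levels the
#' pooled-variance two-sample t-test is used, for which `F = t^2` holds
#' exactly. Empty levels are dropped with a warning.
#'
#' @param y Counts.
#' @param group Level labels.
#' @return A one-row tibble: `statistic` (F), `df1`, `df2`, `p.value`,
#'   `method`.
#' @export
oneway_anova <- function(y, group) {
  check_counts(y)
  group <- factor(group)
  if (any(table(group) == 0L)) {
    warning("dropping empty level(s).", call. = FALSE)
    group <- droplevels(group)
  }
  k <- nlevels(group)
  if (k < 2L) stop("need at least 2 non-empty levels.", call. = FALSE)
  if (k == 2L) {
    tt <- stats::t.test(y ~ group, var.equal = TRUE)
    return(tibble::tibble(
      statistic = unname(tt$statistic)^2, df1 = 1,
      df2 = unname(tt$parameter), p.value = tt$p.value,
      method = "pooled t-test (F = t^2)"
    ))
  }
  av <- stats::oneway.test(y ~ group, var.equal = TRUE)
  tibble::tibble(
    statistic = unname(av$statistic), df1 = unname(av$parameter[1]),
    df2 = unname(av$parameter[2]), p.value = av$p.value,
    method = "one-way ANOVA"
  )
}

#' Significance stars
#'
#' Strict-inequality thresholds: `***` for p < 0.01, `**` for p < 0.05, `*`
#' for p < 0.10, empty otherwise (so p = 0.05 earns a single star).
#'
#' @param p P-value(s) in \[0, 1\].
#' @return Character vector of marks.
#' @examples
#' significance_stars(c(0.005, 0.05, 0.5))
#' @export
significance_stars <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("`p` must lie in [0, 1].", call. = FALSE)
  }
  dplyr::case_when(
    p < 0.01 ~ "***",
    p < 0.05 ~ "**",
    p < 0.10 ~ "*",
    .default = ""
  )
}

#' Descriptive table of a count outcome by categorical covariates
#'
#' The descriptive stage of the analysis: one block of rows per covariate,
#' each row a level with its n, percent, mean count, SE, and 95% CI, plus the
#' omnibus ANOVA/t-test p-value of the across-level comparison and its
#' significance stars (attached to every row of the block).
#'
#' @param data A data frame.
#' @param outcome Name of the count column (default `"anc_visits"`).
#' @param variables Character vector of covariate columns; defaults to all
#'   factor/character columns except the outcome and `latent_class`.
#' @return A tibble with the [group_summary()] columns plus `p.value` and
#'   `stars`.
#' @examples
#' sim <- simulate_bdhs(n = 300, seed = 2)
#' describe_counts(sim, variables = c("residence", "wealth_index"))
#' @export
describe_counts <- function(data, outcome = "anc_visits", variables = NULL) {
  stopifnot(outcome %in% names(data))
  if (is.null(variables)) {
    variables <- names(data)[vapply(data, function(x) {
      is.factor(x) || is.character(x)
    }, TRUE)]
    variables <- setdiff(variables, c(outcome, "latent_class"))
  }
  y <- data[[outcome]]
  purrr::map_dfr(variables, function(v) {
    test <- oneway_anova(y, data[[v]])
    group_summary(y, data[[v]], variable = v) |>
      dplyr::mutate(p.value = test$p.value,
                    stars = significance_stars(test$p.value))
  })
}

#' Format the descriptive table for display
#'
#' Rounds to the conventions of the published table: percentages to 1
#' decimal, means/SEs/CI bounds to 2 decimals, with an `n (%)` column and a
#' `95% CI` range column.
#'
#' @param desc Output of [describe_counts()].
#' @return A tibble of display strings.
#' @export
format_descriptives <- function(desc) {
  dplyr::transmute(
    desc,
    variable = paste0(.data$variable, .data$stars),
    level = .data$level,
    `n (%)` = sprintf("%d (%.1f)", .data$n, .data$pct),
    mean = sprintf("%.2f", .data$mean),
    se = sprintf("%.2f", .data$se),
    `95% CI` = sprintf("%.2f-%.2f", .data$ci_low, .data$ci_high)
  )
}

#' Plot group means of the count outcome with confidence intervals
#'
#' @param desc Output of [describe_counts()].
#' @return A ggplot object: one panel per covariate, point and 95% CI per
#'   level.
#' @export
plot_descriptives <- function(desc) {
  ggplot2::ggplot(desc, ggplot2::aes(x = .data$mean, y = .data$level)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "Mean count (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
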