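test_that("covariate specifications are validated", {
  expect_error(covariate_spec("x", "only_one", 1), "at least 2 levels")
  expect_error(covariate_spec("x", c("a", "b"), c(0.6, 0.5)), "sum to 1")
  expect_error(covariate_spec("x", c("a", "b"), c(1.2, -0.2)), "\\[0, 1\\]")
  s <- covariate_spec("residence", c("rural", "urban"), c(0.657, 0.343))
  expect_identical(s$reference, "rural")
  specs <- bdhs_covariate_specs()
  expect_length(specs, 9)
  for (s in specs) expect_equal(sum(s$probabilities), 1, tolerance = 1e-9)
})

test_that("study continuity classification is total and matches its rules", {
  expect_equal(as.character(classify_study_continuity(12, TRUE, TRUE)),
               "continued")
  # boundary: exactly 10 years, stopped after marriage
  expect_equal(as.character(classify_study_continuity(10, TRUE, FALSE)),
               "not_continued_ge10")
  # under 10 years is a dropout regardless of continuation flags
  expect_equal(as.character(classify_study_continuity(8, TRUE, TRUE)),
               "drop_outed")
  expect_error(classify_study_continuity(-1, TRUE, TRUE), "non-negative")
  # totality: every combination maps to exactly one of the three levels
  grid <- expand.grid(years = 0:16, before = c(TRUE, FALSE),
                      after = c(TRUE, FALSE))
  out <- classify_study_continuity(grid$years, grid$before, grid$after)
  expect_false(anyNA(out))
  expect_setequal(levels(out),
                  c("continued", "not_continued_ge10", "drop_outed"))
  expect_true(all(out[grid$years < 10] == "drop_outed"))
})

test_that("wealth tertiles split ranks as equally as possible", {
  expect_equal(as.integer(table(assign_wealth_tertile(c(9, 1, 5, 3, 7, 2, 8, 4, 6)))),
               c(3L, 3L, 3L))
  expect_equal(as.character(assign_wealth_tertile(1:6)),
               c("poor", "poor", "middle", "middle", "rich", "rich"))
  set.seed(99)
  scores <- runif(3000)
  counts <- as.integer(table(assign_wealth_tertile(scores)))
  expect_true(all(abs(counts - 1000L) <= 1L))
  # rank invariance: any strictly increasing transform gives the same labels
  expect_identical(assign_wealth_tertile(scores),
                   assign_wealth_tertile(exp(3 * scores) + 7))
  expect_error(assign_wealth_tertile(numeric(0)), "non-empty")
})

test_that("covariate sampling matches its proportions and is reproducible", {
  specs <- bdhs_covariate_specs()
  tab <- simulate_covariates(50000, specs["study_continuity"], seed = 7)
  freq <- prop.table(table(tab$study_continuity))
  expect_lt(abs(freq[["continued"]] - 0.112), 0.01)
  expect_lt(abs(freq[["not_continued_ge10"]] - 0.123), 0.01)
  expect_lt(abs(freq[["drop_outed"]] - 0.765), 0.01)
  expect_identical(simulate_covariates(200, specs, seed = 3),
                   simulate_covariates(200, specs, seed = 3))
})

test_that("count simulation obeys the marginalized mean", {
  n <- 1e5
  X <- matrix(1, n, 1)
  # pi ~ 0: collapses to a single Poisson with the marginal mean
  p <- mpp_params(log(3), 0, -30)
  sim <- simulate_counts(X, X, p, seed = 5)
  mc_se <- sd(sim$y) / sqrt(n)
  expect_lt(abs(mean(sim$y) - 3), 3 * mc_se)
  # intercept-only with beta0 = log 2, alpha0 = 0, tau = 0: mu2 = 3
  p <- mpp_params(log(2), 0, 0)
  sim <- simulate_counts(X, X, p, seed = 6)
  y2 <- sim$y[sim$latent_class == 2]
  expect_lt(abs(mean(y2) - 3), 3 * sd(y2) / sqrt(length(y2)))
  # marginal mean converges to exp(x'beta) for a genuine mixture
  mc_se <- sd(sim$y) / sqrt(n)
  expect_lt(abs(mean(sim$y) - 2), 3 * mc_se)
  # marginal variance matches mu + pi(1-pi)(mu1-mu2)^2
  v_th <- marginal_moments(1, 3, 0.5)$var
  m4 <- mean((sim$y - mean(sim$y))^4)
  se_var <- sqrt((m4 - var(sim$y)^2) / n)
  expect_lt(abs(var(sim$y) - v_th), 3 * se_var)
  # latent class proportions converge to (pi, 1 - pi)
  expect_equal(mean(sim$latent_class == 1), 0.5, tolerance = 0.01)
  # invalid parameter set names the offending rows
  expect_error(simulate_counts(X[1:3, , drop = FALSE], X[1:3, , drop = FALSE],
                               mpp_params(0, 2, 0)),
               "position\\(s\\) 1, 2, 3")
})

test_that("the BDHS-like generator produces a coherent analysis table", {
  sim <- simulate_bdhs(n = 2000, seed = 11)
  specs <- bdhs_covariate_specs()
  expect_named(sim, c(names(specs), "anc_visits", "latent_class"))
  expect_true(all(sim$anc_visits >= 0 & sim$anc_visits == floor(sim$anc_visits)))
  expect_true(all(sim$latent_class %in% 1:2))
  expect_identical(sim, simulate_bdhs(n = 2000, seed = 11))
  # marginal mean near the baseline-weighted prediction of the true model
  expect_equal(mean(sim$anc_visits == 0) > 0, TRUE)
  # latent class 1 frequency near plogis(tau) = 0.61
  expect_equal(mean(sim$latent_class == 1), 0.61, tolerance = 0.03)
})

test_that("simulation configs round-trip through YAML and JSON", {
  cfg <- list(
    n = 150, seed = 42,
    covariates = list(
      list(name = "residence", levels = c("rural", "urban"),
           probabilities = c(0.66, 0.34))
    ),
    params = list(
      beta = list(`(Intercept)` = 1.2, residenceurban = 0.1),
      alpha = list(`(Intercept)` = 0.4, residenceurban = 0.1),
      tau = 0.4
    )
  )
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yml)
  jsn <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, jsn, auto_unbox = TRUE, digits = NA)
  cy <- read_sim_config(yml)
  cj <- read_sim_config(jsn)
  expect_equal(cy$params$beta, cj$params$beta)
  simy <- simulate_from_config(cy)
  expect_identical(simy, simulate_from_config(cj))
  expect_named(simy, c("residence", "anc_visits", "latent_class"))
  # seed is mandatory
  cfg$seed <- NULL
  yaml::write_yaml(cfg, yml)
  expect_error(read_sim_config(yml), "seed")
})
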