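test_that("model specification counts random effects correctly", {
  m1 <- dsem_model(c("social_anxiety", "paranoia"))
  expect_equal(m1$n_random_effects, 6)
  m2 <- dsem_model(c("social_anxiety", "paranoia", "loneliness"),
                   schema_covariates = c("neg_self", "neg_other"))
  expect_equal(m2$n_random_effects, 12)
  expect_equal(dsem_model("x")$n_random_effects, 2)
  expect_error(dsem_model(c("a", "a")), "unique")
  expect_error(dsem_model("x", schema_covariates = "only_one"), "exactly two")
})

test_that("fixed-effects fit on a complete series matches least squares", {
  set.seed(1)
  K <- 2; T <- 500
  phi <- matrix(c(0.5, 0.2, 0.3, 0.4), 2, 2, byrow = TRUE)
  mu <- c(2, 3)
  w <- matrix(0, T, K)
  innov <- matrix(rnorm(T * K, 0, c(sqrt(0.8), sqrt(1.2))), T, K, byrow = TRUE)
  for (t in 2:T) w[t, ] <- phi %*% w[t - 1, ] + innov[t, ]
  y <- sweep(w, 2, mu, "+")
  grid <- tibble::tibble(person_id = 1L, cell = 0:(T - 1),
                         cell_minute = (0:(T - 1)) * 60,
                         clock_hour = 0, hour_c = 0, observed = TRUE,
                         social_anxiety = y[, 1], paranoia = y[, 2])
  attr(grid, "variables") <- c("social_anxiety", "paranoia")
  spec <- dsem_model(c("social_anxiety", "paranoia"),
                     include_hour_trend = FALSE, random_effects = FALSE,
                     chains = 2, iterations = 2000, thin = 4)
  fit <- dsem_fit(grid, spec, seed = 4)
  eta <- colMeans(dsemr:::draws_matrix(fit, "eta_bar"))
  x <- cbind(1, y[-T, ])
  b <- solve(crossprod(x), crossprod(x, y[-1, ]))
  ols_phi <- t(b[-1, ])                       # rows = outcome
  expect_lt(max(abs(eta[3:6] - as.vector(t(ols_phi)))), 0.03)
})

test_that("fits are deterministic given the seed", {
  p <- tiny_params_k2()
  study <- simulate_esm_study(p, n_persons = 8, seed = 5)
  grid <- build_time_grid(study$records)
  spec <- dsem_model(p$variables, chains = 2, iterations = 80, thin = 2)
  f1 <- dsem_fit(grid, spec, seed = 12)
  f2 <- dsem_fit(grid, spec, seed = 12)
  expect_identical(f1$chains[[1]]$eta_bar, f2$chains[[1]]$eta_bar)
  expect_identical(f1$chains[[2]]$person, f2$chains[[2]]$person)
})

test_that("degenerate inputs raise informative errors", {
  grid <- tibble::tibble(person_id = 1L, cell = 0:9, cell_minute = (0:9) * 60,
                         clock_hour = 0, hour_c = 0, observed = TRUE,
                         x = rep(2, 10))
  attr(grid, "variables") <- "x"
  spec1 <- dsem_model("x", random_effects = FALSE, chains = 1,
                      iterations = 20, thin = 1)
  expect_error(dsem_fit(grid, spec1, seed = 1), "zero within-person variance")
  expect_error(dsem_fit(grid, dsem_model("x", chains = 1, iterations = 20, thin = 1),
                        seed = 1), "at least 2 persons")
  expect_error(dsem_fit(grid, dsem_model("y", random_effects = FALSE,
                                         chains = 1, iterations = 20, thin = 1),
                        seed = 1), "not in the grid")
})

test_that("a zero between-person covariance truth is recovered as near-zero", {
  p <- esm_true_params(variables = c("social_anxiety", "paranoia"),
                       mu_sd = c(0, 0), phi_sd = 0, gamma = c(0, 0),
                       schema_cor = matrix(0, 6, 2))
  sch <- hourly_schedule(200, per_day = 12, days = 5)
  eff <- draw_person_effects(p, 200, seed = 61)
  rec <- simulate_series(sch, eff, p, seed = 62)
  grid <- build_time_grid(rec)
  spec <- dsem_model(p$variables, include_hour_trend = FALSE, profile = "smoke")
  fit <- dsem_fit(grid, spec, seed = 63)
  om <- dsemr:::draws_matrix(fit, "omega")
  d <- sqrt(ncol(om))
  diag_med <- vapply(1:6, function(j) median(om[, (j - 1) * d + j]), numeric(1))
  expect_true(all(diag_med < 0.05))
})

test_that("split-chain PSR behaves as the between/within variance ratio dictates", {
  # identical constant chains
  expect_equal(dsemr:::split_psr(list(rep(1, 100), rep(1, 100))), 1)
  # independent standard-normal chains stay near 1
  set.seed(8)
  chains <- replicate(4, rnorm(2000), simplify = FALSE)
  expect_lt(dsemr:::split_psr(chains), 1.01)
  # separated chains are flagged
  set.seed(9)
  expect_gt(dsemr:::split_psr(list(rnorm(500, 0), rnorm(500, 5))), 1.1)
})

test_that("convergence reports cover all parameter groups and cross-check coda", {
  fit <- small_model2_fit()
  conv <- convergence(fit)
  expect_true(all(c("parameter", "psr", "ess", "flagged") %in% names(conv)))
  expect_true(all(conv$psr >= 1 - 1e-8))
  expect_true(any(grepl("^mu_", conv$parameter)))
  expect_true(any(grepl("^sigma_w", conv$parameter)))
  expect_true(any(grepl("^omega", conv$parameter)))
  # independent estimator agreement on one well-mixed parameter
  if (requireNamespace("coda", quietly = TRUE)) {
    eta <- dsemr:::chain_array(fit, "eta_bar")
    ml <- coda::mcmc.list(lapply(eta, function(m) coda::mcmc(m[, 1])))
    gd <- unname(coda::gelman.diag(ml, autoburnin = FALSE)$psrf[1, 1])
    ours <- conv$psr[conv$parameter == fit$effect_names[1]]
    expect_lt(abs(gd - ours), 0.25)
  }
  spec1 <- fit$spec
  fit1 <- fit
  fit1$spec$chains <- 1
  expect_error(convergence(fit1), "at least 2 chains")
})

test_that("gender moderation requires variation and reports lag coefficients", {
  fit <- small_model2_fit()
  gm <- gender_moderation(fit)
  expect_equal(nrow(gm), 9)           # all lag coefficients of the trivariate model
  expect_true(all(gm$lower <= gm$upper))
  # the generator has no gender effect: strong moderation should not appear
  expect_lt(max(abs(gm$estimate)), 0.5)
  study <- small_model2_study()
  persons_const <- study$persons
  persons_const$gender <- 1
  grid <- build_time_grid(suppressMessages(exclusion_filter(study$records)))
  spec <- dsem_model(fit$variables, gender = "gender",
                     chains = 1, iterations = 20, thin = 1)
  expect_error(dsem_fit(grid, spec, persons = persons_const, seed = 1),
               "constant")
})
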