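test_that("parameter validation catches the documented error cases", {
  expect_error(esm_true_params(phi_bar = diag(1.2, 3)), "spectral radius")
  expect_error(esm_true_params(compliance_mean = 0), "compliance_mean")
  expect_error(esm_true_params(schema_cor = matrix(0, 3, 2)), "schema_cor")
  expect_error(esm_true_params(omega = matrix(1, 2, 2)), "omega")
  bad_sigma <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3, 3)
  expect_error(esm_true_params(sigma_w = bad_sigma), "sigma_w")
})

test_that("degenerate between-person covariance gives identical persons", {
  p <- esm_true_params(variables = c("social_anxiety", "paranoia"),
                       mu_sd = c(0, 0), phi_sd = 0,
                       schema_cor = matrix(0, 6, 2), schema_sds = c(1, 1))
  eff <- draw_person_effects(p, 25, seed = 3)
  en <- dsemr:::effect_names(p$variables)
  truth <- unname(c(p$mu_bar, as.vector(t(p$phi_bar))))
  for (j in seq_along(en)) {
    expect_equal(unname(eff[[en[j]]]), rep(truth[j], 25), tolerance = 1e-12)
  }
})

test_that("configured schema-dynamics correlations are reproduced at large n", {
  sc <- matrix(0, 6, 2)
  sc[4, 1] <- 0.4  # paranoia -> social anxiety coefficient vs negative-self
  p <- esm_true_params(variables = c("social_anxiety", "paranoia"),
                       mu_sd = c(0.9, 0.8), phi_sd = 0.1, schema_cor = sc)
  eff <- draw_person_effects(p, 20000, seed = 9)
  r <- cor(eff$phi_paranoia_to_social_anxiety, eff$neg_self)
  expect_lt(abs(r - 0.4), 0.02)
  # law of large numbers on the person means
  se <- sqrt(diag(p$omega)[1:2] / 20000)
  expect_lt(abs(mean(eff$mu_social_anxiety) - p$mu_bar[1]), 3 * se[1])
  expect_lt(abs(mean(eff$mu_paranoia) - p$mu_bar[2]), 3 * se[2])
})

test_that("every generated person has stationary dynamics", {
  p <- esm_true_params(phi_sd = 0.12)
  eff <- draw_person_effects(p, 300, seed = 5)
  en <- dsemr:::effect_names(p$variables)
  radii <- vapply(seq_len(300), function(i) {
    phi_i <- matrix(as.numeric(eff[i, en[4:12]]), 3, 3, byrow = TRUE)
    dsemr:::spectral_radius(phi_i)
  }, numeric(1))
  expect_true(all(radii < 1))
})

test_that("white-noise truth yields near-zero lag-1 autocorrelation", {
  p <- tiny_params_k1(phi = 0, mu_sd = 0, phi_sd = 0)
  sch <- hourly_schedule(1, per_day = 24, days = 2100)  # > 50,000 transitions
  eff <- draw_person_effects(p, 1, seed = 2)
  rec <- simulate_series(sch, eff, p, seed = 3)
  x <- rec$x
  r <- cor(x[-1], x[-length(x)])
  expect_lt(abs(r), 0.03)
})

test_that("simulated series match the analytic stationary covariance", {
  # univariate closed form: 0.75 / (1 - 0.25) = 1
  expect_equal(stationary_cov(0.5, 0.75)[1, 1], 1)
  p <- tiny_params_k2()
  sch <- hourly_schedule(1, per_day = 24, days = 420)  # ~10,000 cells
  eff <- draw_person_effects(
    esm_true_params(variables = p$variables, mu_sd = c(0, 0), phi_sd = 0,
                    gamma = c(0, 0), schema_cor = matrix(0, 6, 2)),
    1, seed = 6)
  rec <- simulate_series(sch, eff, p, seed = 7)
  emp <- cov(cbind(rec$social_anxiety, rec$paranoia))
  ana <- stationary_cov(p$phi_bar, p$sigma_w)
  expect_lt(max(abs(emp - ana)), 0.15)
})

test_that("likert emulation keeps composites on the 1-7 lattice", {
  p <- esm_true_params(likert_emulation = TRUE)
  study <- simulate_esm_study(p, n_persons = 6, seed = 10, missingness = FALSE)
  for (v in p$variables) {
    x <- study$records[[v]]
    expect_true(all(x >= 1 & x <= 7))
    step <- 1 / p$items_per_var[[v]]
    expect_true(all(abs(x / step - round(x / step)) < 1e-8))
  }
  # item-level emission: composite equals the item mean
  rec <- simulate_series(study$schedule, study$persons, p, seed = 11,
                         emit_items = TRUE)
  items <- as.matrix(rec[, paste0("paranoia_item", 1:5)])
  expect_equal(rec$paranoia, rowMeans(items))
  expect_true(all(items %in% 1:7))
})

test_that("missingness honours per-person completion probabilities", {
  p <- esm_true_params()
  study <- simulate_esm_study(p, n_persons = 134, seed = 21, missingness = FALSE)
  # full compliance is a no-op
  eff1 <- study$persons
  eff1$completion_prob <- 1
  expect_identical(nrow(apply_missingness(study$records, eff1, seed = 1)),
                   nrow(study$records))
  # the study design reproduces the reported aggregate completion rate
  thinned <- apply_missingness(study$records, study$persons, seed = 2)
  rate <- nrow(thinned) / nrow(study$records)
  expect_lt(abs(rate - 0.721), 0.02)
  # a 20% complier falls below the downstream exclusion threshold of 20
  expect_lt(0.2 * 60, 20)
})

test_that("retention is missing-at-random: independent of response values", {
  p <- tiny_params_k2()
  study <- simulate_esm_study(p, n_persons = 10, seed = 31, missingness = FALSE)
  shifted <- study$records
  shifted$social_anxiety <- shifted$social_anxiety + 100
  a <- apply_missingness(study$records, study$persons, seed = 5)
  b <- apply_missingness(shifted, study$persons, seed = 5)
  expect_identical(a$person_id, b$person_id)
  expect_identical(a$timestamp_minute, b$timestamp_minute)
})

test_that("identical seeds give identical datasets", {
  p <- esm_true_params()
  s1 <- simulate_esm_study(p, n_persons = 8, seed = 99)
  s2 <- simulate_esm_study(p, n_persons = 8, seed = 99)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$persons, s2$persons)
})
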