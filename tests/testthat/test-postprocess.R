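test_that("credible intervals follow the order-statistic quantiles", {
  expect_equal(credible_intervals(cbind(a = rep(0.5, 200)))$lower, 0.5)
  expect_true(credible_intervals(cbind(a = rep(0.5, 200)))$significant)
  alt <- credible_intervals(cbind(a = rep(c(-1, 1), 100)))
  expect_false(alt$significant)
  expect_lte(alt$lower, 0); expect_gte(alt$upper, 0)
  # brute-force type-7 quantile oracle on sorted draws
  set.seed(3)
  x <- sort(rnorm(1000))
  ci <- credible_intervals(cbind(par = x), level = 0.95)
  brute <- function(p) {
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[lo + 1] - x[lo])
  }
  expect_equal(ci$lower, brute(0.025))
  expect_equal(ci$upper, brute(0.975))
  expect_equal(ci$estimate, median(x))
  expect_error(credible_intervals(cbind(a = rnorm(50)), level = 0.95),
               "at least 100")
})

test_that("stationary covariance solver matches a fixed-point oracle", {
  expect_equal(stationary_cov(0.5, 0.75)[1, 1], 1)   # 0.75 / (1 - 0.25)
  phi <- matrix(c(0.5, 0.2, 0.3, 0.4), 2, 2, byrow = TRUE)
  v <- stationary_cov(phi, diag(2))
  expect_equal(v, lyapunov_fixed_point(phi, diag(2)), tolerance = 1e-10)
  expect_error(stationary_cov(diag(1.2, 2), diag(2)), "stationary")
})

test_that("standardization matches the Lyapunov oracle and its identities", {
  vars <- c("social_anxiety", "paranoia")
  phi <- matrix(c(0.5, 0.2, 0.3, 0.4), 2, 2, byrow = TRUE)
  pe <- matrix(c(2, 3, as.vector(t(phi))), 1, 6)
  fit <- fake_fit(vars, pe, sigma_w = diag(2))
  tab <- standardize_within(fit)
  v <- lyapunov_fixed_point(phi, diag(2))
  sdv <- sqrt(diag(v))
  oracle <- phi * outer(1 / sdv, sdv)
  est <- tab$estimate[match(c("phi_social_anxiety_to_social_anxiety",
                              "phi_paranoia_to_social_anxiety",
                              "phi_social_anxiety_to_paranoia",
                              "phi_paranoia_to_paranoia"), tab$term)]
  expect_equal(est, c(oracle[1, 1], oracle[1, 2], oracle[2, 1], oracle[2, 2]),
               tolerance = 1e-6)
  # means stay on the raw scale
  expect_equal(tab$estimate[tab$term == "mu_social_anxiety"], 2)
  # zero dynamics -> all standardized lag effects exactly zero
  pe0 <- matrix(c(2, 3, rep(0, 4)), 1, 6)
  tab0 <- standardize_within(fake_fit(vars, pe0, sigma_w = diag(2)))
  expect_equal(tab0$estimate[grepl("^phi_", tab0$term)], rep(0, 4))
  # univariate: standardized equals raw
  tab1 <- standardize_within(fake_fit("x", matrix(c(2, 0.6), 1, 2),
                                      sigma_w = matrix(1)))
  expect_equal(tab1$estimate[tab1$term == "phi_x_to_x"], 0.6)
  # equal predictor and outcome SDs: standardized equals unstandardized
  phi_sym <- matrix(c(0.4, 0.2, 0.2, 0.4), 2, 2)
  pe_sym <- matrix(c(0, 0, as.vector(t(phi_sym))), 1, 6)
  tab_sym <- standardize_within(fake_fit(vars, pe_sym, sigma_w = diag(2)))
  expect_equal(tab_sym$estimate[grepl("^phi_", tab_sym$term)],
               as.vector(t(phi_sym)), tolerance = 1e-10)
})

test_that("within-person R-squared follows the AR(1) closed forms", {
  # phi = 0: nothing explained
  r0 <- within_r2(fake_fit("x", matrix(c(2, 0), 1, 2), sigma_w = matrix(1)))
  expect_equal(r0$estimate, 0)
  # phi = 0.5, unit innovation: R2 = 0.25
  r <- within_r2(fake_fit("x", matrix(c(2, 0.5), 1, 2), sigma_w = matrix(1)))
  expect_equal(r$estimate, 0.25)
  # monotone in |phi| and bounded in [0, 1)
  vals <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(ph) {
    within_r2(fake_fit("x", matrix(c(2, ph), 1, 2), sigma_w = matrix(1)))$estimate
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 0 & vals < 1))
})

test_that("between-person correlations are computed from the covariate blocks", {
  vars <- c("social_anxiety", "paranoia")
  de <- 6
  omega <- diag(c(rep(1, de), 4, 9))     # schema variances 4 and 9
  omega[1, 7] <- omega[7, 1] <- 0.8      # mu_SA vs neg_self: r = 0.8/sqrt(1*4)=0.4
  omega[4, 8] <- omega[8, 4] <- -1.5     # phi_PAR->SA vs neg_other: r = -0.5
  pe <- matrix(c(2, 2, 0.4, 0.2, 0.1, 0.3), 1, 6)
  fit <- fake_fit(vars, pe, sigma_w = diag(2), omega = omega,
                  schema_covariates = c("neg_self", "neg_other"))
  fit$schemas_present <- TRUE
  tab <- between_correlations(fit)
  expect_equal(nrow(tab), 12)            # 6 effects x 2 schemas
  expect_true(all(tab$estimate >= -1 & tab$estimate <= 1))
  expect_equal(tab$estimate[tab$term == "mu_social_anxiety" &
                              tab$schema == "neg_self"], 0.4)
  expect_equal(tab$estimate[tab$term == "phi_paranoia_to_social_anxiety" &
                              tab$schema == "neg_other"], -0.5)
})

test_that("a fitted trivariate model recovers the configured schema structure", {
  fit <- small_model2_fit()
  tab <- between_correlations(fit)
  expect_equal(nrow(tab), 24)
  expect_true(all(tab$estimate >= -1 & tab$estimate <= 1))
  expect_true(all(tab$lower <= tab$upper))
  # strongest configured link: mean social anxiety vs negative-self (0.45)
  est <- tab$estimate[tab$term == "mu_social_anxiety" & tab$schema == "neg_self"]
  expect_gt(est, 0.05)
  # a configured near-zero link stays modest
  null_est <- tab$estimate[tab$term == "phi_social_anxiety_to_paranoia" &
                             tab$schema == "neg_self"]
  expect_lt(abs(null_est), 0.55)
})

test_that("tidy and glance summarize fitted models", {
  fit <- small_model2_fit()
  std <- tidy(fit)
  expect_s3_class(std, "dsem_effects")
  expect_equal(nrow(std), 12)
  expect_true(all(c("term", "label", "type", "estimate", "lower", "upper",
                    "significant", "re_variance") %in% names(std)))
  expect_equal(sum(std$type == "mean"), 3)
  expect_equal(sum(std$type == "autoregressive"), 3)
  expect_equal(sum(std$type == "cross-lagged"), 6)
  fx <- tidy(fit, effects = "fixed")
  expect_equal(nrow(fx), 12)
  g <- glance(fit)
  expect_equal(g$n_persons, fit$n_persons)
  expect_equal(g$retained_draws, fit$n_kept * 2)
  # plots build without evaluation errors
  expect_s3_class(autoplot(std), "ggplot")
  expect_s3_class(autoplot(completion_stats(small_model2_study()$records)),
                  "ggplot")
})

test_that("recovered averaged R-squared matches the generator's analytic value", {
  fit <- small_model2_fit()
  p <- esm_true_params()
  eff <- draw_person_effects(p, 2000, seed = 1)
  en <- dsemr:::effect_names(p$variables)
  analytic <- rowMeans(vapply(seq_len(2000), function(i) {
    phi_i <- matrix(as.numeric(eff[i, en[4:12]]), 3, 3, byrow = TRUE)
    1 - diag(p$sigma_w) / diag(stationary_cov(phi_i, p$sigma_w))
  }, numeric(3)))
  recovered <- within_r2(fit)$estimate
  expect_lt(max(abs(recovered - analytic)), 0.08)
})
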