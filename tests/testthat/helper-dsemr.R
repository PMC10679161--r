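# Shared fixtures: built in code, cached across test files.

tiny_params_k1 <- function(phi = 0.5, sigma = 0.75, mu = 2,
                           mu_sd = 0.9, phi_sd = 0.1) {
  esm_true_params(variables = "x", mu_bar = mu, phi_bar = matrix(phi),
                  gamma = 0, mu_sd = mu_sd, phi_sd = phi_sd,
                  sigma_w = matrix(sigma), schema_cor = matrix(0, 2, 2))
}

tiny_params_k2 <- function() {
  esm_true_params(variables = c("social_anxiety", "paranoia"),
                  gamma = c(0, 0))
}

# Contiguous hourly schedule (no gaps beyond nights), built by hand.
hourly_schedule <- function(n_persons, per_day = 13, days = 6,
                            wake_start_hour = 9) {
  sch <- expand.grid(prompt_index = seq_len(per_day), day = seq_len(days),
                     person_id = seq_len(n_persons))
  sch <- tibble::as_tibble(sch[, c("person_id", "day", "prompt_index")])
  sch$scheduled_minute <- (sch$prompt_index - 1) * 60
  sch$abs_minute <- (sch$day - 1) * 1440 + wake_start_hour * 60 + sch$scheduled_minute
  sch$clock_hour <- (sch$abs_minute %% 1440) / 60
  attr(sch, "prompts_per_day") <- per_day
  attr(sch, "n_days") <- days
  attr(sch, "waking_minutes") <- per_day * 60
  attr(sch, "wake_start_hour") <- wake_start_hour
  sch
}

# Minimal hand-built posterior object for post-processing tests: exact
# control over the draws without running the sampler.
fake_fit <- function(variables, person_effects, sigma_w, omega = NULL,
                     eta_bar = NULL, gamma = NULL, n_draws = 200,
                     schema_covariates = NULL, random_effects = TRUE) {
  k <- length(variables)
  de <- k + k * k
  n <- nrow(person_effects)
  pe_vec <- as.vector(t(person_effects))      # person-major flattening
  person <- matrix(rep(pe_vec, each = n_draws), n_draws, n * de)
  if (is.null(eta_bar)) eta_bar <- colMeans(person_effects)
  if (is.null(gamma)) gamma <- rep(0, k)
  d <- if (is.null(omega)) de else nrow(omega)
  if (is.null(omega)) omega <- diag(0, d)
  ch <- list(eta_bar = matrix(rep(eta_bar, each = n_draws), n_draws, de),
             gamma = matrix(rep(gamma, each = n_draws), n_draws, k),
             sigma_w = matrix(rep(as.vector(sigma_w), each = n_draws), n_draws, k * k),
             omega = matrix(rep(as.vector(omega), each = n_draws), n_draws, d * d),
             beta_gender = matrix(0, n_draws, 0),
             person = person, n_kept = n_draws)
  spec <- dsem_model(variables, include_hour_trend = FALSE,
                     schema_covariates = schema_covariates,
                     random_effects = random_effects,
                     chains = 2, iterations = 2 * n_draws, thin = 1, burn_in = 0)
  structure(list(chains = list(ch, ch), spec = spec, variables = variables,
                 effect_names = dsemr:::effect_names(variables),
                 person_ids = seq_len(n), n_persons = n, n_obs = n * 10,
                 schemas_present = !is.null(schema_covariates),
                 gender_present = FALSE, hour_var = 0,
                 n_kept = n_draws, seed = 1),
            class = "dsem_fit")
}

# Independent fixed-point solver for the stationary covariance (oracle).
lyapunov_fixed_point <- function(phi, sigma, iter = 10000, tol = 1e-14) {
  v <- sigma
  for (i in seq_len(iter)) {
    v_new <- phi %*% v %*% t(phi) + sigma
    if (max(abs(v_new - v)) < tol) return(v_new)
    v <- v_new
  }
  v
}

# One small fitted trivariate model with schema covariates, computed once
# and reused across test files.
cached_fit_env <- new.env(parent = emptyenv())
small_model2_fit <- function() {
  if (is.null(cached_fit_env$fit)) {
    p <- esm_true_params()
    study <- simulate_esm_study(p, n_persons = 40, seed = 77)
    analyzed <- suppressMessages(exclusion_filter(study$records))
    grid <- build_time_grid(analyzed)
    spec <- dsem_model(p$variables, schema_covariates = c("neg_self", "neg_other"),
                       gender = "gender", profile = "smoke")
    cached_fit_env$fit <- dsem_fit(grid, spec, persons = study$persons, seed = 78)
    cached_fit_env$study <- study
  }
  cached_fit_env$fit
}
small_model2_study <- function() {
  invisible(small_model2_fit())
  cached_fit_env$study
}
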