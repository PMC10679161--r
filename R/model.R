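#' Specify a two-level dynamic structural equation model
#'
#' Freezes all estimation choices for the multilevel lag-1 vector
#' autoregression: the momentary variables (bivariate social
#' anxiety/paranoia, or trivariate adding loneliness), the random-effect
#' set (all K person means plus all K^2 person lag coefficients, 6 for the
#' bivariate and 12 for the trivariate model), the hour-of-measurement
#' trend, the between-level covariates (schema scores enter the joint
#' between-person covariance, so their correlations with every random
#' effect are estimated; gender enters as a mean-structure predictor of the
#' random effects), priors, and sampler settings.
#'
#' Default priors are diffuse: normal(0, 10^6) on fixed effects and the
#' hour slope, inverse-Wishart(identity, K + 1) on the within residual
#' covariance, and inverse-Wishart(identity, d + 1) on the between
#' covariance of dimension d.
#'
#' @param variables Ordered names of the momentary variables.
#' @param include_hour_trend Add the centered clock hour as a within-level
#'   fixed effect (controls diurnal trend / non-stationarity).
#' @param schema_covariates Names of two between-person covariate columns to
#'   correlate with the random effects (e.g. `c("neg_self", "neg_other")`),
#'   or `NULL`.
#' @param gender Name of a binary between-person predictor column, or
#'   `NULL`.
#' @param random_effects If `FALSE`, all persons share one mean vector and
#'   one lag matrix (used for single-series checks against least squares).
#' @param chains,iterations,thin MCMC settings; the study profile is 4
#'   chains of 5000 iterations thinned by 10, the smoke profile
#'   (`profile = "smoke"`) 2 chains of 500 thinned by 5.
#' @param burn_in Fraction of each chain discarded before thinning.
#' @param beta_prior_var Prior variance of fixed effects and hour slope.
#' @param profile Convenience switch: `"full"` or `"smoke"`.
#' @return An object of class `dsem_spec`.
#' @examples
#' dsem_model(c("social_anxiety", "paranoia"))           # 6 random effects
#' dsem_model(c("social_anxiety", "paranoia", "loneliness"),
#'            schema_covariates = c("neg_self", "neg_other"))
#' @export
dsem_model <- function(variables,
                       include_hour_trend = TRUE,
                       schema_covariates = NULL,
                       gender = NULL,
                       random_effects = TRUE,
                       chains = NULL, iterations = NULL, thin = NULL,
                       burn_in = 0.5,
                       beta_prior_var = 1e6,
                       profile = c("full", "smoke")) {
  profile <- match.arg(profile)
  if (length(variables) < 1 || anyDuplicated(variables)) {
    abort("`variables` must be a non-empty vector of unique names.")
  }
  if (!is.null(schema_covariates) && length(schema_covariates) != 2) {
    abort("`schema_covariates` must name exactly two columns (negative-self, negative-other).")
  }
  defaults <- if (profile == "smoke") list(chains = 2L, iterations = 500L, thin = 5L)
              else list(chains = 4L, iterations = 5000L, thin = 10L)
  chains <- as.integer(chains %||% defaults$chains)
  iterations <- as.integer(iterations %||% defaults$iterations)
  thin <- as.integer(thin %||% defaults$thin)
  if (chains < 1 || iterations < thin) abort("Invalid sampler settings.")
  k <- length(variables)
  structure(list(
    variables = variables,
    k = k,
    n_random_effects = k + k * k,
    include_hour_trend = isTRUE(include_hour_trend),
    schema_covariates = schema_covariates,
    gender = gender,
    random_effects = isTRUE(random_effects),
    chains = chains, iterations = iterations, thin = thin,
    burn_in = burn_in, beta_prior_var = beta_prior_var,
    sigma_df_add = 1, omega_df_add = 1
  ), class = "dsem_spec")
}

#' @export
print.dsem_spec <- function(x, ...) {
  cat("<dsem_spec> VAR(1) on ", paste(x$variables, collapse = ", "), "\n", sep = "")
  cat("  random effects: ",
      if (x$random_effects) paste0(x$n_random_effects, " (", x$k, " means + ",
                                   x$k^2, " lag coefficients)") else "none (shared dynamics)",
      "\n", sep = "")
  if (!is.null(x$schema_covariates)) {
    cat("  between covariates: ", paste(x$schema_covariates, collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$gender)) cat("  between predictor: ", x$gender, "\n", sep = "")
  cat("  sampler: ", x$chains, " chains x ", x$iterations, " iterations, thin ",
      x$thin, ", burn-in ", sprintf("%.0f%%", 100 * x$burn_in), "\n", sep = "")
  invisible(x)
}
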