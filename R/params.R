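#' Ground-truth parameters for a synthetic experience-sampling study
#'
#' Defines the data-generating parameters of a two-level VAR(1) on momentary
#' variables: grand means, the population lag-1 coefficient matrix, an
#' hour-of-day trend, the between-person covariance of the random effects
#' (person means and person lag coefficients), the within-person innovation
#' covariance, correlations linking the random effects to two baseline
#' schema scores (negative-self and negative-other), and the compliance
#' distribution. Defaults emulate a 6-day, 10-prompt/day momentary study of
#' social anxiety, paranoia and loneliness in a non-clinical sample:
#' population dynamics with moderate inertia and positive spill-over,
#' momentary means near 2 on the 1-7 scale, mean compliance 72.1% (SD 0.16),
#' and schema-dynamics correlations concentrated on the mean levels and a
#' few cross-lagged couplings.
#'
#' @param variables Ordered names of the momentary variables (K = 1-3
#'   supported by the defaults; arbitrary K if all matrices are supplied).
#' @param mu_bar Grand means, length K (Likert units).
#' @param phi_bar K x K lag-1 coefficient matrix, row = outcome,
#'   column = predictor; must have spectral radius < 1.
#' @param gamma Hour-of-measurement slopes (Likert units per hour), length K.
#' @param mu_sd Between-person SDs of the person means, length K. Ignored if
#'   `omega` is given.
#' @param phi_sd Between-person SD of every lag coefficient (scalar or
#'   length K^2). Ignored if `omega` is given.
#' @param omega Optional full (K + K^2) x (K + K^2) between-person covariance
#'   of the stacked random effects `[means; lag coefficients]` in canonical
#'   order (K means, then the K^2 lag coefficients outcome-major).
#' @param sigma_w K x K within-person innovation covariance.
#' @param schema_cor (K + K^2) x 2 matrix of correlations between the random
#'   effects and the two schema scores (columns: negative-self,
#'   negative-other).
#' @param schema_means,schema_sds Length-2 mean and SD of the schema scores
#'   (subscale units, 0-24 scale).
#' @param schema_schema_cor Correlation between the two schema scores.
#' @param compliance_mean,compliance_sd Mean and SD of the per-person
#'   prompt-completion probability (Beta distributed, moment matched).
#' @param likert_emulation If `TRUE`, simulated composites are rounded to the
#'   item-mean lattice and clipped to the 1-7 response range. The default
#'   keeps composites continuous, matching the estimation model's treatment
#'   of the data.
#' @param items_per_var Number of items averaged into each composite (used
#'   by the Likert lattice and by optional item-level emission).
#'
#' @return An object of class `esm_true_params`.
#' @examples
#' p <- esm_true_params()
#' p$phi_bar
#' @export
esm_true_params <- function(variables = c("social_anxiety", "paranoia", "loneliness"),
                            mu_bar = NULL,
                            phi_bar = NULL,
                            gamma = NULL,
                            mu_sd = NULL,
                            phi_sd = 0.10,
                            omega = NULL,
                            sigma_w = NULL,
                            schema_cor = NULL,
                            schema_means = c(6, 6),
                            schema_sds = c(4.5, 4.5),
                            schema_schema_cor = 0.5,
                            compliance_mean = 0.721,
                            compliance_sd = 0.16,
                            likert_emulation = FALSE,
                            items_per_var = NULL) {
  k <- length(variables)
  if (k < 1 || anyDuplicated(variables)) {
    abort("`variables` must be a non-empty vector of unique names.")
  }
  defs <- default_truth(variables)
  if (is.null(mu_bar)) mu_bar <- defs$mu_bar
  if (is.null(phi_bar)) phi_bar <- defs$phi_bar
  if (is.null(gamma)) gamma <- rep(0, k)
  if (is.null(mu_sd)) mu_sd <- defs$mu_sd
  if (is.null(sigma_w)) sigma_w <- defs$sigma_w
  if (is.null(schema_cor)) schema_cor <- defs$schema_cor
  if (is.null(items_per_var)) items_per_var <- defs$items_per_var

  phi_bar <- as.matrix(phi_bar)
  sigma_w <- as.matrix(sigma_w)
  d_e <- k + k * k
  if (length(mu_bar) != k) abort("`mu_bar` must have length K.")
  if (!all(dim(phi_bar) == k)) abort("`phi_bar` must be K x K.")
  if (length(gamma) != k) abort("`gamma` must have length K.")
  if (spectral_radius(phi_bar) >= 1) {
    abort("`phi_bar` must have spectral radius < 1 (stationary mean dynamics).")
  }
  if (!is_psd(sigma_w)) abort("`sigma_w` must be symmetric positive semi-definite.")
  if (is.null(omega)) {
    if (length(phi_sd) == 1) phi_sd <- rep(phi_sd, k * k)
    if (length(mu_sd) != k || length(phi_sd) != k * k) {
      abort("`mu_sd` must have length K and `phi_sd` length 1 or K^2.")
    }
    omega <- diag(c(mu_sd, phi_sd)^2, d_e)
  }
  omega <- as.matrix(omega)
  if (!all(dim(omega) == d_e)) {
    abort(sprintf("`omega` must be %d x %d (K means + K^2 lag coefficients).", d_e, d_e))
  }
  if (!is_psd(omega)) abort("`omega` must be symmetric positive semi-definite.")
  schema_cor <- as.matrix(schema_cor)
  if (!all(dim(schema_cor) == c(d_e, 2))) {
    abort(sprintf("`schema_cor` must be %d x 2 (effects x {negative-self, negative-other}).", d_e))
  }
  if (any(abs(schema_cor) > 1)) abort("`schema_cor` entries must be correlations in [-1, 1].")
  if (!(compliance_mean > 0 && compliance_mean <= 1)) {
    abort("`compliance_mean` must lie in (0, 1].")
  }

  out <- structure(list(
    variables = variables,
    mu_bar = setNames(as.numeric(mu_bar), variables),
    phi_bar = structure(phi_bar, dimnames = list(variables, variables)),
    gamma = setNames(as.numeric(gamma), variables),
    omega = structure(omega, dimnames = list(effect_names(variables), effect_names(variables))),
    sigma_w = structure(sigma_w, dimnames = list(variables, variables)),
    schema_cor = structure(schema_cor,
                           dimnames = list(effect_names(variables),
                                           c("neg_self", "neg_other"))),
    schema_means = setNames(as.numeric(schema_means), c("neg_self", "neg_other")),
    schema_sds = setNames(as.numeric(schema_sds), c("neg_self", "neg_other")),
    schema_schema_cor = schema_schema_cor,
    compliance_mean = compliance_mean,
    compliance_sd = compliance_sd,
    likert_emulation = isTRUE(likert_emulation),
    items_per_var = setNames(as.integer(rep_len(items_per_var, k)), variables)
  ), class = "esm_true_params")
  # The joint [effects; schemas] covariance must itself be PSD.
  jc <- joint_effect_schema_cov(out)
  if (!is_psd(jc)) {
    abort(paste0("The joint covariance of [random effects; schema scores] implied by ",
                 "`omega` and `schema_cor` is not positive semi-definite; ",
                 "reduce `schema_cor` or the schema-schema correlation."))
  }
  out
}

# Joint covariance of the stacked random effects and the two schema scores,
# assembled from omega, the schema correlations and the schema SDs.
joint_effect_schema_cov <- function(params) {
  omega <- params$omega
  d_e <- nrow(omega)
  eff_sd <- sqrt(diag(omega))
  s_sd <- params$schema_sds
  cross <- params$schema_cor * outer(eff_sd, s_sd)       # cov(effect, schema)
  s_cov <- diag(s_sd^2)
  s_cov[1, 2] <- s_cov[2, 1] <- params$schema_schema_cor * prod(s_sd)
  out <- rbind(cbind(omega, cross), cbind(t(cross), s_cov))
  dimnames(out) <- list(c(rownames(omega), names(s_sd)),
                        c(rownames(omega), names(s_sd)))
  out
}

# Study-condition default truths per variable set. Population dynamics and
# mean levels follow the reported trivariate momentary model; the bivariate
# subset uses the corresponding bivariate fit.
default_truth <- function(variables) {
  canon <- c("social_anxiety", "paranoia", "loneliness")
  k <- length(variables)
  if (identical(variables, canon[1:2])) {
    mu <- c(2.08, 2.02)
    phi <- matrix(c(0.50, 0.29,
                    0.20, 0.47), 2, 2, byrow = TRUE)
    mu_sd <- sqrt(c(0.80, 0.62))
  } else if (identical(variables, canon)) {
    mu <- c(1.94, 1.88, 1.96)
    phi <- matrix(c(0.41, 0.25, 0.26,
                    0.19, 0.31, 0.21,
                    0.05, 0.19, 0.61), 3, 3, byrow = TRUE)
    mu_sd <- sqrt(c(0.95, 0.72, 0.84))
  } else {
    mu <- rep(2, k)
    phi <- diag(0.4, k)
    mu_sd <- rep(0.9, k)
  }
  sigma_w <- matrix(0.3, k, k) + diag(0.7, k)
  d_e <- k + k * k
  sc <- matrix(0, d_e, 2)
  if (identical(variables, canon)) {
    # rows in canonical order: mu_SA, mu_PAR, mu_LONE, then Phi rows
    # (outcome-major): SA<-SA, SA<-PAR, SA<-LONE, PAR<-SA, PAR<-PAR,
    # PAR<-LONE, LONE<-SA, LONE<-PAR, LONE<-LONE.
    sc[, 1] <- c(0.45, 0.35, 0.41,
                 -0.08, 0.32, -0.06,
                 -0.04, 0.28, -0.05,
                 -0.24, 0.24, 0.27)
    sc[, 2] <- c(0.29, 0.23, 0.27,
                 0.22, 0.10, -0.10,
                 0.30, 0.10, -0.23,
                 0.03, 0.15, 0.20)
  } else if (identical(variables, canon[1:2])) {
    sc[, 1] <- c(0.45, 0.35, -0.08, 0.32, -0.04, 0.28)
    sc[, 2] <- c(0.29, 0.23, 0.22, 0.10, 0.30, 0.10)
  }
  items <- c(social_anxiety = 3L, paranoia = 5L, loneliness = 3L)
  ipv <- ifelse(variables %in% names(items), items[variables], 3L)
  list(mu_bar = mu, phi_bar = phi, mu_sd = mu_sd, sigma_w = sigma_w,
       schema_cor = sc, items_per_var = unname(ipv))
}

#' @export
print.esm_true_params <- function(x, ...) {
  k <- length(x$variables)
  cat("<esm_true_params> ", k, " momentary variable(s): ",
      paste(x$variables, collapse = ", "), "\n", sep = "")
  cat("  grand means: ", paste(sprintf("%.2f", x$mu_bar), collapse = ", "), "\n", sep = "")
  cat("  spectral radius of phi_bar: ", sprintf("%.3f", spectral_radius(x$phi_bar)), "\n", sep = "")
  cat("  compliance: Beta(mean ", x$compliance_mean, ", sd ", x$compliance_sd, ")\n", sep = "")
  invisible(x)
}
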