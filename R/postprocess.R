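#' Equal-tailed credible intervals with a significance flag
#'
#' Summarizes labelled posterior draws into point estimates (posterior
#' median), equal-tailed credible bounds from empirical quantiles, and a
#' significance flag set when the interval excludes zero.
#'
#' @param draws A numeric matrix of draws (rows) by parameters (named
#'   columns), or a long data frame with columns `term` and `value`.
#' @param level Credible level (default 0.95).
#' @return A tibble: `term`, `estimate`, `lower`, `upper`, `significant`.
#' @examples
#' credible_intervals(cbind(phi = rnorm(1000, 0.3, 0.05)))
#' @export
credible_intervals <- function(draws, level = 0.95) {
  if (is.data.frame(draws)) {
    if (!all(c("term", "value") %in% names(draws))) {
      abort("Long-format `draws` needs columns `term` and `value`.")
    }
    wide <- split(draws$value, draws$term)
  } else {
    draws <- as.matrix(draws)
    if (is.null(colnames(draws))) colnames(draws) <- paste0("par", seq_len(ncol(draws)))
    wide <- as.list(as.data.frame(draws))
  }
  n_min <- ceiling(5 / (1 - level))
  lens <- lengths(wide)
  if (any(lens < n_min)) {
    abort(sprintf("Need at least %d draws per parameter for a %.0f%% interval (got %d).",
                  n_min, 100 * level, min(lens)))
  }
  a <- (1 - level) / 2
  purrr::map_dfr(names(wide), function(nm) {
    x <- wide[[nm]]
    q <- unname(quantile(x, c(a, 1 - a), type = 7))
    tibble::tibble(term = nm, estimate = median(x),
                   lower = q[1], upper = q[2],
                   significant = q[1] > 0 | q[2] < 0)
  })
}

# Per-draw person-averaged standardized lag effects and within-person R2.
# For each retained draw: solve each person's stationary covariance
# V = Phi V Phi' + Sigma_w, standardize phi[out, pred] by sd_pred / sd_out,
# compute R2_k = 1 - Sigma_w[k,k] / (V[k,k] + gamma_k^2 var(hour)), then
# average over persons. Non-stationary person draws are excluded from that
# draw's average and counted.
per_draw_summaries <- function(fit) {
  k <- length(fit$variables)
  de <- k + k * k
  sig <- draws_matrix(fit, "sigma_w")
  gam <- draws_matrix(fit, "gamma")
  n_draws <- nrow(sig)
  hv <- fit$hour_var
  if (fit$spec$random_effects) {
    pers <- draws_matrix(fit, "person")
    n <- fit$n_persons
  } else {
    eta <- draws_matrix(fit, "eta_bar")
    n <- 1L
  }
  std <- array(NA_real_, c(n_draws, k, k))
  r2 <- matrix(NA_real_, n_draws, k)
  n_nonstat <- 0L
  ikk <- diag(k * k)
  for (r in seq_len(n_draws)) {
    s <- matrix(sig[r, ], k, k)
    std_sum <- matrix(0, k, k)
    r2_sum <- numeric(k)
    used <- 0L
    for (i in seq_len(n)) {
      if (fit$spec$random_effects) {
        e_i <- pers[r, ((i - 1) * de + 1):(i * de)]
      } else {
        e_i <- eta[r, ]
      }
      phi_i <- matrix(e_i[(k + 1):de], k, k, byrow = TRUE)
      kp <- ikk - kronecker(phi_i, phi_i)
      v <- try(matrix(solve(kp, as.vector(s)), k, k), silent = TRUE)
      if (inherits(v, "try-error") || any(diag(v) <= 0) ||
          spectral_radius(phi_i) >= 1) {
        n_nonstat <- n_nonstat + 1L
        next
      }
      sdv <- sqrt(diag(v))
      std_sum <- std_sum + phi_i * outer(1 / sdv, sdv)
      r2_sum <- r2_sum + 1 - diag(s) / (diag(v) + gam[r, ]^2 * hv)
      used <- used + 1L
    }
    if (used > 0) {
      std[r, , ] <- std_sum / used
      r2[r, ] <- r2_sum / used
    }
  }
  list(std = std, r2 = r2, n_nonstat = n_nonstat, n_draws = n_draws)
}

#' Within-person standardized fixed-effect table
#'
#' Builds the main effect table of the analysis: person means on the raw
#' response scale, and lag-1 autoregressive and cross-lagged effects
#' standardized within person. Per draw and person, each lag coefficient is
#' multiplied by the ratio of the predictor's to the outcome's stationary
#' within-person SD (the stationary covariance solves the discrete Lyapunov
#' equation \eqn{V = \Phi_i V \Phi_i' + \Sigma_w}); standardized values are
#' averaged over persons within each draw and then summarized across draws
#' (median and equal-tailed credible interval). Random-effect variances are
#' summarized from the between-covariance diagonal.
#'
#' @param fit A [dsem_fit()] object.
#' @param level Credible level.
#' @return A tibble of class `dsem_effects`: `term`, `label`, `type`,
#'   `estimate`, `lower`, `upper`, `significant`, and random-effect
#'   variance columns `re_variance`, `re_lower`, `re_upper`. K means +
#'   K^2 lag rows (6 for the bivariate, 12 for the trivariate model).
#' @export
standardize_within <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "dsem_fit"))
  vars <- fit$variables
  k <- length(vars)
  en <- fit$effect_names
  sums <- per_draw_summaries(fit)
  if (sums$n_nonstat > 0) {
    rlang::inform(sprintf(
      "%d non-stationary person-draw(s) excluded from standardization averages.",
      sums$n_nonstat))
  }
  eta <- draws_matrix(fit, "eta_bar")
  draw_mat <- eta[, seq_len(k), drop = FALSE]   # means, raw scale
  colnames(draw_mat) <- en[seq_len(k)]
  std_mat <- matrix(NA_real_, sums$n_draws, k * k)
  col <- 0L
  for (out in seq_len(k)) for (pred in seq_len(k)) {
    col <- col + 1L
    std_mat[, col] <- sums$std[, out, pred]
  }
  colnames(std_mat) <- en[(k + 1):(k + k * k)]
  all_draws <- cbind(draw_mat, std_mat)
  all_draws <- all_draws[stats::complete.cases(all_draws), , drop = FALSE]
  tab <- credible_intervals(all_draws, level)
  tab <- tab[match(en, tab$term), ]
  tab$label <- vapply(tab$term, effect_label, "", variables = vars)
  tab$type <- effect_type(tab$term)
  if (fit$spec$random_effects) {
    om <- draws_matrix(fit, "omega")
    d <- as.integer(sqrt(ncol(om)))
    re <- purrr::map_dfr(seq_along(en), function(j) {
      x <- om[, (j - 1) * d + j]
      q <- quantile(x, c((1 - level) / 2, 1 - (1 - level) / 2))
      tibble::tibble(re_variance = median(x), re_lower = q[[1]], re_upper = q[[2]])
    })
  } else {
    re <- tibble::tibble(re_variance = rep(NA_real_, length(en)),
                         re_lower = NA_real_, re_upper = NA_real_)
  }
  out <- dplyr::bind_cols(tab[, c("term", "label")],
                          tibble::tibble(type = tab$type),
                          tab[, c("estimate", "lower", "upper", "significant")], re)
  structure(out, table_id = paste0("model_k", k), level = level,
            class = c("dsem_effects", class(out)))
}

#' Averaged within-person R-squared
#'
#' Per draw and person, the proportion of stationary within-person variance
#' of each momentary variable explained by the lagged predictors and the
#' hour trend, \eqn{R^2_k = 1 - \Sigma_w[k,k] / V_{total}[k,k]}, averaged
#' over persons and summarized across draws.
#'
#' @inheritParams standardize_within
#' @return A tibble: `variable`, `estimate`, `lower`, `upper`.
#' @export
within_r2 <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "dsem_fit"))
  sums <- per_draw_summaries(fit)
  r2 <- sums$r2[stats::complete.cases(sums$r2), , drop = FALSE]
  colnames(r2) <- fit$variables
  tab <- credible_intervals(r2, level)
  tibble::tibble(variable = tab$term, estimate = tab$estimate,
                 lower = tab$lower, upper = tab$upper)
}

#' Between-person correlations of random effects with schema scores
#'
#' Per draw, the correlation between each random effect (person means and
#' lag coefficients) and each schema covariate is computed from the
#' covariate blocks of the between-person covariance \eqn{\Omega}
#' (cov / sqrt(var x var)), then summarized with credible intervals and the
#' exclusion-of-zero significance rule — the trivariate model yields the
#' 12 x 2 correlation table.
#'
#' @inheritParams standardize_within
#' @return A tibble of class `dsem_effects`: `term`, `schema`, `label`,
#'   `estimate`, `lower`, `upper`, `significant`.
#' @export
between_correlations <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "dsem_fit"))
  if (!fit$schemas_present) {
    abort("The model was fitted without schema covariates; no covariate block in Omega.")
  }
  vars <- fit$variables
  k <- length(vars)
  de <- k + k * k
  en <- fit$effect_names
  scnames <- fit$spec$schema_covariates
  om <- draws_matrix(fit, "omega")
  d <- as.integer(sqrt(ncol(om)))
  n_s <- d - de
  cors <- matrix(NA_real_, nrow(om), de * n_s)
  nm <- character(de * n_s)
  col <- 0L
  for (s in seq_len(n_s)) for (j in seq_len(de)) {
    col <- col + 1L
    js <- de + s
    cors[, col] <- om[, (js - 1) * d + j] /
      sqrt(om[, (j - 1) * d + j] * om[, (js - 1) * d + js])
    nm[col] <- paste0(en[j], "~", scnames[s])
  }
  if (any(abs(cors) > 1 + 1e-8)) {
    abort("A posterior draw produced a correlation outside [-1, 1]; Omega draw not positive definite.")
  }
  cors <- pmin(pmax(cors, -1), 1)
  colnames(cors) <- nm
  tab <- credible_intervals(cors, level)
  parts <- strsplit(tab$term, "~", fixed = TRUE)
  tab$schema <- vapply(parts, `[[`, "", 2)
  tab$effect <- vapply(parts, `[[`, "", 1)
  out <- tibble::tibble(
    term = tab$effect, schema = tab$schema,
    label = paste0(vapply(tab$effect, effect_label, "", variables = vars),
                   " ~ ", tab$schema),
    type = effect_type(tab$effect),
    estimate = tab$estimate, lower = tab$lower, upper = tab$upper,
    significant = tab$significant)
  out <- dplyr::arrange(out, match(.data$term, en), match(.data$schema, scnames))
  structure(out, table_id = "between_correlations", level = level,
            class = c("dsem_effects", class(out)))
}

#' Gender moderation of the random dynamics
#'
#' Summarizes the between-level regression of each random lag coefficient
#' on the binary gender predictor: posterior medians, credible intervals
#' and the exclusion-of-zero significance flag.
#'
#' @inheritParams standardize_within
#' @return A tibble of class `dsem_effects` with one row per lag
#'   coefficient.
#' @export
gender_moderation <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "dsem_fit"))
  if (!fit$gender_present) {
    abort("The model was fitted without a gender predictor; refit with `gender=` in dsem_model().")
  }
  vars <- fit$variables
  k <- length(vars)
  en <- fit$effect_names
  bg <- draws_matrix(fit, "beta_gender")
  colnames(bg) <- en
  lag_terms <- en[(k + 1):(k + k * k)]
  tab <- credible_intervals(bg[, lag_terms, drop = FALSE], level)
  out <- tibble::tibble(
    term = tab$term,
    label = paste0("gender -> ", vapply(tab$term, effect_label, "", variables = vars)),
    type = effect_type(tab$term),
    estimate = tab$estimate, lower = tab$lower, upper = tab$upper,
    significant = tab$significant)
  structure(out, table_id = "gender_moderation", level = level,
            class = c("dsem_effects", class(out)))
}
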