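#' Fit a two-level Bayesian VAR(1) by blocked Gibbs sampling
#'
#' Estimates the dynamic structural equation model on gridded momentary
#' series: per person i and grid cell t,
#' \deqn{y_{it} = \mu_i + w_{it}, \quad
#'       w_{it} = \Phi_i w_{i,t-1} + \gamma \, hour_{it} + \varepsilon_{it},
#'       \quad \varepsilon \sim N(0, \Sigma_w),}
#' with the person means, all person lag coefficients and (when supplied)
#' the grand-mean-centered schema scores jointly multivariate normal with
#' free covariance \eqn{\Omega} at the between level, and gender (when
#' supplied) as a between-level predictor of the random effects. Missing
#' grid cells are treated as missing at random and sampled as latent data
#' inside the chain. All updates are conjugate (normal / inverse-Wishart);
#' draws are deterministic given the seed.
#'
#' @param grid A [build_time_grid()] result (or any tibble with
#'   `person_id`, `cell`, `hour_c`, `observed` and the model variables).
#' @param model A [dsem_model()] specification.
#' @param persons Optional per-person tibble with `person_id` and the
#'   between-level covariate columns named in the spec. Schema covariates
#'   are grand-mean centered over the analyzed persons before entering the
#'   model.
#' @param seed Integer seed; chain seeds are derived from it.
#' @return An object of class `dsem_fit` holding labelled posterior draws
#'   per chain (fixed effects, hour slopes, within residual covariance,
#'   between covariance including covariate blocks, gender coefficients,
#'   per-person effects) plus metadata. Use [generics::tidy()],
#'   [standardize_within()], [within_r2()], [between_correlations()],
#'   [convergence()].
#' @export
dsem_fit <- function(grid, model, persons = NULL, seed = 1) {
  stopifnot(inherits(model, "dsem_spec"))
  vars <- model$variables
  missing_vars <- setdiff(vars, names(grid))
  if (length(missing_vars)) {
    abort(paste0("Variables not in the grid: ", paste(missing_vars, collapse = ", "),
                 ". Available: ", paste(setdiff(names(grid), c("person_id", "cell",
                 "cell_minute", "clock_hour", "hour_c", "observed")), collapse = ", ")))
  }
  ids <- unique(grid$person_id)
  n <- length(ids)
  if (model$random_effects && n < 2) abort("Random-effects estimation needs at least 2 persons.")

  y_list <- vector("list", n)
  hour_list <- vector("list", n)
  usable <- logical(n)
  for (i in seq_len(n)) {
    g_i <- grid[grid$person_id == ids[i], ]
    g_i <- g_i[order(g_i$cell), ]
    obs_idx <- which(g_i$observed)
    if (length(obs_idx) == 0) abort(sprintf("Person %s has no observed cells.", ids[i]))
    g_i <- g_i[min(obs_idx):max(obs_idx), ]   # series must start/end observed
    y <- as.matrix(g_i[, vars])
    y[!g_i$observed, ] <- NA_real_
    if (nrow(y) < 2) abort(sprintf("Person %s has fewer than 2 grid cells.", ids[i]))
    obs_vals <- y[g_i$observed, , drop = FALSE]
    v <- apply(obs_vals, 2, stats::var)
    if (any(!is.finite(v)) || any(v <= 0)) {
      abort(sprintf("Person %s has zero within-person variance for at least one variable.", ids[i]))
    }
    usable[i] <- any(g_i$observed & dplyr::lag(g_i$observed, default = FALSE))
    y_list[[i]] <- y
    hour_list[[i]] <- if (model$include_hour_trend) g_i$hour_c else rep(0, nrow(g_i))
  }
  if (!any(usable)) abort("No person has two adjacent occupied grid cells; nothing identifies the lag effects.")

  schemas <- matrix(0, n, 0)
  gender <- numeric(0)
  if (!is.null(model$schema_covariates) || !is.null(model$gender)) {
    if (is.null(persons)) abort("Between-level covariates requested but `persons` not supplied.")
    pcols <- c(model$schema_covariates, model$gender)
    missing_cols <- setdiff(pcols, names(persons))
    if (length(missing_cols)) {
      abort(paste0("Covariates not in `persons`: ", paste(missing_cols, collapse = ", "),
                   ". Available: ", paste(names(persons), collapse = ", ")))
    }
    pm <- persons[match(ids, persons$person_id), ]
    if (anyNA(pm$person_id)) abort("Every analyzed person must appear in `persons`.")
    if (!is.null(model$schema_covariates)) {
      schemas <- as.matrix(pm[, model$schema_covariates])
      schemas <- scale(schemas, center = TRUE, scale = FALSE)  # grand-mean centered
    }
    if (!is.null(model$gender)) {
      gender <- as.numeric(pm[[model$gender]])
      if (length(unique(gender)) < 2) {
        abort("`gender` is constant across persons; no between-person variance to model.")
      }
    }
  }

  burn <- as.integer(floor(model$burn_in * model$iterations))
  chains <- vector("list", model$chains)
  for (ch in seq_len(model$chains)) {
    with_seed(derive_seed(seed, 100 + ch), {
      chains[[ch]] <- .gibbs_dsem(
        y_list, hour_list, schemas,
        if (length(gender)) gender else numeric(0),
        model$random_effects, model$include_hour_trend, length(gender) > 0,
        model$iterations, burn, model$thin,
        model$beta_prior_var, model$sigma_df_add, model$omega_df_add)
    })
  }

  en <- effect_names(vars)
  structure(list(
    chains = chains,
    spec = model,
    variables = vars,
    effect_names = en,
    person_ids = ids,
    n_persons = n,
    n_obs = sum(grid$observed),
    schemas_present = ncol(schemas) > 0,
    gender_present = length(gender) > 0,
    hour_var = if (model$include_hour_trend) stats::var(grid$hour_c[grid$observed]) else 0,
    n_kept = chains[[1]]$n_kept,
    seed = seed
  ), class = "dsem_fit")
}

#' @export
print.dsem_fit <- function(x, ...) {
  cat("<dsem_fit> ", length(x$variables), "-variate two-level VAR(1), ",
      x$n_persons, " persons, ", x$n_obs, " observations\n", sep = "")
  cat("  ", x$spec$chains, " chains x ", x$n_kept, " retained draws",
      if (x$schemas_present) "; schema covariates in Omega", "",
      if (x$gender_present) "; gender predictor", "", "\n", sep = "")
  cat("  posterior median fixed effects:\n")
  s <- apply(draws_matrix(x, "eta_bar"), 2, median)
  names(s) <- vapply(x$effect_names, effect_label, "", variables = x$variables)
  print(round(s, 3))
  invisible(x)
}

# Stack one component's draws across chains into a draws x dim matrix.
draws_matrix <- function(fit, what) {
  do.call(rbind, lapply(fit$chains, function(ch) ch[[what]]))
}

# Per-chain array accessor used by convergence diagnostics.
chain_array <- function(fit, what) {
  lapply(fit$chains, function(ch) ch[[what]])
}
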