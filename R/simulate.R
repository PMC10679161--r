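#' Draw person-level random effects and baseline covariates
#'
#' Person means, person lag-coefficient matrices and the two schema scores
#' are drawn jointly multivariate normal around
#' `(mu_bar, vec(phi_bar), schema_means)` with the joint covariance implied
#' by `omega` and the configured schema correlations, mirroring the
#' between-person level of the model where all random effects correlate
#' freely with each other and with the baseline schemas. Gender is
#' Bernoulli(0.5) and, by default, has no effect on the dynamics; a
#' configurable additive shift on chosen lag coefficients supports
#' moderation power studies. Persons whose lag matrix is non-stationary
#' (spectral radius >= 1) are rejected and redrawn.
#'
#' @param params An [esm_true_params()] object.
#' @param n_persons Number of persons to draw.
#' @param seed Integer seed.
#' @param gender_shift Optional named numeric vector of additive shifts
#'   applied to lag coefficients for persons with `gender == 1`, e.g.
#'   `c("phi_social_anxiety_to_paranoia" = 0.3)`.
#' @param max_attempts Redraw budget per batch before erroring on
#'   persistent non-stationarity.
#'
#' @return A tibble with one row per person: `person_id`, the random
#'   effects in canonical order (`mu_*`, `phi_*_to_*`), `neg_self`,
#'   `neg_other`, `gender` and `completion_prob`.
#' @export
draw_person_effects <- function(params, n_persons, seed = NULL,
                                gender_shift = NULL, max_attempts = 1000) {
  stopifnot(inherits(params, "esm_true_params"))
  k <- length(params$variables)
  d_e <- k + k * k
  jc <- joint_effect_schema_cov(params)
  if (!is_psd(jc)) {
    abort("Joint covariance of [random effects; schemas] is not positive semi-definite.")
  }
  centre <- c(params$mu_bar, as.vector(t(params$phi_bar)), params$schema_means)
  with_seed(seed, {
    draws <- matrix(NA_real_, n_persons, d_e + 2)
    need <- seq_len(n_persons)
    attempts <- 0L
    while (length(need) > 0) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        abort("Could not draw stationary person dynamics within `max_attempts`; reduce `phi_sd` or `phi_bar`.")
      }
      cand <- rmvn(length(need), matrix(centre, length(need), d_e + 2, byrow = TRUE), jc)
      ok <- vapply(seq_len(nrow(cand)), function(i) {
        phi_i <- matrix(cand[i, (k + 1):d_e], k, k, byrow = TRUE)
        spectral_radius(phi_i) < 1
      }, logical(1))
      draws[need[ok], ] <- cand[ok, , drop = FALSE]
      need <- need[!ok]
    }
    gender <- stats::rbinom(n_persons, 1, 0.5)
    if (!is.null(gender_shift)) {
      en <- effect_names(params$variables)
      bad <- setdiff(names(gender_shift), en)
      if (length(bad)) abort(paste0("Unknown effect in `gender_shift`: ", paste(bad, collapse = ", ")))
      for (nm in names(gender_shift)) {
        j <- match(nm, en)
        draws[gender == 1, j] <- draws[gender == 1, j] + gender_shift[[nm]]
      }
    }
    completion <- rbeta_moments(n_persons, params$compliance_mean, params$compliance_sd)
    out <- tibble::as_tibble(as.data.frame(draws))
    names(out) <- c(effect_names(params$variables), "neg_self", "neg_other")
    out <- dplyr::bind_cols(tibble::tibble(person_id = seq_len(n_persons)), out)
    out$gender <- gender
    out$completion_prob <- completion
    out
  })
}

# Beta draws with given mean and SD (moment matched); degenerate SD -> constant.
rbeta_moments <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  v <- sd^2
  vmax <- mean * (1 - mean)
  if (v >= vmax) v <- 0.95 * vmax
  conc <- mean * (1 - mean) / v - 1
  pmin(pmax(rbeta(n, mean * conc, (1 - mean) * conc), 1e-3), 1)
}

#' Simulate momentary responses on the study schedule
#'
#' Per person, a latent centered process is simulated on a continuous
#' one-hour grid spanning the study week (so that the generator's dynamics
#' coincide exactly with the hourly estimand of the analysis), starting from
#' the stationary distribution of that person's VAR(1) and evolving as
#' \eqn{w_t = \Phi_i w_{t-1} + \gamma \, h_t + \varepsilon_t},
#' \eqn{\varepsilon_t \sim N(0, \Sigma_w)}, where `h_t` is the centered
#' clock hour of grid cell `t`. The observed composite at each prompt is the
#' person mean plus the latent deviation at the prompt's grid cell.
#'
#' @param schedule A [generate_schedule()] tibble.
#' @param effects A [draw_person_effects()] tibble.
#' @param params An [esm_true_params()] object.
#' @param seed Integer seed.
#' @param emit_items If `TRUE`, per-item responses are also emitted: each
#'   item is the composite plus independent Gaussian item noise, rounded and
#'   clipped to the 1-7 scale, and the composite is replaced by the item
#'   mean.
#' @param item_noise_sd SD of the item-level noise.
#'
#' @return A long-format tibble (`person_id`, `day`, `prompt_index`,
#'   `scheduled_minute`, `timestamp_minute`, one column per momentary
#'   variable, optional item columns), carrying the schedule's design
#'   attributes plus `scheduled_per_person`.
#' @export
simulate_series <- function(schedule, effects, params, seed = NULL,
                            emit_items = FALSE, item_noise_sd = 0.5) {
  stopifnot(inherits(params, "esm_true_params"))
  vars <- params$variables
  k <- length(vars)
  en <- effect_names(vars)
  wake <- attr(schedule, "wake_start_hour") %||% 9
  waking <- attr(schedule, "waking_minutes") %||% 780
  hour_centre <- wake + waking / 120  # mean clock hour of the waking window
  n_cells <- ceiling(max(schedule$abs_minute) / 60) + 1L

  with_seed(seed, {
    out <- vector("list", nrow(effects))
    for (i in seq_len(nrow(effects))) {
      pid <- effects$person_id[i]
      mu_i <- as.numeric(effects[i, paste0("mu_", vars)])
      phi_i <- matrix(as.numeric(effects[i, en[(k + 1):(k + k * k)]]), k, k, byrow = TRUE)
      if (spectral_radius(phi_i) >= 1) {
        abort(sprintf("Person %s has non-stationary dynamics (spectral radius >= 1).", pid))
      }
      v0 <- stationary_cov(phi_i, params$sigma_w)
      hours <- ((seq_len(n_cells) - 1) %% 24)
      h_c <- hours - hour_centre
      w <- matrix(NA_real_, n_cells, k)
      w[1, ] <- rmvn(1, matrix(0, 1, k), v0)
      innov <- rmvn(n_cells - 1, matrix(0, n_cells - 1, k), params$sigma_w)
      for (t in 2:n_cells) {
        w[t, ] <- phi_i %*% w[t - 1, ] + params$gamma * h_c[t] + innov[t - 1, ]
      }
      sch_i <- schedule[schedule$person_id == pid, ]
      cell <- round(sch_i$abs_minute / 60) + 1L
      y <- sweep(w[cell, , drop = FALSE], 2, mu_i, "+")
      colnames(y) <- vars
      row <- dplyr::bind_cols(
        sch_i[, c("person_id", "day", "prompt_index", "scheduled_minute")],
        tibble::tibble(timestamp_minute = sch_i$abs_minute),
        tibble::as_tibble(y)
      )
      out[[i]] <- row
    }
    res <- dplyr::bind_rows(out)
    if (emit_items) {
      for (j in seq_along(vars)) {
        n_it <- params$items_per_var[[j]]
        items <- matrix(rnorm(nrow(res) * n_it, 0, item_noise_sd), ncol = n_it) + res[[vars[j]]]
        items <- pmin(pmax(round(items), 1), 7)
        colnames(items) <- paste0(vars[j], "_item", seq_len(n_it))
        res[[vars[j]]] <- rowMeans(items)
        res <- dplyr::bind_cols(res, tibble::as_tibble(items))
      }
    } else if (params$likert_emulation) {
      for (j in seq_along(vars)) {
        step <- 1 / params$items_per_var[[j]]
        res[[vars[j]]] <- pmin(pmax(round(res[[vars[j]]] / step) * step, 1), 7)
      }
    }
    attr(res, "scheduled_per_person") <-
      (attr(schedule, "prompts_per_day") %||% NA_integer_) *
      (attr(schedule, "n_days") %||% NA_integer_)
    attr(res, "variables") <- vars
    attr(res, "wake_start_hour") <- wake
    res
  })
}

#' Thin a simulated dataset by person-level compliance
#'
#' Each prompt row is retained independently with that person's completion
#' probability, a missingness mechanism that depends only on the person
#' (never on the momentary responses), hence missing at random with respect
#' to the within-person process. Retained rows are unchanged.
#'
#' @param data A long-format momentary dataset (from [simulate_series()]).
#' @param effects A [draw_person_effects()] tibble supplying
#'   `completion_prob` per person.
#' @param seed Integer seed.
#' @return The thinned tibble; realized per-person completion rates are
#'   attached as attribute `realized_completion`.
#' @export
apply_missingness <- function(data, effects, seed = NULL) {
  p <- effects$completion_prob[match(data$person_id, effects$person_id)]
  if (any(is.na(p))) abort("Every person in `data` must appear in `effects`.")
  if (any(p <= 0 | p > 1)) abort("`completion_prob` must lie in (0, 1].")
  with_seed(seed, {
    keep <- runif(nrow(data)) < p
    out <- data[keep, ]
    realized <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(person_id = data$person_id, keep = keep), .data$person_id),
      scheduled = dplyr::n(), completed = sum(.data$keep),
      rate = mean(.data$keep), .groups = "drop")
    for (a in c("scheduled_per_person", "variables", "wake_start_hour")) {
      attr(out, a) <- attr(data, a)
    }
    attr(out, "realized_completion") <- realized
    if (nrow(out) == 0) warn("All prompts were thinned away; the dataset is empty.")
    out
  })
}

#' Simulate a complete synthetic experience-sampling study
#'
#' Convenience wrapper chaining [generate_schedule()],
#' [draw_person_effects()], [simulate_series()] and [apply_missingness()]
#' with deterministically derived stage seeds.
#'
#' @inheritParams generate_schedule
#' @inheritParams simulate_series
#' @param params An [esm_true_params()] object.
#' @param seed Master seed; stage seeds are derived from it.
#' @param missingness If `FALSE`, all scheduled prompts are completed.
#' @return A list of class `esm_study`: `records` (completed prompts),
#'   `persons` (true effects and covariates), `schedule`, `params`.
#' @examples
#' study <- simulate_esm_study(esm_true_params(), n_persons = 4, seed = 7)
#' dplyr::glimpse(study$records)
#' @export
simulate_esm_study <- function(params = esm_true_params(),
                               n_persons = 134,
                               n_days = 6,
                               prompts_per_day = 10,
                               waking_minutes = 780,
                               min_gap = 15,
                               seed = 1,
                               emit_items = FALSE,
                               missingness = TRUE) {
  schedule <- generate_schedule(n_persons, n_days, prompts_per_day,
                                waking_minutes, min_gap, seed = derive_seed(seed, 1))
  persons <- draw_person_effects(params, n_persons, seed = derive_seed(seed, 2))
  records <- simulate_series(schedule, persons, params,
                             seed = derive_seed(seed, 3), emit_items = emit_items)
  if (missingness) {
    records <- apply_missingness(records, persons, seed = derive_seed(seed, 4))
  }
  structure(list(records = records, persons = persons,
                 schedule = schedule, params = params, seed = seed),
            class = "esm_study")
}

#' @export
print.esm_study <- function(x, ...) {
  cat("<esm_study> ", dplyr::n_distinct(x$records$person_id), " persons, ",
      nrow(x$records), " completed prompts (",
      sprintf("%.1f%%", 100 * nrow(x$records) / nrow(x$schedule)),
      " of scheduled)\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
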