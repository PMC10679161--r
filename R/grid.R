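#' Exclude persons below the minimum completion fraction
#'
#' Persons completing fewer than `min_fraction` of their scheduled prompts
#' are removed before analysis, the standard ESM inclusion rule (one third
#' of 60 scheduled prompts is 20; a person with 19 completed is excluded, a
#' person with exactly 20 retained). The comparison is strict: completed
#' counts equal to the threshold are kept.
#'
#' @param data Long-format momentary tibble; the scheduled prompt count per
#'   person must be available, either as attribute `scheduled_per_person`
#'   (set by the simulator) or via the argument.
#' @param scheduled_per_person Scheduled prompts per person (scalar), used
#'   when the attribute is absent.
#' @param min_fraction Minimum completed fraction (default one third).
#' @return The retained rows, unmodified, with attribute
#'   `exclusion_report`: a tibble of `person_id`, `completed`, `scheduled`,
#'   `excluded` covering every person in the input.
#' @export
exclusion_filter <- function(data, scheduled_per_person = NULL, min_fraction = 1 / 3) {
  sched <- scheduled_per_person %||% attr(data, "scheduled_per_person")
  if (is.null(sched) || is.na(sched)) {
    abort(paste0("Scheduled prompt count unknown: attach attribute ",
                 "`scheduled_per_person` or pass `scheduled_per_person=`."))
  }
  counts <- dplyr::count(data, .data$person_id, name = "completed")
  counts$scheduled <- sched
  counts$excluded <- counts$completed < min_fraction * sched
  keep_ids <- counts$person_id[!counts$excluded]
  out <- data[data$person_id %in% keep_ids, ]
  for (a in c("scheduled_per_person", "variables", "wake_start_hour")) {
    attr(out, a) <- attr(data, a)
  }
  attr(out, "scheduled_per_person") <- sched
  attr(out, "exclusion_report") <- counts
  if (any(counts$excluded)) {
    rlang::inform(sprintf("Excluded %d person(s) completing fewer than %.0f of %d prompts.",
                          sum(counts$excluded), min_fraction * sched, sched))
  }
  out
}

#' Completion descriptives for a momentary dataset
#'
#' Per-person completed counts and completion rates, aggregate mean/SD/range
#' of rates, the total number of entries, and the mean within-day gap
#' between consecutive completed prompts.
#'
#' @inheritParams exclusion_filter
#' @return A list of class `completion_stats` with elements `person` (one
#'   row per person) and `aggregate` (one row). [generics::tidy()] returns
#'   the per-person table, [generics::glance()] the aggregate row.
#' @export
completion_stats <- function(data, scheduled_per_person = NULL) {
  sched <- scheduled_per_person %||% attr(data, "scheduled_per_person")
  if (is.null(sched) || is.na(sched)) {
    abort("Scheduled prompt count unknown; pass `scheduled_per_person=`.")
  }
  person <- dplyr::count(data, .data$person_id, name = "completed")
  person$scheduled <- sched
  person$rate <- person$completed / sched
  gaps <- data |>
    dplyr::arrange(.data$person_id, .data$timestamp_minute) |>
    dplyr::group_by(.data$person_id, .data$day) |>
    dplyr::mutate(gap = .data$timestamp_minute - dplyr::lag(.data$timestamp_minute)) |>
    dplyr::ungroup()
  aggregate <- tibble::tibble(
    n_persons = nrow(person),
    total_entries = sum(person$completed),
    mean_rate = mean(person$rate),
    sd_rate = sd(person$rate),
    min_rate = min(person$rate),
    max_rate = max(person$rate),
    mean_within_day_gap = mean(gaps$gap, na.rm = TRUE)
  )
  structure(list(person = person, aggregate = aggregate), class = "completion_stats")
}

#' @export
print.completion_stats <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("<completion_stats> %d persons, %d entries; mean completion %.1f%% (SD %.2f, range %.1f-%.1f%%)\n",
              a$n_persons, a$total_entries, 100 * a$mean_rate, a$sd_rate,
              100 * a$min_rate, 100 * a$max_rate))
  invisible(x)
}

#' Discretize unequally spaced prompts onto an hourly grid
#'
#' Implements the discrete time filter used to put unequally spaced
#' momentary observations on a common lag scale: grid cells are aligned to
#' the absolute clock lattice (multiples of `interval_minutes` counted from
#' midnight of day 1), each observation is assigned to its nearest cell,
#' and indices are shifted so the first completed observation sits at cell
#' 0. The grid runs through nights as runs of
#' empty cells, so overnight lags attenuate through missing steps rather
#' than wrapping across days. When two observations map to the same cell
#' the earlier one keeps it and the later one shifts to the next cell if
#' empty, otherwise it is dropped; every shift and drop is logged.
#'
#' @param data Long-format momentary tibble with `timestamp_minute`.
#' @param interval_minutes Grid interval, minutes (default 60: effects are
#'   interpreted per hour).
#' @param collision How to resolve two observations mapping to one cell:
#'   `"shift"` moves the later one to the next cell if empty (else drops
#'   it); `"drop"` always discards the later one. Both are logged.
#' @return A tibble of class `gridded_esm` with one row per grid cell per
#'   person (from each person's first to last observation): `person_id`,
#'   `cell`, `cell_minute`, `clock_hour`, `hour_c` (clock hour centered at
#'   the grand mean over occupied cells), `observed`, and one column per
#'   momentary variable (`NA` in empty cells). Attributes: `interval`,
#'   `variables`, `collisions` (log tibble), `hour_center`.
#' @export
build_time_grid <- function(data, interval_minutes = 60,
                            collision = c("shift", "drop")) {
  collision <- match.arg(collision)
  if (interval_minutes <= 0) abort("`interval_minutes` must be positive.")
  vars <- attr(data, "variables")
  if (is.null(vars)) {
    vars <- setdiff(names(data), c("person_id", "day", "prompt_index",
                                   "scheduled_minute", "timestamp_minute"))
    vars <- vars[vapply(data[vars], is.numeric, logical(1))]
    vars <- vars[!grepl("_item[0-9]+$", vars)]
  }
  if (nrow(data) == 0) {
    out <- tibble::tibble(person_id = integer(), cell = integer(),
                          cell_minute = numeric(), clock_hour = numeric(),
                          hour_c = numeric(), observed = logical())
    for (v in vars) out[[v]] <- numeric()
    return(structure(out, interval = interval_minutes, variables = vars,
                     collisions = tibble::tibble(), hour_center = NA_real_,
                     class = c("gridded_esm", class(out))))
  }
  data <- dplyr::arrange(data, .data$person_id, .data$timestamp_minute)
  pieces <- vector("list", 0)
  collisions <- vector("list", 0)
  for (pid in unique(data$person_id)) {
    d_i <- data[data$person_id == pid, ]
    if (anyDuplicated(d_i$timestamp_minute)) {
      abort(sprintf("Person %s has duplicated timestamps; fix the input data.", pid))
    }
    origin_cell <- round(d_i$timestamp_minute[1] / interval_minutes)
    origin <- origin_cell * interval_minutes
    cell <- as.integer(round(d_i$timestamp_minute / interval_minutes) - origin_cell)
    assigned <- rep(NA_integer_, length(cell))
    taken <- integer(0)
    for (j in seq_along(cell)) {
      c_j <- cell[j]
      if (!(c_j %in% taken)) {
        assigned[j] <- c_j
      } else if (collision == "shift" && !((c_j + 1L) %in% taken)) {
        assigned[j] <- c_j + 1L
        collisions[[length(collisions) + 1L]] <- tibble::tibble(
          person_id = pid, timestamp_minute = d_i$timestamp_minute[j],
          cell = c_j, action = "shifted", new_cell = c_j + 1L)
      } else {
        collisions[[length(collisions) + 1L]] <- tibble::tibble(
          person_id = pid, timestamp_minute = d_i$timestamp_minute[j],
          cell = c_j, action = "dropped", new_cell = NA_integer_)
      }
      if (!is.na(assigned[j])) taken <- c(taken, assigned[j])
    }
    keep <- !is.na(assigned)
    n_cells <- max(assigned[keep]) + 1L
    grid <- tibble::tibble(person_id = pid, cell = 0:(n_cells - 1L))
    grid$cell_minute <- origin + grid$cell * interval_minutes
    grid$clock_hour <- (grid$cell_minute %% 1440) / 60
    grid$observed <- grid$cell %in% assigned[keep]
    for (v in vars) {
      col <- rep(NA_real_, n_cells)
      col[assigned[keep] + 1L] <- d_i[[v]][keep]
      grid[[v]] <- col
    }
    pieces[[length(pieces) + 1L]] <- grid
  }
  out <- dplyr::bind_rows(pieces)
  hour_center <- mean(out$clock_hour[out$observed])
  out$hour_c <- out$clock_hour - hour_center
  out <- out[, c("person_id", "cell", "cell_minute", "clock_hour", "hour_c",
                 "observed", vars)]
  structure(out, interval = interval_minutes, variables = vars,
            collisions = dplyr::bind_rows(collisions), hour_center = hour_center,
            class = c("gridded_esm", class(out)))
}

#' Count usable lag-1 transitions on the grid
#'
#' A transition is usable when two consecutive grid cells are both occupied;
#' these are the pairs that inform the autoregressive and cross-lagged
#' coefficients directly (imputation recovers information from longer gaps,
#' at a precision cost).
#'
#' @param grid A [build_time_grid()] result.
#' @return A tibble `person_id`, `n_pairs`, plus attribute `total`.
#' @export
lag_pairs <- function(grid) {
  out <- grid |>
    dplyr::group_by(.data$person_id) |>
    dplyr::arrange(.data$cell, .by_group = TRUE) |>
    dplyr::summarise(n_pairs = sum(diff(.data$cell[.data$observed]) == 1L),
                     .groups = "drop")
  attr(out, "total") <- sum(out$n_pairs)
  out
}
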