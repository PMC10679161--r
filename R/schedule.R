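#' Generate a signal-contingent prompt schedule
#'
#' Draws pseudo-randomized prompt times for every person-day: the waking
#' window is partitioned into `prompts_per_day` equal-width blocks and one
#' time is drawn uniformly inside each block, with whole-day rejection until
#' all consecutive gaps meet the minimum spacing. This reproduces the
#' blocked signal-contingent design of smartphone ESM studies (ten prompts a
#' day within thirteen waking hours, at least fifteen minutes apart).
#'
#' @param n_persons Number of persons.
#' @param n_days Number of consecutive sampling days.
#' @param prompts_per_day Prompts per day.
#' @param waking_minutes Length of the daily sampling window, minutes.
#' @param min_gap Minimum spacing between consecutive prompts, minutes.
#' @param expiry_minutes Response window per prompt, minutes (metadata only;
#'   response latency is not simulated).
#' @param wake_start_hour Clock hour at which the waking window opens; fixes
#'   the mapping from within-day minutes to absolute study time.
#' @param seed Integer seed; identical seeds give identical schedules.
#'
#' @return A tibble with one row per prompt: `person_id`, `day`,
#'   `prompt_index`, `scheduled_minute` (minutes since that day's window
#'   opened), `abs_minute` (minutes since midnight before day 1) and
#'   `clock_hour`. Design constants are attached as attributes
#'   (`waking_minutes`, `min_gap`, `expiry_minutes`, `prompts_per_day`,
#'   `n_days`, `wake_start_hour`).
#' @examples
#' sch <- generate_schedule(n_persons = 2, seed = 1)
#' nrow(sch)  # 2 persons x 6 days x 10 prompts
#' @export
generate_schedule <- function(n_persons,
                              n_days = 6,
                              prompts_per_day = 10,
                              waking_minutes = 780,
                              min_gap = 15,
                              expiry_minutes = 15,
                              wake_start_hour = 9,
                              seed = NULL) {
  if (n_persons < 1) abort("`n_persons` must be at least 1.")
  block <- waking_minutes / prompts_per_day
  if (prompts_per_day * min_gap >= waking_minutes) {
    abort(paste0("Infeasible schedule: ", prompts_per_day, " prompts with a ",
                 min_gap, "-minute minimum gap do not fit a ",
                 waking_minutes, "-minute waking window."))
  }
  with_seed(seed, {
    rows <- vector("list", n_persons * n_days)
    idx <- 0L
    for (p in seq_len(n_persons)) {
      for (d in seq_len(n_days)) {
        repeat {
          t <- sort((seq_len(prompts_per_day) - 1) * block +
                      runif(prompts_per_day, 0, block))
          if (prompts_per_day == 1L || all(diff(t) >= min_gap)) break
        }
        idx <- idx + 1L
        rows[[idx]] <- tibble::tibble(
          person_id = p, day = d, prompt_index = seq_len(prompts_per_day),
          scheduled_minute = t
        )
      }
    }
    out <- dplyr::bind_rows(rows)
    out$abs_minute <- (out$day - 1) * 1440 + wake_start_hour * 60 + out$scheduled_minute
    out$clock_hour <- (out$abs_minute %% 1440) / 60
    attr(out, "waking_minutes") <- waking_minutes
    attr(out, "min_gap") <- min_gap
    attr(out, "expiry_minutes") <- expiry_minutes
    attr(out, "prompts_per_day") <- prompts_per_day
    attr(out, "n_days") <- n_days
    attr(out, "wake_start_hour") <- wake_start_hour
    out
  })
}
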