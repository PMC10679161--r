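make_records <- function(completed_per_person, scheduled = 60) {
  rows <- purrr::imap_dfr(completed_per_person, function(m, i) {
    if (m == 0) return(NULL)
    tibble::tibble(person_id = as.integer(i), day = 1L,
                   prompt_index = seq_len(m),
                   scheduled_minute = (seq_len(m) - 1) * 80,
                   timestamp_minute = 540 + (seq_len(m) - 1) * 80,
                   social_anxiety = 2, paranoia = 2)
  })
  attr(rows, "scheduled_per_person") <- scheduled
  attr(rows, "variables") <- c("social_anxiety", "paranoia")
  rows
}

test_that("one-third exclusion keeps the boundary case", {
  rec <- make_records(c(19, 20, 60, 0))
  out <- suppressMessages(exclusion_filter(rec))
  rep <- attr(out, "exclusion_report")
  expect_setequal(unique(out$person_id), c(2L, 3L))
  expect_equal(rep$excluded, c(TRUE, FALSE, FALSE))  # person 4 has no rows
  expect_equal(rep$completed[rep$person_id == 1], 19)
  # full compliance: output identical, nothing flagged
  full <- make_records(c(60, 60))
  kept <- exclusion_filter(full)
  expect_equal(nrow(kept), nrow(full))
  expect_false(any(attr(kept, "exclusion_report")$excluded))
  # unknown schedule size is an explicit error
  norm <- make_records(c(30))
  attr(norm, "scheduled_per_person") <- NULL
  expect_error(exclusion_filter(norm), "Scheduled prompt count")
})

test_that("completion statistics reproduce the design arithmetic", {
  # 134 persons totalling 5,800 completed of 60 scheduled -> 72.1% to 1 dp
  completed <- rep(5800 %/% 134, 134)
  completed[seq_len(5800 - sum(completed))] <-
    completed[seq_len(5800 - sum(completed))] + 1
  rec <- make_records(completed)
  cs <- completion_stats(rec)
  agg <- glance(cs)
  expect_equal(agg$total_entries, 5800)
  expect_equal(round(100 * agg$total_entries / (134 * 60), 1), 72.1)
  # single fully compliant person
  one <- completion_stats(make_records(c(60)))
  expect_equal(one$person$rate, 1)
  expect_equal(glance(one)$total_entries, 60)
})

test_that("per-person rates match an independent row count", {
  p <- esm_true_params()
  study <- simulate_esm_study(p, n_persons = 25, seed = 13)
  cs <- completion_stats(study$records)
  brute <- table(factor(study$records$person_id, levels = cs$person$person_id))
  expect_equal(cs$person$completed, as.integer(brute))
  expect_equal(cs$person$rate, as.integer(brute) / 60)
})

test_that("grid assignment follows the nearest-cell rule with logged collisions", {
  rec <- tibble::tibble(person_id = 1L, day = 1L, prompt_index = 1:2,
                        scheduled_minute = c(0, 80),
                        timestamp_minute = c(0, 80), x = c(1, 2))
  attr(rec, "variables") <- "x"
  g <- build_time_grid(rec)
  expect_equal(g$cell[g$observed], c(0L, 1L))
  # 0 and 30 collide in cell 0; the later one shifts to cell 1
  rec2 <- tibble::tibble(person_id = 1L, day = 1L, prompt_index = 1:2,
                         scheduled_minute = c(0, 30),
                         timestamp_minute = c(0, 30), x = c(1, 2))
  attr(rec2, "variables") <- "x"
  g2 <- build_time_grid(rec2)
  expect_equal(g2$cell[g2$observed], c(0L, 1L))
  log2 <- attr(g2, "collisions")
  expect_equal(nrow(log2), 1)
  expect_equal(log2$action, "shifted")
  # drop policy discards instead
  g3 <- build_time_grid(rec2, collision = "drop")
  expect_equal(sum(g3$observed), 1)
  expect_equal(attr(g3, "collisions")$action, "dropped")
  # empty input
  empty <- rec[0, ]
  attr(empty, "variables") <- "x"
  expect_equal(nrow(build_time_grid(empty)), 0)
  # duplicated timestamps are an upstream fault
  dup <- rec
  dup$timestamp_minute <- c(10, 10)
  expect_error(build_time_grid(dup), "duplicated")
})

test_that("gridding conserves observations and preserves order", {
  p <- esm_true_params()
  study <- simulate_esm_study(p, n_persons = 15, seed = 44)
  g <- build_time_grid(study$records)
  log <- attr(g, "collisions")
  dropped <- sum(log$action == "dropped")
  expect_equal(sum(g$observed) + dropped, nrow(study$records))
  ord <- g |>
    dplyr::filter(observed) |>
    dplyr::group_by(person_id) |>
    dplyr::summarise(ok = !is.unsorted(cell), .groups = "drop")
  expect_true(all(ord$ok))
})

test_that("gridding is idempotent and lossless on hourly data", {
  p <- tiny_params_k2()
  sch <- hourly_schedule(4, per_day = 13, days = 3)
  eff <- draw_person_effects(p, 4, seed = 1)
  rec <- simulate_series(sch, eff, p, seed = 2)
  g <- build_time_grid(rec)
  expect_equal(nrow(attr(g, "collisions")), 0)   # lossless
  # regrid the occupied cells: identical cells and values
  occ <- g[g$observed, ]
  rec2 <- tibble::tibble(person_id = occ$person_id,
                         timestamp_minute = occ$cell_minute,
                         social_anxiety = occ$social_anxiety,
                         paranoia = occ$paranoia)
  attr(rec2, "variables") <- c("social_anxiety", "paranoia")
  g2 <- build_time_grid(rec2)
  expect_equal(g2$cell[g2$observed], occ$cell)
  expect_equal(g2$social_anxiety[g2$observed], occ$social_anxiety)
})

test_that("lag-pair counts match a brute-force adjacency scan", {
  g <- tibble::tibble(person_id = rep(1:2, c(10, 4)),
                      cell = c(0:9, c(0L, 1L, 3L, 5L)),
                      observed = TRUE)
  lp <- lag_pairs(g)
  expect_equal(lp$n_pairs[lp$person_id == 1], 9)
  expect_equal(lp$n_pairs[lp$person_id == 2], 1)
  p <- esm_true_params()
  study <- simulate_esm_study(p, n_persons = 12, seed = 3)
  grid <- build_time_grid(study$records)
  lp2 <- lag_pairs(grid)
  brute <- vapply(lp2$person_id, function(pid) {
    cells <- sort(grid$cell[grid$person_id == pid & grid$observed])
    sum(diff(cells) == 1)
  }, numeric(1))
  expect_equal(lp2$n_pairs, as.integer(brute))
})
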