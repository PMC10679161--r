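#' Sample descriptives table
#'
#' Joins the momentary data with a per-person baseline table and summarizes
#' the baseline covariates the way sample-characteristics tables are
#' reported: counts and percentages for categorical columns, mean and SD
#' for numeric ones, with the analyzed N in the header row.
#'
#' @param data Long-format momentary tibble (defines the analyzed persons).
#' @param baseline Per-person tibble with `person_id` and covariate
#'   columns.
#' @param covariates Columns of `baseline` to describe (default: all except
#'   `person_id`).
#' @return A tibble: `covariate`, `level`, `n`, `percent`, `mean`, `sd`.
#' @export
describe_sample <- function(data, baseline, covariates = NULL) {
  ids <- unique(data$person_id)
  orphans <- setdiff(ids, baseline$person_id)
  if (length(orphans)) {
    abort(paste0("Persons in the momentary data missing from `baseline`: ",
                 paste(head(orphans, 10), collapse = ", ")))
  }
  b <- baseline[baseline$person_id %in% ids, ]
  covariates <- covariates %||% setdiff(names(b), "person_id")
  rows <- list(tibble::tibble(covariate = "N", level = NA_character_,
                              n = nrow(b), percent = 100,
                              mean = NA_real_, sd = NA_real_))
  for (cv in covariates) {
    x <- b[[cv]]
    binary <- is.numeric(x) && all(x %in% c(0, 1))
    if (is.numeric(x) && !binary) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        covariate = cv, level = NA_character_, n = NA_integer_,
        percent = NA_real_, mean = mean(x), sd = sd(x))
    } else {
      tb <- table(x)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        covariate = cv, level = names(tb), n = as.integer(tb),
        percent = 100 * as.integer(tb) / nrow(b),
        mean = NA_real_, sd = NA_real_)
    }
  }
  dplyr::bind_rows(rows)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the complete workflow: simulate a synthetic study (or read
#' long-format CSVs), apply the completion-based exclusion rule, compute
#' compliance descriptives, discretize onto the hourly grid, fit the
#' bivariate and trivariate models, post-process into effect,
#' R-squared and correlation tables with convergence reports, and write
#' everything (CSV/JSON) plus a manifest with content hashes. Identical
#' config and seed give identical manifests; stage seeds are derived
#' deterministically from the master seed.
#'
#' @param config A named list, or path to a YAML file, with (all optional)
#'   `n_persons`, `n_days`, `prompts_per_day`, `min_fraction`,
#'   `interval_minutes`, `profile` ("smoke"/"full"), `models` (subset of
#'   `"model1"`, `"model2"`), `moderation` (logical), `seed`, `out_dir`,
#'   `input_csv` + `baseline_csv` to analyze existing data instead of
#'   simulating.
#' @return The run manifest (a list): artifact paths with MD5 hashes,
#'   seeds, and a short summary. Written artifacts include Table-1-style
#'   descriptives, effect tables for both models, the schema-correlation
#'   table and convergence reports.
#' @export
run_dsem_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cf <- utils::modifyList(list(
    n_persons = 134, n_days = 6, prompts_per_day = 10,
    min_fraction = 1 / 3, interval_minutes = 60,
    profile = "smoke", models = c("model1", "model2"),
    moderation = FALSE, seed = 1, out_dir = tempfile("dsem_run_"),
    input_csv = NULL, baseline_csv = NULL), config)
  if (is.null(cf$seed)) abort("`seed` is mandatory for reproducible runs.")
  dir.create(cf$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  write_tab <- function(x, name) {
    p_csv <- file.path(cf$out_dir, paste0(name, ".csv"))
    utils::write.csv(tibble::as_tibble(x), p_csv, row.names = FALSE)
    artifacts[[name]] <<- p_csv
  }

  # stage 1: data
  if (!is.null(cf$input_csv)) {
    records <- tibble::as_tibble(utils::read.csv(cf$input_csv))
    persons <- tibble::as_tibble(utils::read.csv(cf$baseline_csv %||%
      abort("`baseline_csv` required with `input_csv`.")))
    attr(records, "scheduled_per_person") <- cf$prompts_per_day * cf$n_days
  } else {
    study <- simulate_esm_study(esm_true_params(), n_persons = cf$n_persons,
                                n_days = cf$n_days,
                                prompts_per_day = cf$prompts_per_day,
                                seed = derive_seed(cf$seed, 1))
    records <- study$records
    persons <- study$persons
    write_tab(persons, "true_person_effects")
  }
  if (dplyr::n_distinct(records$person_id) < 10) {
    warn("Small sample: fewer than 10 persons; between-person estimates will be unstable.")
  }
  write_tab(records, "records")

  # stage 2: exclusion + compliance
  analyzed <- exclusion_filter(records, min_fraction = cf$min_fraction)
  write_tab(attr(analyzed, "exclusion_report"), "exclusion_report")
  stats <- completion_stats(analyzed)
  write_tab(glance(stats), "completion_aggregate")
  desc <- describe_sample(analyzed, persons,
                          covariates = intersect(c("neg_self", "neg_other", "gender"),
                                                 names(persons)))
  write_tab(desc, "sample_descriptives")

  # stage 3: grid
  grid <- build_time_grid(analyzed, interval_minutes = cf$interval_minutes)

  # stage 4-5: fit + post-process
  vars3 <- attr(grid, "variables")
  model_defs <- list(
    model1 = list(vars = vars3[1:2], schemas = NULL),
    model2 = list(vars = vars3, schemas = intersect(c("neg_self", "neg_other"),
                                                    names(persons))))
  for (m in cf$models) {
    md <- model_defs[[m]]
    schemas <- if (length(md$schemas) == 2) md$schemas else NULL
    spec <- dsem_model(md$vars, schema_covariates = schemas,
                       gender = if (isTRUE(cf$moderation)) "gender" else NULL,
                       profile = cf$profile)
    fit <- dsem_fit(grid, spec, persons = persons,
                    seed = derive_seed(cf$seed, match(m, c("model1", "model2")) + 1))
    write_tab(standardize_within(fit), paste0(m, "_effects"))
    write_tab(within_r2(fit), paste0(m, "_r2"))
    write_tab(tibble::as_tibble(convergence(fit)), paste0(m, "_convergence"))
    if (!is.null(schemas)) write_tab(between_correlations(fit), paste0(m, "_correlations"))
    if (isTRUE(cf$moderation)) write_tab(gender_moderation(fit), paste0(m, "_moderation"))
  }

  hashes <- vapply(artifacts, function(p) unname(tools::md5sum(p)), "")
  manifest <- list(config = cf[setdiff(names(cf), "out_dir")],
                   seed = cf$seed,
                   artifacts = lapply(names(artifacts), function(nm) {
                     list(name = nm, path = artifacts[[nm]], md5 = unname(hashes[[nm]]))
                   }),
                   summary = list(
                     n_persons_analyzed = glance(stats)$n_persons,
                     total_entries = glance(stats)$total_entries,
                     mean_completion = glance(stats)$mean_rate))
  jsonlite::write_json(manifest, file.path(cf$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
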