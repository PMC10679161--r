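#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted two-level VAR(1)
#'
#' @param x A [dsem_fit()] object.
#' @param effects Which summary to return: `"standardized"` (the main
#'   effect table), `"fixed"` (unstandardized fixed effects),
#'   `"correlations"` (schema correlations), or `"gender"` (moderation).
#' @param conf.level Credible level.
#' @param ... Unused.
#' @return A tibble; see the corresponding summarizer.
#' @method tidy dsem_fit
#' @export
tidy.dsem_fit <- function(x, effects = c("standardized", "fixed",
                                         "correlations", "gender"),
                          conf.level = 0.95, ...) {
  effects <- match.arg(effects)
  switch(effects,
    standardized = standardize_within(x, conf.level),
    fixed = {
      eta <- draws_matrix(x, "eta_bar")
      colnames(eta) <- x$effect_names
      tab <- credible_intervals(eta, conf.level)
      tab$label <- vapply(tab$term, effect_label, "", variables = x$variables)
      tab$type <- effect_type(tab$term)
      tab[, c("term", "label", "type", "estimate", "lower", "upper", "significant")]
    },
    correlations = between_correlations(x, conf.level),
    gender = gender_moderation(x, conf.level))
}

#' One-row summary of a fitted model
#'
#' @param x A [dsem_fit()] object.
#' @param ... Unused.
#' @return A one-row tibble with design and sampler sizes.
#' @method glance dsem_fit
#' @export
glance.dsem_fit <- function(x, ...) {
  tibble::tibble(
    n_persons = x$n_persons, n_obs = x$n_obs,
    k = length(x$variables),
    n_random_effects = if (x$spec$random_effects) x$spec$n_random_effects else 0L,
    chains = x$spec$chains, iterations = x$spec$iterations,
    thin = x$spec$thin, retained_draws = x$n_kept * x$spec$chains)
}

#' @method tidy completion_stats
#' @export
tidy.completion_stats <- function(x, ...) x$person

#' @method glance completion_stats
#' @export
glance.completion_stats <- function(x, ...) x$aggregate

#' Forest plot of an effect table
#'
#' @param object A `dsem_effects` tibble (from [standardize_within()],
#'   [between_correlations()] or [gender_moderation()]).
#' @param ... Unused.
#' @return A ggplot object: estimates with credible intervals, significant
#'   effects filled.
#' @method autoplot dsem_effects
#' @export
autoplot.dsem_effects <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- factor(df$label, levels = rev(unique(df$label)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lower, xmax = .data$upper),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(fill = .data$significant),
                        shape = 21, size = 2.4) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black", `FALSE` = "white")) +
    ggplot2::labs(x = "Estimate (95% CrI)", y = NULL, fill = "CrI excludes 0") +
    ggplot2::theme_minimal()
}

#' Forest plot of standardized effects for a fitted model
#'
#' @param object A [dsem_fit()] object.
#' @param ... Passed on.
#' @method autoplot dsem_fit
#' @export
autoplot.dsem_fit <- function(object, ...) {
  autoplot(standardize_within(object), ...)
}

#' Completion-rate histogram
#'
#' @param object A [completion_stats()] object.
#' @param ... Unused.
#' @method autoplot completion_stats
#' @export
autoplot.completion_stats <- function(object, ...) {
  ggplot2::ggplot(object$person, ggplot2::aes(x = .data$rate)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey40", colour = "white") +
    ggplot2::geom_vline(xintercept = object$aggregate$mean_rate,
                        linetype = 2, colour = "red") +
    ggplot2::labs(x = "Completion rate", y = "Persons") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
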