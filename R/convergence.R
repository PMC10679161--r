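#' Convergence diagnostics for a fitted model
#'
#' Computes the split-chain potential scale reduction factor (PSR) and an
#' effective sample size per scalar parameter. Each retained chain is split
#' in half; PSR is the classical between/within variance ratio
#' \eqn{\sqrt{((N-1)/N \, W + B/N) / W}} over the resulting half-chains.
#' ESS uses Geyer's initial positive sequence truncation of the
#' autocorrelation sum on each chain.
#'
#' @param fit A [dsem_fit()] object (needs at least 2 chains).
#' @param threshold PSR above which a parameter is flagged (default 1.1).
#' @return A tibble of class `dsem_convergence`: `parameter`, `psr`, `ess`,
#'   `flagged`; attributes `worst_psr` and `pass`.
#' @export
convergence <- function(fit, threshold = 1.1) {
  stopifnot(inherits(fit, "dsem_fit"))
  if (fit$spec$chains < 2) abort("Convergence diagnostics need at least 2 chains.")
  mats <- scalar_chain_draws(fit)
  res <- purrr::map_dfr(names(mats), function(nm) {
    chains <- mats[[nm]]  # list of per-chain vectors
    tibble::tibble(parameter = nm,
                   psr = split_psr(chains),
                   ess = sum(vapply(chains, ess_geyer, numeric(1))))
  })
  res$flagged <- res$psr > threshold
  structure(res, worst_psr = max(res$psr), pass = !any(res$flagged),
            threshold = threshold,
            class = c("dsem_convergence", class(res)))
}

# Named list: parameter -> list of per-chain draw vectors. Covers fixed
# effects, hour slopes, the within residual covariance, and (with random
# effects) the between-covariance diagonal.
scalar_chain_draws <- function(fit) {
  vars <- fit$variables
  k <- length(vars)
  en <- fit$effect_names
  out <- list()
  eta <- chain_array(fit, "eta_bar")
  for (j in seq_along(en)) out[[en[j]]] <- lapply(eta, function(m) m[, j])
  if (fit$spec$include_hour_trend) {
    g <- chain_array(fit, "gamma")
    for (j in seq_len(k)) out[[paste0("gamma_", vars[j])]] <- lapply(g, function(m) m[, j])
  }
  s <- chain_array(fit, "sigma_w")
  for (a in seq_len(k)) for (b in a:k) {
    out[[paste0("sigma_w[", vars[a], ",", vars[b], "]")]] <-
      lapply(s, function(m) m[, (b - 1) * k + a])
  }
  if (fit$spec$random_effects) {
    om <- chain_array(fit, "omega")
    d <- as.integer(sqrt(ncol(om[[1]])))
    for (j in seq_along(en)) {
      out[[paste0("omega[", en[j], "]")]] <- lapply(om, function(m) m[, (j - 1) * d + j])
    }
  }
  out
}

# Split-chain PSR on a list of equal-length chains.
split_psr <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    h <- length(x) %/% 2
    list(x[seq_len(h)], x[(h + 1):(2 * h)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  w <- mean(vars)
  b <- n * var(means)
  if (w <= .Machine$double.eps) return(if (b <= .Machine$double.eps) 1 else Inf)
  max(1, sqrt(((n - 1) / n * w + b / n) / w))
}

# Effective sample size of one chain (initial positive sequence estimator).
ess_geyer <- function(x) {
  n <- length(x)
  if (var(x) <= .Machine$double.eps) return(n)
  acf_x <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq(1, length(acf_x) - 1, by = 2)) {
    pair <- acf_x[k] + acf_x[k + 1]
    if (is.na(pair) || pair <= 0) break
    s <- s + pair
  }
  n / (1 + 2 * s)
}

#' @export
print.dsem_convergence <- function(x, ...) {
  cat(sprintf("<dsem_convergence> %d parameters; worst PSR %.3f (threshold %.2f): %s\n",
              nrow(x), attr(x, "worst_psr"), attr(x, "threshold"),
              if (attr(x, "pass")) "pass" else
                paste0(sum(x$flagged), " flagged")))
  NextMethod()
}
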