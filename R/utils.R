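#' @importFrom rlang abort warn .data
#' @importFrom stats median quantile rnorm rbeta runif sd var setNames
#' @importFrom utils head tail
NULL

# Run code with a private RNG stream, restoring the caller's state afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

# Deterministic child seeds: stage k of a run with master seed s.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) + 1009 * as.double(k)) %% 2147483646L) + 1L
}

#' Stationary covariance of a VAR(1)
#'
#' Solves the discrete Lyapunov equation \eqn{V = \Phi V \Phi' + \Sigma} for
#' the steady-state covariance of a stationary first-order vector
#' autoregression, using the vectorized (Kronecker) form. This is the
#' covariance used for within-person standardization and for the
#' within-person R-squared.
#'
#' @param phi Lag-1 coefficient matrix (row = outcome, column = predictor),
#'   or a scalar for the univariate case.
#' @param sigma Innovation (residual) covariance matrix, or a scalar
#'   variance in the univariate case.
#' @return The stationary covariance matrix `V`.
#' @examples
#' stationary_cov(0.5, 0.75)  # = 0.75 / (1 - 0.25) = 1
#' @export
stationary_cov <- function(phi, sigma) {
  phi <- as.matrix(phi)
  sigma <- as.matrix(sigma)
  k <- nrow(phi)
  stopifnot(ncol(phi) == k, all(dim(sigma) == k))
  if (spectral_radius(phi) >= 1) {
    abort("`phi` is not stationary (spectral radius >= 1); no stationary covariance exists.")
  }
  v <- solve(diag(k * k) - kronecker(phi, phi), as.vector(sigma))
  v <- matrix(v, k, k)
  (v + t(v)) / 2
}

spectral_radius <- function(phi) {
  max(Mod(eigen(as.matrix(phi), only.values = TRUE)$values))
}

is_psd <- function(m, tol = 1e-8) {
  m <- as.matrix(m)
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-6))) return(FALSE)
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  all(ev > -tol * max(1, abs(ev[1])))
}

# One multivariate normal draw per row; mean n x d, sigma d x d.
rmvn <- function(n, mean, sigma) {
  d <- ncol(sigma)
  if (d == 0L) return(matrix(0, n, 0))
  ev <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
  rt <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  z <- matrix(rnorm(n * d), n, d)
  sweep(z %*% rt, 2, rep(0, d), "+") + mean
}

# Canonical ordering of the person-level random effects: K means followed by
# the K^2 lag coefficients in outcome-major order (row k of Phi = all
# predictors of outcome k). Used everywhere a stacked effect vector appears.
effect_names <- function(variables) {
  k <- length(variables)
  phis <- as.vector(t(outer(variables, variables,
                            function(out, pred) paste0("phi_", pred, "_to_", out))))
  c(paste0("mu_", variables), phis)
}

# Paper-style display label for an internal effect name.
effect_label <- function(term, variables) {
  ab <- abbreviate_vars(variables)
  lab <- term
  for (i in seq_along(variables)) {
    lab <- gsub(variables[i], ab[i], lab, fixed = TRUE)
  }
  lab <- sub("^mu_", "μ_", lab)
  lab <- sub("^phi_", "ϕ_", lab)
  gsub("_to_", "⟶", lab)
}

abbreviate_vars <- function(variables) {
  known <- c(social_anxiety = "SA", paranoia = "PAR", loneliness = "LONE")
  out <- ifelse(variables %in% names(known), known[variables],
                toupper(abbreviate(variables, 4)))
  unname(out)
}

effect_type <- function(term) {
  dplyr::case_when(
    grepl("^mu_", term) ~ "mean",
    grepl("^phi_(.+)_to_\\1$", term) ~ "autoregressive",
    TRUE ~ "cross-lagged"
  )
}
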