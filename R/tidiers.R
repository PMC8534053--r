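#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a population fit
#'
#' @param x A `kpd_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per model parameter: `parameter`,
#'   `estimate`, `estimated` (TRUE for parameters the fit optimized,
#'   FALSE for those held fixed).
#' @method tidy kpd_fit
#' @export
tidy.kpd_fit <- function(x, ...) {
  est <- unclass(x$estimates)
  tibble::tibble(
    parameter = names(est),
    estimate = unlist(est, use.names = FALSE),
    estimated = names(est) %in% x$estimated
  )
}

#' One-row fit summary
#'
#' @param x A `kpd_fit` object.
#' @param ... Unused.
#' @return A tibble: `minus2ll`, `aic`, `n_params`, `n_animals`, `n_obs`,
#'   `eps_shrinkage`, `converged`.
#' @export
glance.kpd_fit <- function(x, ...) {
  tibble::tibble(
    minus2ll = x$minus2ll, aic = x$aic, n_params = length(x$estimated),
    n_animals = x$n_animals, n_obs = x$n_obs,
    eps_shrinkage = if (nrow(x$iwres) > 1) eps_shrinkage(x) else NA_real_,
    converged = x$converged
  )
}

#' Tidy a bootstrap result
#'
#' @param x A `kpd_boot` object.
#' @param ... Unused.
#' @return The per-parameter percentile intervals tibble.
#' @method tidy kpd_boot
#' @export
tidy.kpd_boot <- function(x, ...) x$intervals
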