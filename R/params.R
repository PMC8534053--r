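#' Population parameters for the tumor-immune K-PD model
#'
#' Constructs and validates the full population parameter set of the
#' semi-mechanistic model: exponential tumor growth, the three K-PD drug-signal
#' chains (antigen, PIC, anti-PD1), the CD8-mediated kill, log-normal
#' inter-animal variability (IAV) and the additive residual error on log
#' tumor volume.
#'
#' The CD8 turnover rate constant `k_cd8` is structurally tied to the antigen
#' signal rate constant `k_ag` (they are not separately identifiable), so it is
#' never supplied: it is always set equal to `k_ag`. `resistance` is a
#' dimensionless constant describing tumor immune-evasion mechanisms (Tregs,
#' MDSCs, PD-1/PD-L1) which the anti-PD1 effect divides down; it is fixed at 1.
#'
#' @param ts0 Tumor volume at inoculation, mm^3.
#' @param lam Net tumor growth rate constant, day^-1.
#' @param k_ag Antigen signal rate constant, day^-1 (also used for CD8 turnover).
#' @param k_pic PIC (TLR-3 agonist) signal rate constant, day^-1.
#' @param k_apd1 Anti-PD1 signal rate constant, day^-1.
#' @param theta_cd8 CD8 kill efficiency, au^-1 day^-1.
#' @param theta_pic PIC effect slope, au^-1.
#' @param theta_apd1 Anti-PD1 effect slope, au^-1.
#' @param resistance Dimensionless resistance constant (fixed at 1 in the model).
#' @param sigma_log Residual SD on log(mm^3).
#' @param omega_lam,omega_theta_cd8,omega_k_pic,omega_k_apd1 SDs of the
#'   log-normal random effects on the four parameters carrying IAV.
#'
#' @return An object of class `kpd_params`: a named list with the fields above
#'   plus `k_cd8` (== `k_ag`).
#' @seealso [published_params()] for the packaged final estimates.
#' @export
#' @examples
#' p <- pop_params(ts0 = 19.5, lam = 0.194)
#' p$k_cd8 == p$k_ag
pop_params <- function(ts0 = 19.5, lam = 0.194, k_ag = 4.93,
                       k_pic = 0, k_apd1 = 0,
                       theta_cd8 = 0, theta_pic = 0, theta_apd1 = 0,
                       resistance = 1, sigma_log = 0.597,
                       omega_lam = 0, omega_theta_cd8 = 0,
                       omega_k_pic = 0, omega_k_apd1 = 0) {
  p <- list(
    ts0 = ts0, lam = lam, k_ag = k_ag, k_cd8 = k_ag,
    k_pic = k_pic, k_apd1 = k_apd1,
    theta_cd8 = theta_cd8, theta_pic = theta_pic, theta_apd1 = theta_apd1,
    resistance = resistance, sigma_log = sigma_log,
    omega_lam = omega_lam, omega_theta_cd8 = omega_theta_cd8,
    omega_k_pic = omega_k_pic, omega_k_apd1 = omega_k_apd1
  )
  class(p) <- "kpd_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "kpd_params"))
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("all parameters must be finite scalars; offending: ",
         paste(names(p)[!num], collapse = ", "), call. = FALSE)
  }
  if (p$ts0 <= 0) stop("ts0 must be > 0", call. = FALSE)
  rates <- c("lam", "k_ag", "k_cd8", "k_pic", "k_apd1",
             "theta_cd8", "theta_pic", "theta_apd1", "sigma_log",
             "omega_lam", "omega_theta_cd8", "omega_k_pic", "omega_k_apd1")
  neg <- vapply(rates, function(nm) p[[nm]] < 0, logical(1))
  if (any(neg)) {
    stop("rate constants, slopes, sigma and omegas must be >= 0; offending: ",
         paste(rates[neg], collapse = ", "), call. = FALSE)
  }
  if (p$k_cd8 != p$k_ag) stop("k_cd8 is structurally tied to k_ag", call. = FALSE)
  if (p$resistance <= 0) stop("resistance must be > 0", call. = FALSE)
  invisible(p)
}

#' @export
print.kpd_params <- function(x, ...) {
  cat("<kpd_params>\n")
  df <- tibble::tibble(parameter = names(x),
                       value = unlist(x, use.names = FALSE))
  print(df, n = nrow(df))
  invisible(x)
}

#' Published final population estimates
#'
#' Loads the packaged final parameter estimates of the combination-therapy
#' model (fixed effects, IAV standard deviations, residual SD) from the
#' flat YAML configuration shipped with the package, together with the 90%
#' bootstrap confidence intervals for the two K-PD rate constants used by the
#' grid-exploration study.
#'
#' @param ci Logical; if `TRUE`, return a list with elements `params`
#'   (a [pop_params()] object) and `ci` (a tibble with columns `parameter`,
#'   `lower`, `upper` of 90% bootstrap intervals). If `FALSE` (default),
#'   return just the `kpd_params` object.
#' @return A `kpd_params` object, or a list (see `ci`).
#' @export
#' @examples
#' published_params()$lam
published_params <- function(ci = FALSE) {
  path <- system.file("extdata", "published_params.yaml", package = "immunokpd",
                      mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  p <- do.call(pop_params, cfg$params)
  if (!ci) return(p)
  ci_tbl <- dplyr::bind_rows(lapply(names(cfg$ci90), function(nm) {
    tibble::tibble(parameter = nm,
                   lower = cfg$ci90[[nm]][[1]], upper = cfg$ci90[[nm]][[2]])
  }))
  list(params = p, ci = ci_tbl)
}

# parameters that carry a log-normal random effect, and their omega fields
iav_map <- c(lam = "omega_lam", theta_cd8 = "omega_theta_cd8",
             k_pic = "omega_k_pic", k_apd1 = "omega_k_apd1")

#' Draw individual-level parameters
#'
#' Samples per-animal parameter sets from the population distribution.
#' IAV is exponential (log-normal): for each parameter `p` with a nonzero
#' `omega`, the individual value is `p_pop * exp(eta)` with
#' `eta ~ Normal(0, omega^2)`. Parameters without IAV (`ts0`, `k_ag`,
#' `theta_pic`, `theta_apd1`, ...) are returned unchanged, so the population
#' value is the individual-level median.
#'
#' @param pop A [pop_params()] object.
#' @param n Number of animals to draw.
#' @param seed Optional integer seed (local to this call).
#' @return A tibble with `n` rows: column `animal` plus one column per model
#'   parameter (individual values) and the sampled `eta_*` deviates.
#' @export
#' @examples
#' draw_individuals(published_params(), 3, seed = 1)
draw_individuals <- function(pop, n, seed = NULL) {
  validate_params(pop)
  stopifnot(n >= 1)
  if (!is.null(seed)) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
  }
  out <- tibble::tibble(animal = seq_len(n))
  for (nm in setdiff(names(pop), names(iav_map))) out[[nm]] <- pop[[nm]]
  for (nm in names(iav_map)) {
    omega <- pop[[iav_map[[nm]]]]
    eta <- if (omega > 0) stats::rnorm(n, 0, omega) else rep(0, n)
    out[[paste0("eta_", nm)]] <- eta
    out[[nm]] <- pop[[nm]] * exp(eta)
  }
  out
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# local-seed helper used by every stochastic entry point
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  expr
}
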