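#' PIC drug-effect term
#'
#' Inhibitory linear effect of the PIC (TLR-3 agonist) transit signal on the
#' APC/CD8 turnover rate: `E_PIC = 1 / (1 + theta_pic * tr_pic)`. With no
#' signal the effect is 1 (no modulation); larger signals slow APC elimination
#' and CD8 turnover, sustaining the activated-CD8 pool.
#'
#' @param tr_pic PIC transit signal, au (>= 0). Vectorized.
#' @param theta_pic PIC effect slope, au^-1 (>= 0).
#' @return Dimensionless multiplier in (0, 1], strictly decreasing in `tr_pic`.
#' @export
#' @examples
#' effect_pic(0.001, 1200) # 1 / 2.2
effect_pic <- function(tr_pic, theta_pic) {
  if (any(tr_pic < 0) || theta_pic < 0) {
    stop("effect_pic: tr_pic and theta_pic must be >= 0", call. = FALSE)
  }
  1 / (1 + theta_pic * tr_pic)
}

#' Anti-PD1 drug-effect term
#'
#' Stimulatory linear effect of the second anti-PD1 transit signal on tumor
#' resistance: `E_aPD1 = 1 + theta_apd1 * tr_apd1_2`. The model divides the
#' constant resistance term by this effect, so values above 1 relieve
#' CD8 exhaustion and enhance tumor kill.
#'
#' @param tr_apd1_2 Second anti-PD1 transit signal, au (>= 0). Vectorized.
#' @param theta_apd1 Anti-PD1 effect slope, au^-1 (>= 0).
#' @return Dimensionless multiplier >= 1, strictly increasing in `tr_apd1_2`.
#' @export
#' @examples
#' effect_apd1(0.01, 821) # 9.21
effect_apd1 <- function(tr_apd1_2, theta_apd1) {
  if (any(tr_apd1_2 < 0) || theta_apd1 < 0) {
    stop("effect_apd1: tr_apd1_2 and theta_apd1 must be >= 0", call. = FALSE)
  }
  1 + theta_apd1 * tr_apd1_2
}

# canonical state ordering of the 9-compartment system
state_names <- c("trt_ag", "trt_pic", "trt_apd1", "apc", "tr_pic",
                 "tr_apd1_1", "tr_apd1_2", "cd8_act", "ts")

#' System derivatives of the tumor-immune K-PD model
#'
#' Right-hand side of the nine-state ODE system: three drug depots decaying by
#' first-order kinetics, the antigen transit compartment (interpreted as the
#' APC signal), one PIC transit stage, two anti-PD1 transit stages in series,
#' the activated-CD8 pool, and tumor volume.
#'
#' The PIC effect multiplies the APC elimination term and both CD8 turnover
#' terms; the anti-PD1 effect (driven by the second transit signal) divides the
#' resistance constant, reducing CD8 exhaustion and amplifying the kill term.
#' With all drug signals at zero the system reduces to exponential growth
#' `dts/dt = lam * ts`.
#'
#' @param state Named numeric vector with elements `trt_ag`, `trt_pic`,
#'   `trt_apd1`, `apc`, `tr_pic`, `tr_apd1_1`, `tr_apd1_2`, `cd8_act`, `ts`,
#'   all >= 0 (`ts` > 0).
#' @param params A [pop_params()] object or a named list/one-row data frame of
#'   individual-level values with the same fields.
#' @return Named numeric vector of time derivatives, same order as `state`.
#' @export
#' @examples
#' s <- c(trt_ag = 1, trt_pic = 0, trt_apd1 = 0, apc = 0, tr_pic = 0,
#'        tr_apd1_1 = 0, tr_apd1_2 = 0, cd8_act = 0, ts = 19.5)
#' derivatives(s, published_params())["apc"] # k_ag * 1
derivatives <- function(state, params) {
  if (!all(state_names %in% names(state))) {
    stop("state must contain: ", paste(state_names, collapse = ", "),
         call. = FALSE)
  }
  if (any(state[state_names] < 0) || state[["ts"]] <= 0) {
    stop("state components must be >= 0 and ts > 0", call. = FALSE)
  }
  p <- as.list(params)
  d <- kpd_rhs(0, state[state_names], p)[[1]]
  stats::setNames(d, state_names)
}

# deSolve-style RHS; p is a plain list of individual parameter values.
# Kept branch-free and allocation-light: it is the hot path of every
# simulation in the package.
kpd_rhs <- function(t, y, p) {
  e_pic <- 1 / (1 + p$theta_pic * y[5L])
  e_apd1 <- 1 + p$theta_apd1 * y[7L]
  res <- p$resistance / e_apd1 # effective exhaustion/kill modifier
  list(c(
    -p$k_ag * y[1L],
    -p$k_pic * y[2L],
    -p$k_apd1 * y[3L],
    p$k_ag * y[1L] - p$k_ag * y[4L] * e_pic,
    p$k_pic * y[2L] - p$k_pic * y[5L],
    p$k_apd1 * y[3L] - p$k_apd1 * y[6L],
    p$k_apd1 * y[6L] - p$k_apd1 * y[7L],
    p$k_cd8 * y[4L] * e_pic - p$k_cd8 * y[8L] * e_pic * res,
    p$lam * y[9L] - p$theta_cd8 * y[8L] * y[9L] / res
  ))
}

#' Build a dose-event table
#'
#' Dose events are unitless boluses added to the matching drug depot at the
#' stated time; the K-PD signal is scale-free (microgram amounts are absorbed
#' by the effect slopes), so the default bolus is 1.
#'
#' @param compound Character vector, each one of `"Ag"`, `"PIC"`, `"aPD1"`.
#' @param time Days post-inoculation (>= 0).
#' @param signal Bolus size added to the depot (> 0), default 1.
#' @return A tibble with columns `compound`, `time`, `signal`.
#' @export
#' @examples
#' dose_events(c("Ag", "Ag"), c(7, 14))
dose_events <- function(compound = character(), time = numeric(), signal = 1) {
  ok <- compound %in% c("Ag", "PIC", "aPD1")
  if (!all(ok)) {
    stop("unknown compound: ", paste(unique(compound[!ok]), collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(compound = compound, time = time, signal = signal)
  if (nrow(out) > 0 && (any(out$time < 0) || any(out$signal <= 0))) {
    stop("dose times must be >= 0 and signals > 0", call. = FALSE)
  }
  out
}

depot_of <- c(Ag = "trt_ag", PIC = "trt_pic", aPD1 = "trt_apd1")

# parameter order expected by the compiled RHS (src/kpd_model.c)
kpd_parm_order <- c("lam", "k_ag", "k_cd8", "k_pic", "k_apd1",
                    "theta_cd8", "theta_pic", "theta_apd1", "resistance")

#' Simulate one animal's trajectory
#'
#' Numerically integrates the nine-state system for a single parameter set and
#' dosing schedule. The initial state is tumor volume `ts0` with every other
#' compartment at zero; each dose event adds its signal to the matching depot
#' at its time (doses at t = 0 are applied to the initial state; later doses
#' are hard integrator events). A stiff-capable solver with tight tolerances
#' is used because the rate constants span three orders of magnitude.
#'
#' @param params A [pop_params()] object or one row of [draw_individuals()]
#'   output (any named list with the model fields).
#' @param doses A [dose_events()] tibble (possibly empty).
#' @param times Sorted numeric vector of output times (days), starting at 0.
#' @param rtol,atol Relative/absolute solver tolerances.
#' @param compiled Use the compiled C right-hand side (default). The pure-R
#'   right-hand side ([derivatives()]) gives identical results and serves as
#'   its cross-check.
#' @return A tibble: column `time` plus the nine state variables, one row per
#'   requested time. Values are clamped at 0 to remove negative round-off.
#' @export
#' @useDynLib immunokpd
#' @examples
#' tr <- simulate_profile(published_params(), dose_events("Ag", 7), 0:21)
#' tr$ts[1] # 19.5
simulate_profile <- function(params, doses = dose_events(), times,
                             rtol = 1e-8, atol = 1e-10, compiled = TRUE) {
  p <- as.list(params)
  stopifnot(length(times) >= 1, !is.unsorted(times), times[1] >= 0)
  y0 <- stats::setNames(numeric(9L), state_names)
  y0["ts"] <- p$ts0

  ev <- NULL
  if (nrow(doses) > 0) {
    at_start <- doses$time <= times[1]
    for (i in which(at_start)) {
      v <- depot_of[[doses$compound[i]]]
      y0[v] <- y0[v] + doses$signal[i]
    }
    later <- doses[!at_start, , drop = FALSE]
    if (nrow(later) > 0) {
      ev <- data.frame(var = depot_of[later$compound], time = later$time,
                       value = later$signal, method = "add")
      ev <- ev[order(ev$time), , drop = FALSE]
    }
  }

  tt <- sort(unique(c(times, if (!is.null(ev)) ev$time)))
  sol <- if (compiled) {
    deSolve::lsoda(
      y = y0, times = tt, func = "kpd_derivs", parms = unlist(p[kpd_parm_order]),
      dllname = "immunokpd", initfunc = "kpd_initmod",
      rtol = rtol, atol = atol,
      events = if (!is.null(ev)) list(data = ev) else NULL
    )
  } else {
    deSolve::lsoda(
      y = y0, times = tt, func = kpd_rhs, parms = p,
      rtol = rtol, atol = atol,
      events = if (!is.null(ev)) list(data = ev) else NULL
    )
  }
  if (attr(sol, "istate")[1L] < 0) {
    stop("integration failed for parameter set (lam=", signif(p$lam, 3),
         ", theta_cd8=", signif(p$theta_cd8, 3), ")", call. = FALSE)
  }
  out <- tibble::as_tibble(as.data.frame(sol))
  out <- out[match(times, out$time), , drop = FALSE]
  out[state_names] <- lapply(out[state_names], function(x) pmax(x, 0))
  out
}

#' Closed-form transit-chain signal for a single unit bolus
#'
#' For an equal-rate chain (depot then `n_transit` transit stages, all at rate
#' `k`) loaded with a unit bolus at t = 0, the depot decays as `exp(-k t)` and
#' the n-th transit signal is the gamma-density-shaped
#' `(k t)^n exp(-k t) / n!`, peaking at `t = n / k`. Used as the independent
#' oracle for the numerically integrated drug-signal chains.
#'
#' @param k Rate constant, day^-1 (> 0).
#' @param t Time(s) since the bolus, days (>= 0). Vectorized.
#' @param n_transit Number of transit stages: 1 (antigen, PIC) or 2 (anti-PD1).
#' @return A tibble with columns `time`, `depot`, `transit`.
#' @export
#' @examples
#' closed_form_transit(0.721, c(0, 1 / 0.721), 1)
closed_form_transit <- function(k, t, n_transit) {
  stopifnot(k > 0, all(t >= 0))
  if (!n_transit %in% c(1L, 2L)) {
    stop("n_transit must be 1 or 2", call. = FALSE)
  }
  tibble::tibble(
    time = t,
    depot = exp(-k * t),
    transit = (k * t)^n_transit * exp(-k * t) / factorial(n_transit)
  )
}
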