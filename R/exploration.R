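#' Trapezoidal area under a trajectory
#'
#' @param times Sorted sampling times, days.
#' @param values Signal values at `times` (same length, >= 2 points).
#' @return The trapezoidal integral over the sampled window.
#' @export
#' @examples
#' auc_trajectory(c(0, 10), c(1, 1)) # 10
auc_trajectory <- function(times, values) {
  if (length(times) < 2 || length(times) != length(values)) {
    stop("need >= 2 (time, value) pairs of equal length", call. = FALSE)
  }
  if (is.unsorted(times)) stop("times must be sorted", call. = FALSE)
  sum(diff(times) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}

#' Resistance-inhibition time profile induced by anti-PD1
#'
#' Pointwise fractional reduction of the exhaustion/kill modifier:
#' `1 - resistance / E_aPD1(t)` with `E_aPD1` evaluated on the second
#' anti-PD1 transit signal. It is 0 with no drug and approaches (but never
#' reaches) 1 as the effect grows.
#'
#' @param trajectory A [simulate_profile()] tibble (needs `tr_apd1_2`).
#' @param params The parameter set used for the simulation.
#' @return A tibble with columns `time` and `inhibition`.
#' @export
resistance_inhibition_profile <- function(trajectory, params) {
  p <- as.list(params)
  e <- effect_apd1(trajectory$tr_apd1_2, p$theta_apd1)
  tibble::tibble(time = trajectory$time, inhibition = 1 - p$resistance / e)
}

#' Grid exploration of response rates against exposure metrics
#'
#' Reproduces the model-exploration study: the PIC and anti-PD1 K-PD rate
#' constants are varied over a grid of `n_per_param` values each inside their
#' 90% confidence intervals (log-spaced, since the intervals span orders of
#' magnitude) while every other parameter stays at its final estimate. For
#' each of the `n_per_param^2` combinations and each antigen-containing arm
#' plus the triple therapy, `n_sim` animals are simulated with inter-animal
#' and residual variability and classified; the CD8 and resistance-inhibition
#' exposure metrics (`auc_cd8`, `auc_resistance_inhibition`) are computed from
#' the typical (no-random-effect, noise-free) trajectory over the follow-up
#' window.
#'
#' @param pop A [pop_params()] object (final estimates).
#' @param ci Tibble with columns `parameter` (`"k_pic"`, `"k_apd1"`),
#'   `lower`, `upper`: the 90% CIs to span (see [published_params()]).
#' @param design A `study_design`; defaults to [default_design()].
#' @param arms Arms to explore (default: the antigen-containing arms and the
#'   triple therapy).
#' @param n_per_param Grid points per parameter (10 reproduces the published
#'   100-combination exercise).
#' @param n_sim Simulated animals per combination and arm (1000 reproduces
#'   the published exercise).
#' @param seed Integer seed. Records are keyed by combination, so the output
#'   is order-independent and reproducible.
#' @param auc_dt Time step (days) of the dense grid used for the trapezoidal
#'   AUCs.
#' @return A tibble with one row per combination x arm: `k_pic`, `k_apd1`,
#'   `arm`, `auc_cd8`, `auc_resistance_inhibition`, `pct_responder`,
#'   `pct_partial`, `pct_non`.
#' @export
grid_exploration <- function(pop, ci = published_params(ci = TRUE)$ci,
                             design = default_design(),
                             arms = c("Ag", "Ag+PIC", "Ag+aPD1", "Ag+PIC+aPD1"),
                             n_per_param = 10, n_sim = 1000, seed = NULL,
                             auc_dt = 0.25) {
  validate_params(pop)
  stopifnot(all(c("k_pic", "k_apd1") %in% ci$parameter))
  stopifnot(all(arms %in% design$arms$arm))
  grid_of <- function(nm) {
    row <- ci[ci$parameter == nm, ]
    exp(seq(log(row$lower), log(row$upper), length.out = n_per_param))
  }
  combos <- tidyr::expand_grid(k_pic = grid_of("k_pic"),
                               k_apd1 = grid_of("k_apd1"))
  auc_times <- seq(0, design$followup_end, by = auc_dt)
  obs_days <- design$schedule

  base_seed <- if (is.null(seed)) {
    sample.int(.Machine$integer.max, 1)
  } else {
    seed
  }
  out <- vector("list", nrow(combos) * length(arms))
  k <- 0L
  for (ci_row in seq_len(nrow(combos))) {
    p <- unclass(pop)
    p$k_pic <- combos$k_pic[ci_row]
    p$k_apd1 <- combos$k_apd1[ci_row]
    class(p) <- "kpd_params"
    for (a in seq_along(arms)) {
      k <- k + 1L
      doses <- arm_doses(design, arms[a])
      # exposure metrics on the typical individual (eta = 0, no noise)
      typ <- simulate_profile(p, doses, auc_times)
      auc_cd8 <- auc_trajectory(typ$time, typ$cd8_act)
      auc_res <- auc_trajectory(
        typ$time, resistance_inhibition_profile(typ, p)$inhibition
      )
      # population response rates: one single-arm virtual study of n_sim mice
      sub <- design
      sub$arms <- tibble::tibble(arm = arms[a], n_animals = as.integer(n_sim))
      arm_key <- sum(utf8ToInt(arms[a])) # stable under arm reordering
      tr <- with_local_seed(
        (base_seed + 7919L * ci_row + 104729L * arm_key) %% .Machine$integer.max,
        simulate_trial(sub, p)
      )
      calls <- classify_response(tr$records, loq = design$loq,
                                 end_time = design$followup_end)
      out[[k]] <- tibble::tibble(
        k_pic = p$k_pic, k_apd1 = p$k_apd1, arm = arms[a],
        auc_cd8 = auc_cd8, auc_resistance_inhibition = auc_res,
        pct_responder = 100 * cure_probability(calls),
        pct_partial = 100 * partial_probability(calls),
        pct_non = 100 * mean(calls$class == "non_responder")
      )
    }
  }
  dplyr::bind_rows(out)
}
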