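#' Classify per-animal treatment response
#'
#' Applies the trial's operational response definitions to each animal's
#' longitudinal record:
#'
#' * **responder** — tumor below the limit of quantification at the end of
#'   follow-up: the final observation is censored, the animal was followed to
#'   the end of the study window, and no regrowth follows the last censored
#'   stretch.
#' * **partial responder** — a transient response: the profile shrank (any
#'   observation below `shrink_frac` of the running maximum, or any censored
#'   observation) but regrew above the randomization volume (the animal's
#'   first observation) before the end of follow-up, or the animal shrank but
#'   was not below the LOQ at the end.
#' * **non-responder** — control-like growth (the complement of the two
#'   classes above).
#'
#' @param records Observation tibble (the [simulate_trial()] record format);
#'   may contain many animals.
#' @param loq Limit of quantification, mm^3.
#' @param end_time End of follow-up, days; responders must be observed at or
#'   beyond `end_time - end_slack`.
#' @param end_slack Tolerance on the final observation day (one observation
#'   interval by default, so the last scheduled measurement qualifies).
#' @param shrink_frac Shrinkage threshold relative to the running maximum.
#' @return A tibble with one row per animal: `animal_id`, `arm` (if present),
#'   `class` (factor: responder / partial_responder / non_responder),
#'   `final_volume`, `max_shrinkage` (1 - min(dv)/max-before-min), `regrew`.
#' @export
classify_response <- function(records, loq = 4, end_time = 90,
                              end_slack = 4, shrink_frac = 0.5) {
  stopifnot(nrow(records) > 0)
  has_arm <- "arm" %in% names(records)
  records |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$time)
      if (max(d$time) < 7) {
        stop("animal ", key$animal_id,
             ": profile ends before day 7, unclassifiable", call. = FALSE)
      }
      run_max <- cummax(d$dv)
      shrank <- any(d$dv < shrink_frac * run_max) || any(d$censored)
      # regrowth: above the randomization volume after the deepest response
      i_min <- which.min(d$dv)
      regrew <- shrank && any(d$dv[-seq_len(i_min)] > d$dv[1])
      n <- nrow(d)
      followed_to_end <- max(d$time) >= end_time - end_slack
      responder <- d$censored[n] && followed_to_end && !regrew
      cls <- if (responder) {
        "responder"
      } else if (shrank) {
        "partial_responder"
      } else {
        "non_responder"
      }
      tibble::tibble(
        arm = if (has_arm) d$arm[1] else NA_character_,
        class = factor(cls, levels = c("responder", "partial_responder",
                                       "non_responder")),
        final_volume = d$dv[n],
        max_shrinkage = 1 - min(d$dv) / max(run_max[seq_len(i_min)]),
        regrew = regrew
      )
    }) |>
    dplyr::ungroup()
}

#' Probability of cure / partial response
#'
#' Fraction of animals in a given response class: the number of responders
#' (or partial responders) over the total number of animals classified.
#'
#' @param calls A [classify_response()] tibble.
#' @return A fraction in `[0, 1]`.
#' @export
#' @examples
#' calls <- tibble::tibble(class = factor(c("responder", "non_responder")))
#' cure_probability(calls) # 0.5
cure_probability <- function(calls) {
  stopifnot(nrow(calls) > 0)
  mean(calls$class == "responder")
}

#' @rdname cure_probability
#' @export
partial_probability <- function(calls) {
  stopifnot(nrow(calls) > 0)
  mean(calls$class == "partial_responder")
}

#' Numerical predictive check of response probabilities
#'
#' Simulation-based model diagnostic: `n_replicates` full studies are
#' simulated under the population model, every animal is classified, and the
#' per-arm cure and partial-response probabilities are summarized by their
#' 5th, 50th and 95th percentiles across replicates. Observed probabilities
#' (from a simulated or real-format dataset) are attached for comparison:
#' a well-specified model puts the observed values inside the 5-95% band.
#'
#' @param pop A [pop_params()] object.
#' @param design A `study_design`.
#' @param n_replicates Number of simulated replicate studies (1000 reproduces
#'   the published diagnostic).
#' @param seed Integer seed.
#' @param observed Optional `sim_trial` object or records tibble whose per-arm
#'   probabilities are attached as the observed values.
#' @return An `npc_summary` tibble: one row per arm and metric
#'   (`cure` / `partial`) with `p5`, `p50`, `p95`, `observed`,
#'   `n_replicates`.
#' @export
npc <- function(pop, design, n_replicates = 1000, seed = NULL,
                observed = NULL) {
  stopifnot(n_replicates >= 1)
  with_local_seed(seed, {
    per_rep <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      tr <- tryCatch(simulate_trial(design, pop), error = function(e) e)
      if (inherits(tr, "error")) {
        stop("replicate ", r, " failed: ", conditionMessage(tr), call. = FALSE)
      }
      calls <- classify_response(tr$records, loq = design$loq,
                                 end_time = design$followup_end)
      per_rep[[r]] <- calls |>
        dplyr::group_by(.data$arm) |>
        dplyr::summarise(cure = cure_probability(dplyr::pick(dplyr::everything())),
                         partial = partial_probability(dplyr::pick(dplyr::everything())),
                         .groups = "drop") |>
        dplyr::mutate(replicate = r)
    }
    sim <- dplyr::bind_rows(per_rep) |>
      tidyr::pivot_longer(c("cure", "partial"), names_to = "metric",
                          values_to = "p") |>
      dplyr::group_by(.data$arm, .data$metric) |>
      dplyr::summarise(
        p5 = stats::quantile(.data$p, 0.05, names = FALSE),
        p50 = stats::quantile(.data$p, 0.50, names = FALSE),
        p95 = stats::quantile(.data$p, 0.95, names = FALSE),
        .groups = "drop"
      )
    if (!is.null(observed)) {
      rec <- if (inherits(observed, "sim_trial")) observed$records else observed
      obs <- classify_response(rec, loq = design$loq,
                               end_time = design$followup_end) |>
        dplyr::group_by(.data$arm) |>
        dplyr::summarise(cure = cure_probability(dplyr::pick(dplyr::everything())),
                         partial = partial_probability(dplyr::pick(dplyr::everything())),
                         .groups = "drop") |>
        tidyr::pivot_longer(c("cure", "partial"), names_to = "metric",
                            values_to = "observed")
      sim <- dplyr::left_join(sim, obs, by = c("arm", "metric"))
    } else {
      sim$observed <- NA_real_
    }
    sim$n_replicates <- n_replicates
    class(sim) <- c("npc_summary", class(sim))
    sim
  })
}
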