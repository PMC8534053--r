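#' Tumor volume from caliper measurements
#'
#' Converts two perpendicular caliper diameters to a volume assuming an ovoid
#' tumor: `length * width^2 / 2`. Provided for preprocessing real caliper
#' data; the virtual-trial generator produces volumes directly.
#'
#' @param length Longest diameter, mm. Vectorized.
#' @param width Perpendicular diameter, mm; must not exceed `length`
#'   (swapping is the caller's job).
#' @return Volume, mm^3.
#' @export
#' @examples
#' tumor_volume(5, 5) # 62.5, the randomization size at 5 mm average diameter
tumor_volume <- function(length, width) {
  if (any(width <= 0) || any(length < width)) {
    stop("require length >= width > 0", call. = FALSE)
  }
  length * width^2 / 2
}

arm_compounds <- list(
  "control" = character(),
  "Ag" = "Ag",
  "PIC" = "PIC",
  "aPD1" = "aPD1",
  "Ag+PIC" = c("Ag", "PIC"),
  "Ag+aPD1" = c("Ag", "aPD1"),
  "PIC+aPD1" = c("PIC", "aPD1"),
  "Ag+PIC+aPD1" = c("Ag", "PIC", "aPD1")
)

#' Default eight-arm study design
#'
#' The packaged design of the preclinical experiment: 121 animals across a
#' control arm, three monotherapies, three bi-therapies and the
#' triple-therapy. Antigen and PIC are dosed intratumorally on days 7 and 14;
#' anti-PD1 intravenously on days 7, 10 and 14 (optionally also day 17 for a
#' triple-therapy subgroup, off by default since the published arm table does
#' not split it out). Tumor volume is observed twice weekly from day 7;
#' volumes at or below 4 mm^3 are below the limit of quantification.
#'
#' @param day17_apd1 Add the day-17 anti-PD1 dose to the triple-therapy arm.
#' @param loq Limit of quantification, mm^3.
#' @param ts_cap Humane-endpoint volume, mm^3; observation stops at the first
#'   measurement exceeding it. The regulatory maximum is not published; the
#'   default is the conventional 1500 mm^3 mouse endpoint.
#' @param followup_end End of relapse follow-up, days (three months).
#' @return A `study_design` object: list with `arms` (tibble: `arm`,
#'   `n_animals`), `doses` (tibble: `arm`, `compound`, `time`, `signal`),
#'   `schedule` (observation days), `loq`, `ts_cap`, `followup_end`.
#' @export
#' @examples
#' default_design()$arms
default_design <- function(day17_apd1 = FALSE, loq = 4, ts_cap = 1500,
                           followup_end = 90) {
  arms <- tibble::tibble(
    arm = names(arm_compounds),
    n_animals = c(27L, 6L, 6L, 12L, 12L, 12L, 12L, 34L)
  )
  doses <- purrr::map_dfr(names(arm_compounds), function(a) {
    purrr::map_dfr(arm_compounds[[a]], function(cmp) {
      days <- if (cmp == "aPD1") {
        c(7, 10, 14, if (day17_apd1 && a == "Ag+PIC+aPD1") 17)
      } else {
        c(7, 14)
      }
      tibble::tibble(arm = a, compound = cmp, time = days, signal = 1)
    })
  })
  design <- list(
    arms = arms, doses = doses,
    # twice weekly from the first post-treatment measurement at day 7:
    # every 3.5 days, rounded down to whole days {7, 10, 14, 17, 21, ...}
    schedule = unique(floor(seq(7, followup_end, by = 3.5))),
    loq = loq, ts_cap = ts_cap, followup_end = followup_end
  )
  class(design) <- "study_design"
  design
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design> ", sum(x$arms$n_animals), " animals, ",
      nrow(x$arms), " arms; LOQ ", x$loq, " mm^3, cap ", x$ts_cap,
      " mm^3, follow-up to day ", x$followup_end, "\n", sep = "")
  print(x$arms, n = nrow(x$arms))
  invisible(x)
}

# dose table of one arm as a dose_events() tibble
arm_doses <- function(design, arm) {
  d <- design$doses[design$doses$arm == arm, , drop = FALSE]
  dose_events(d$compound, d$time, d$signal)
}

#' Simulate a virtual preclinical trial
#'
#' Generates one full synthetic study: for every animal, individual parameters
#' are drawn from the population distribution ([draw_individuals()]), the
#' nine-state model is integrated with the arm's dosing schedule
#' ([simulate_profile()]), and the tumor volume is sampled at the observation
#' days with additive Normal noise on the log scale. Volumes at or below the
#' LOQ are flagged censored and carry the LOQ as their value. Observation
#' stops at the first measurement exceeding the humane-endpoint cap;
#' otherwise animals are followed to the end of the relapse window.
#'
#' @param design A [default_design()]-style `study_design`.
#' @param pop A [pop_params()] object (generating truth).
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A `sim_trial` object: list with `records` (tibble: `animal_id`,
#'   `arm`, `time`, `dv`, `log_dv`, `censored`, `loq`), `truth` (list: `pop`,
#'   `individuals` tibble of generating per-animal parameters) and `design`.
#' @export
#' @examples
#' tr <- simulate_trial(default_design(), published_params(), seed = 1)
#' dplyr::count(tr$records, arm)
simulate_trial <- function(design, pop, seed = NULL) {
  stopifnot(inherits(design, "study_design"))
  validate_params(pop)
  with_local_seed(seed, {
    obs_days <- design$schedule
    sim_times <- sort(unique(c(0, obs_days)))
    records <- vector("list", nrow(design$arms))
    indivs <- vector("list", nrow(design$arms))
    id0 <- 0L
    for (a in seq_len(nrow(design$arms))) {
      arm <- design$arms$arm[a]
      n <- design$arms$n_animals[a]
      doses <- arm_doses(design, arm)
      ind <- draw_individuals(pop, n)
      ind$animal_id <- id0 + seq_len(n)
      ind$arm <- arm
      arm_rec <- vector("list", n)
      for (i in seq_len(n)) {
        p_i <- as.list(ind[i, ])
        traj <- tryCatch(
          simulate_profile(p_i, doses, sim_times),
          error = function(e) NULL
        )
        if (is.null(traj)) { # one redraw, then hard failure
          redraw <- draw_individuals(pop, 1)
          for (nm in names(iav_map)) {
            ind[[nm]][i] <- redraw[[nm]]
            ind[[paste0("eta_", nm)]][i] <- redraw[[paste0("eta_", nm)]]
          }
          p_i <- as.list(ind[i, ])
          traj <- simulate_profile(p_i, doses, sim_times)
        }
        pred <- traj$ts[match(obs_days, traj$time)]
        eps <- if (pop$sigma_log > 0) {
          stats::rnorm(length(obs_days), 0, pop$sigma_log)
        } else {
          numeric(length(obs_days))
        }
        dv <- exp(log(pmax(pred, .Machine$double.xmin)) + eps)
        cens <- dv <= design$loq
        rec <- tibble::tibble(
          animal_id = ind$animal_id[i], arm = arm, time = obs_days,
          dv = ifelse(cens, design$loq, dv),
          log_dv = ifelse(cens, log(design$loq), log(dv)),
          censored = cens, loq = design$loq
        )
        over <- which(rec$dv > design$ts_cap)
        if (length(over) > 0) rec <- rec[seq_len(over[1]), , drop = FALSE]
        arm_rec[[i]] <- rec
      }
      records[[a]] <- dplyr::bind_rows(arm_rec)
      indivs[[a]] <- ind
      id0 <- id0 + n
    }
    out <- list(
      records = dplyr::bind_rows(records),
      truth = list(pop = pop, individuals = dplyr::bind_rows(indivs)),
      design = design
    )
    class(out) <- "sim_trial"
    out
  })
}

#' @export
print.sim_trial <- function(x, ...) {
  cat("<sim_trial> ", dplyr::n_distinct(x$records$animal_id), " animals, ",
      nrow(x$records), " records (", round(100 * mean(x$records$censored), 1),
      "% BQL)\n", sep = "")
  invisible(x)
}

cmt_code <- c(Ag = 1L, PIC = 2L, aPD1 = 3L)

#' Write a dataset in the NONMEM-style CSV dialect
#'
#' Columns `ID, TIME, DV, MDV, CENS, LLOQ, AMT, CMT, ARM`: observation rows
#' carry the volume (mm^3) in `DV` with `MDV = 0` and `CENS = 1` when below
#' the LOQ; dose rows carry the unitless bolus in `AMT` with the compound code
#' in `CMT` (1 = Ag, 2 = PIC, 3 = aPD1) and `MDV = 1`.
#'
#' @param x A `sim_trial` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_nonmem_csv <- function(x, path) {
  stopifnot(inherits(x, "sim_trial"))
  obs <- dplyr::transmute(
    x$records,
    ID = .data$animal_id, TIME = .data$time, DV = .data$dv, MDV = 0L,
    CENS = as.integer(.data$censored), LLOQ = .data$loq,
    AMT = 0, CMT = 0L, ARM = .data$arm
  )
  ids <- dplyr::distinct(x$records, .data$animal_id, .data$arm)
  dose_rows <- dplyr::inner_join(ids, x$design$doses,
                                 by = c(arm = "arm"), relationship = "many-to-many")
  dos <- dplyr::transmute(
    dose_rows,
    ID = .data$animal_id, TIME = .data$time, DV = NA_real_, MDV = 1L,
    CENS = 0L, LLOQ = NA_real_, AMT = .data$signal,
    CMT = cmt_code[.data$compound], ARM = .data$arm
  )
  all_rows <- dplyr::arrange(dplyr::bind_rows(obs, dos),
                             .data$ID, .data$TIME, dplyr::desc(.data$MDV))
  readr::write_csv(all_rows, path, na = ".")
  invisible(path)
}

#' Read a NONMEM-style CSV dataset
#'
#' Inverse of [write_nonmem_csv()]: splits the file into observation records
#' and dose events.
#'
#' @param path CSV path in the dialect of [write_nonmem_csv()].
#' @return A list with `records` (tibble: `animal_id`, `arm`, `time`, `dv`,
#'   `log_dv`, `censored`, `loq`) and `doses` (tibble: `animal_id`, `arm`,
#'   `compound`, `time`, `signal`).
#' @export
read_nonmem_csv <- function(path) {
  raw <- readr::read_csv(path, na = ".", show_col_types = FALSE)
  obs <- raw[raw$MDV == 0L, , drop = FALSE]
  dos <- raw[raw$MDV == 1L, , drop = FALSE]
  list(
    records = tibble::tibble(
      animal_id = obs$ID, arm = obs$ARM, time = obs$TIME, dv = obs$DV,
      log_dv = log(obs$DV), censored = obs$CENS == 1L, loq = obs$LLOQ
    ),
    doses = tibble::tibble(
      animal_id = dos$ID, arm = dos$ARM,
      compound = names(cmt_code)[dos$CMT], time = dos$TIME, signal = dos$AMT
    )
  )
}

#' Export a simulated trial with its generating truth
#'
#' Writes `dataset.csv` (the [write_nonmem_csv()] dialect) and `truth.yaml`
#' (generating population parameters plus per-animal parameter values) into a
#' directory, so recovery experiments can be re-run from files alone.
#'
#' @param x A `sim_trial` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(x, dir) {
  stopifnot(inherits(x, "sim_trial"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_nonmem_csv(x, file.path(dir, "dataset.csv"))
  truth <- list(
    pop = lapply(unclass(x$truth$pop), function(v) v),
    individuals = lapply(
      split(x$truth$individuals, x$truth$individuals$animal_id),
      function(r) as.list(r[, c("animal_id", "arm", names(iav_map))])
    )
  )
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}
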