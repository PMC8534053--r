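#' Log-likelihood contribution of one observation (M3 censoring)
#'
#' Residual error is additive on the log-volume scale. A non-censored record
#' contributes the Normal log-density of `log_dv` around the model prediction;
#' a below-LOQ record contributes the log probability mass below the limit of
#' quantification, `log Phi((log LOQ - pred_log) / sigma_log)` (the M3
#' method). Vectorized over records.
#'
#' @param log_dv Observed log volume (ignored for censored records).
#' @param pred_log Model-predicted log volume.
#' @param sigma_log Residual SD on the log scale (> 0).
#' @param censored Logical flag per record.
#' @param log_loq Log of the LOQ; required (finite) for censored records.
#' @return Log-likelihood contribution per record.
#' @export
#' @examples
#' obs_loglik(log(4), log(4), 0.597, censored = TRUE, log_loq = log(4)) # log(0.5)
obs_loglik <- function(log_dv, pred_log, sigma_log, censored, log_loq = NA) {
  stopifnot(sigma_log > 0)
  n <- length(pred_log)
  censored <- rep_len(censored, n)
  log_loq <- rep_len(log_loq, n)
  if (any(censored & !is.finite(log_loq))) {
    stop("censored records must carry a finite LOQ", call. = FALSE)
  }
  out <- numeric(n)
  if (any(!censored)) {
    i <- !censored
    out[i] <- stats::dnorm(log_dv[i], pred_log[i], sigma_log, log = TRUE)
  }
  if (any(censored)) {
    i <- censored
    out[i] <- stats::pnorm((log_loq[i] - pred_log[i]) / sigma_log, log.p = TRUE)
  }
  out
}

# ---- structural predictors ---------------------------------------------------
# Each predictor maps (individual params, observation times, dose table) to
# predicted log volume. "growth" and "single_compound" have closed forms and
# are used in the staged model builds; "full" integrates the nine-state system.

pred_growth <- function(p, times, doses) {
  log(p$ts0) + p$lam * times
}

# Antigen and PIC treated as one active compound: equal-rate chain
# depot -> transit -> CD8act at rate k_ag, kill integrated in closed form via
# the incomplete gamma function.
pred_single_compound <- function(p, times, doses) {
  kill <- numeric(length(times))
  if (nrow(doses) > 0) {
    for (i in seq_len(nrow(doses))) {
      dt <- pmax(times - doses$time[i], 0)
      kill <- kill + doses$signal[i] *
        stats::pgamma(dt, shape = 3, rate = p$k_ag) / p$k_ag
    }
  }
  log(p$ts0) + p$lam * times - p$theta_cd8 * kill
}

pred_full <- function(p, times, doses) {
  tt <- sort(unique(c(0, times)))
  traj <- simulate_profile(p, doses, tt)
  log(pmax(traj$ts[match(times, traj$time)], 1e-300))
}

kpd_predictor <- function(model) {
  switch(model,
    growth = pred_growth,
    single_compound = pred_single_compound,
    full = pred_full,
    stop("unknown model: ", model, call. = FALSE)
  )
}

# ---- Laplace marginal likelihood --------------------------------------------

# joint log-likelihood of one animal given its random-effect vector eta
joint_ll <- function(eta, re_names, pop, pred_fn, obs, doses) {
  p <- as.list(pop)
  for (j in seq_along(re_names)) {
    p[[re_names[j]]] <- p[[re_names[j]]] * exp(eta[j])
  }
  pred <- tryCatch(pred_fn(p, obs$time, doses), error = function(e) NULL)
  if (is.null(pred) || any(!is.finite(pred))) return(-1e10)
  ll <- sum(obs_loglik(obs$log_dv, pred, p$sigma_log, obs$censored,
                       log(obs$loq)))
  omegas <- vapply(re_names, function(nm) pop[[iav_map[[nm]]]], numeric(1))
  ll + sum(stats::dnorm(eta, 0, omegas, log = TRUE))
}

# Laplace-approximate marginal log-likelihood of one animal; returns the
# approximation and the empirical Bayes mode.
laplace_animal <- function(re_names, pop, pred_fn, obs, doses) {
  q <- length(re_names)
  if (q == 0) {
    return(list(ll = joint_ll(numeric(0), re_names, pop, pred_fn, obs, doses),
                eta = numeric(0)))
  }
  f <- function(eta) -joint_ll(eta, re_names, pop, pred_fn, obs, doses)
  opt <- stats::nlminb(numeric(q), f)
  eta_hat <- opt$par
  h <- 1e-4
  if (q == 1) {
    hess <- (f(eta_hat + h) - 2 * opt$objective + f(eta_hat - h)) / h^2
    logdet <- log(max(hess, 1e-12))
  } else {
    H <- matrix(0, q, q)
    for (a in seq_len(q)) {
      for (b in a:q) {
        ea <- eb <- numeric(q); ea[a] <- h; eb[b] <- h
        H[a, b] <- H[b, a] <-
          (f(eta_hat + ea + eb) - f(eta_hat + ea - eb) -
             f(eta_hat - ea + eb) + f(eta_hat - ea - eb)) / (4 * h^2)
      }
    }
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    logdet <- sum(log(pmax(ev, 1e-12)))
  }
  list(ll = -opt$objective + q / 2 * log(2 * pi) - logdet / 2, eta = eta_hat)
}

#' Fit the population model by marginal maximum likelihood
#'
#' Maximizes the marginal likelihood of a longitudinal tumor-volume dataset
#' under log-normal inter-animal variability and the M3 censored residual
#' model. Per-animal random effects are integrated out with a Laplace
#' approximation around the empirical Bayes mode; the outer problem is solved
#' by quasi-Newton optimization on log-transformed parameters. Which
#' parameters are estimated (fixed effects, `omega_*` variability terms,
#' `sigma_log`) is declared via `estimate`; everything else stays at `init`,
#' which supports the staged model builds (control-only growth fit,
#' antigen+PIC-as-one-compound fit, then the drug-specific extensions).
#'
#' @param records Observation tibble with columns `animal_id`, `time`, `dv`,
#'   `log_dv`, `censored`, `loq` (the [simulate_trial()] record format).
#' @param doses Dose table: either one [dose_events()] tibble shared by all
#'   animals, or a per-animal tibble with an `animal_id` column.
#' @param init A [pop_params()] object of starting/fixed values.
#' @param estimate Character vector of parameters to estimate, e.g.
#'   `c("ts0", "lam", "omega_lam", "sigma_log")`.
#' @param model Structural predictor: `"growth"`, `"single_compound"`, or
#'   `"full"` (see Details in the package vignette).
#' @param control List passed to [stats::nlminb()] (e.g. `iter.max`).
#' @return A `kpd_fit` object: estimates (`kpd_params`), `minus2ll`, `aic`
#'   (`minus2ll + 2 * #estimated`), per-animal empirical Bayes parameters,
#'   IWRES for non-censored records, the objective trace, and a convergence
#'   flag. Non-convergence is flagged, never silent.
#' @export
fit_population <- function(records, doses = dose_events(), init, estimate,
                           model = "growth", control = list(iter.max = 300)) {
  validate_params(init)
  stopifnot(nrow(records) > 0, length(estimate) > 0)
  bad <- setdiff(estimate, names(init))
  if (length(bad) > 0) {
    stop("unknown parameters in estimate: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  pred_fn <- kpd_predictor(model)
  per_animal_doses <- "animal_id" %in% names(doses)
  ids <- unique(records$animal_id)
  obs_split <- split(records, factor(records$animal_id, levels = ids))
  dose_split <- if (per_animal_doses) {
    lapply(ids, function(id) {
      d <- doses[doses$animal_id == id, , drop = FALSE]
      dose_events(d$compound, d$time, d$signal)
    })
  } else {
    rep(list(doses), length(ids))
  }

  # random effects: parameters whose omega is estimated or fixed nonzero
  re_names <- names(iav_map)[vapply(names(iav_map), function(nm) {
    iav_map[[nm]] %in% estimate || init[[iav_map[[nm]]]] > 0
  }, logical(1))]

  trace <- numeric(0)
  m2ll_at <- function(pop) {
    ll <- 0
    for (i in seq_along(ids)) {
      ll <- ll + laplace_animal(re_names, pop, pred_fn,
                                obs_split[[i]], dose_split[[i]])$ll
    }
    -2 * ll
  }
  obj <- function(x) {
    pop <- unclass(init)
    pop[estimate] <- exp(x)
    pop$k_cd8 <- pop$k_ag
    v <- m2ll_at(pop)
    trace <<- c(trace, min(v, if (length(trace)) trace[length(trace)] else Inf))
    v
  }
  x0 <- log(unlist(unclass(init)[estimate]))
  opt <- stats::nlminb(x0, obj, control = control)

  est <- unclass(init)
  est[estimate] <- exp(opt$par)
  est$k_cd8 <- est$k_ag
  class(est) <- "kpd_params"

  # empirical Bayes modes and residuals at the final estimates
  eb <- vector("list", length(ids))
  iwres <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    la <- laplace_animal(re_names, est, pred_fn, obs_split[[i]],
                         dose_split[[i]])
    p_i <- as.list(est)
    for (j in seq_along(re_names)) {
      p_i[[re_names[j]]] <- p_i[[re_names[j]]] * exp(la$eta[j])
    }
    eb[[i]] <- tibble::as_tibble(c(list(animal_id = ids[i]),
                                   p_i[c("ts0", names(iav_map))]))
    obs <- obs_split[[i]]
    keep <- !obs$censored
    if (any(keep)) {
      ipred <- pred_fn(p_i, obs$time[keep], dose_split[[i]])
      iwres[[i]] <- tibble::tibble(
        animal_id = ids[i], time = obs$time[keep],
        iwres = (obs$log_dv[keep] - ipred) / est$sigma_log
      )
    }
  }

  minus2ll <- opt$objective
  out <- list(
    estimates = est, estimated = estimate, model = model,
    minus2ll = minus2ll, aic = minus2ll + 2 * length(estimate),
    individual_params = dplyr::bind_rows(eb),
    iwres = dplyr::bind_rows(iwres),
    trace = trace, converged = opt$convergence == 0,
    message = opt$message,
    n_animals = length(ids), n_obs = nrow(records)
  )
  class(out) <- "kpd_fit"
  if (!out$converged) {
    warning("fit did not converge: ", opt$message, call. = FALSE)
  }
  out
}

#' @export
print.kpd_fit <- function(x, ...) {
  cat("<kpd_fit> model '", x$model, "', ", x$n_animals, " animals, ",
      x$n_obs, " records\n-2LL = ", round(x$minus2ll, 2), ", AIC = ",
      round(x$aic, 2), if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  print(tidy(x), n = 20)
  invisible(x)
}

#' Compare two nested model fits
#'
#' Reports the change in -2 log-likelihood and AIC between two fits of the
#' same dataset. For nested models differing by `df` parameters, the
#' likelihood-ratio test flags significance at the 5% level
#' (`qchisq(0.95, 1) = 3.84` for one extra parameter).
#'
#' @param fit_a,fit_b `kpd_fit` objects on the same data (`fit_a` nested in
#'   `fit_b`).
#' @param df Difference in number of estimated parameters (default: inferred).
#' @return One-row tibble: `delta_m2ll`, `delta_aic`, `df`, `significant`.
#' @export
compare_fits <- function(fit_a, fit_b, df = NULL) {
  stopifnot(inherits(fit_a, "kpd_fit"), inherits(fit_b, "kpd_fit"))
  if (fit_a$n_obs != fit_b$n_obs || fit_a$n_animals != fit_b$n_animals) {
    stop("fits are not on the same dataset", call. = FALSE)
  }
  if (is.null(df)) df <- abs(length(fit_b$estimated) - length(fit_a$estimated))
  delta <- fit_a$minus2ll - fit_b$minus2ll
  # 3.84 is the conventional 5% chi-square cutoff at one degree of freedom
  thresh <- if (df == 1) 3.84 else stats::qchisq(0.95, max(df, 1))
  tibble::tibble(
    delta_m2ll = delta,
    delta_aic = fit_a$aic - fit_b$aic,
    df = df,
    significant = df > 0 & delta >= thresh
  )
}

#' Non-parametric bootstrap of a population fit
#'
#' Resamples animals (all their records) with replacement, preserving the
#' number of animals per arm, refits each replicate, and summarizes
#' per-parameter 5th-95th percentile intervals. Replicate fits that fail are
#' recorded and excluded with a count.
#'
#' @inheritParams fit_population
#' @param n_replicates Number of bootstrap datasets.
#' @param seed Integer seed.
#' @return A `kpd_boot` object: `replicates` (tibble of per-replicate
#'   estimates), `intervals` (tibble: `parameter`, `lower`, `upper`),
#'   `n_failed`.
#' @export
bootstrap_fit <- function(records, doses = dose_events(), init, estimate,
                          model = "growth", n_replicates = 1000, seed = NULL,
                          control = list(iter.max = 300)) {
  stopifnot(n_replicates >= 1)
  if (!"arm" %in% names(records)) records$arm <- "all"
  ids <- dplyr::distinct(records, .data$animal_id, .data$arm)
  with_local_seed(seed, {
    reps <- vector("list", n_replicates)
    n_failed <- 0L
    for (r in seq_len(n_replicates)) {
      resampled <- dplyr::bind_rows(lapply(split(ids, ids$arm), function(g) {
        tibble::tibble(orig_id = sample(g$animal_id, nrow(g), replace = TRUE))
      }))
      resampled$new_id <- seq_len(nrow(resampled))
      boot_rec <- dplyr::bind_rows(lapply(seq_len(nrow(resampled)), function(i) {
        rec <- records[records$animal_id == resampled$orig_id[i], , drop = FALSE]
        rec$animal_id <- resampled$new_id[i]
        rec
      }))
      boot_doses <- doses
      if ("animal_id" %in% names(doses)) {
        boot_doses <- dplyr::bind_rows(lapply(seq_len(nrow(resampled)), function(i) {
          d <- doses[doses$animal_id == resampled$orig_id[i], , drop = FALSE]
          d$animal_id <- resampled$new_id[i]
          d
        }))
      }
      fit <- tryCatch(
        suppressWarnings(fit_population(boot_rec, boot_doses, init, estimate,
                                        model, control)),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        n_failed <- n_failed + 1L
      } else {
        reps[[r]] <- tibble::as_tibble(
          c(list(replicate = r), unclass(fit$estimates)[estimate])
        )
      }
    }
    replicates <- dplyr::bind_rows(reps)
    intervals <- tidyr::pivot_longer(replicates, -"replicate",
                                     names_to = "parameter") |>
      dplyr::group_by(.data$parameter) |>
      dplyr::summarise(
        lower = stats::quantile(.data$value, 0.05, names = FALSE),
        upper = stats::quantile(.data$value, 0.95, names = FALSE),
        .groups = "drop"
      )
    out <- list(replicates = replicates, intervals = intervals,
                n_failed = n_failed)
    class(out) <- "kpd_boot"
    out
  })
}

#' Epsilon-shrinkage of a fit
#'
#' `1 - sd(IWRES)` over the non-censored records. Values near 0 indicate
#' individual predictions carry information beyond the residual noise.
#'
#' @param fit A `kpd_fit` object.
#' @return Shrinkage fraction.
#' @export
eps_shrinkage <- function(fit) {
  stopifnot(inherits(fit, "kpd_fit"))
  if (nrow(fit$iwres) == 0) {
    stop("no non-censored residuals: shrinkage undefined", call. = FALSE)
  }
  1 - stats::sd(fit$iwres$iwres)
}
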