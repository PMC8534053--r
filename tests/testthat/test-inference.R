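# Censored (M3) likelihood, the Laplace fitter, model comparison, bootstrap
# and shrinkage diagnostics.

test_that("observation likelihood matches the M3 definitions", {
  # censored record with the prediction at the censoring bound: mass 1/2
  expect_equal(obs_loglik(NA, log(4), 0.597, TRUE, log(4)), log(0.5))
  # non-censored at the mode: Normal density height
  expect_equal(obs_loglik(log(10), log(10), 0.597, FALSE),
               log(1 / (0.597 * sqrt(2 * pi))))
  # censored contribution -> 0 as the prediction drops far below the LOQ,
  # and -> -Inf as it rises far above
  expect_equal(obs_loglik(NA, log(4) - 50, 0.597, TRUE, log(4)), 0,
               tolerance = 1e-12)
  expect_lt(obs_loglik(NA, log(4) + 20, 0.597, TRUE, log(4)), -100)
  expect_error(obs_loglik(NA, 0, 0.5, TRUE, NA), "finite LOQ")
})

test_that("censored contribution equals the integrated Normal tail", {
  sigma <- 0.597
  for (pred in c(0.5, log(4), 3)) {
    tail_mass <- integrate(function(x) dnorm(x, pred, sigma), -Inf, log(4),
                           rel.tol = 1e-12)$value
    expect_equal(obs_loglik(NA, pred, sigma, TRUE, log(4)), log(tail_mass),
                 tolerance = 1e-8)
  }
})

test_that("dataset log-likelihood is the sum of record contributions", {
  pop <- control_truth()
  tr <- simulate_trial(one_arm_design("control", 5), pop, seed = 3)
  rec <- tr$records
  pred <- log(pop$ts0) + pop$lam * rec$time
  total <- sum(obs_loglik(rec$log_dv, pred, pop$sigma_log, rec$censored,
                          log(rec$loq)))
  by_record <- sum(vapply(seq_len(nrow(rec)), function(i) {
    obs_loglik(rec$log_dv[i], pred[i], pop$sigma_log, rec$censored[i],
               log(rec$loq[i]))
  }, numeric(1)))
  expect_equal(total, by_record)
})

test_that("degenerate mixed-effects fit agrees with pooled least squares", {
  # all omegas zero: the marginal model is plain nonlinear regression on log
  # volumes, so the fixed effects must match a pooled least-squares fit
  pop <- pop_params(ts0 = 19.5, lam = 0.194, sigma_log = 0.2)
  tr <- simulate_trial(one_arm_design("control", 12, ts_cap = 1e6), pop,
                       seed = 21)
  rec <- tr$records[!tr$records$censored, ]
  fit <- fit_population(rec, init = pop_params(ts0 = 10, lam = 0.1,
                                               sigma_log = 0.2),
                        estimate = c("ts0", "lam", "sigma_log"),
                        model = "growth")
  ls <- lm(log_dv ~ time, data = rec)
  expect_equal(fit$estimates$ts0, exp(unname(coef(ls)[1])), tolerance = 0.01)
  expect_equal(fit$estimates$lam, unname(coef(ls)[2]), tolerance = 0.01)
})

test_that("control-arm fit recovers the growth rate from synthetic truth", {
  pop <- control_truth()
  tr <- simulate_trial(one_arm_design("control", 27), pop, seed = 31)
  fit <- suppressWarnings(fit_population(
    tr$records, init = pop_params(ts0 = 30, lam = 0.3, omega_lam = 0.3,
                                  sigma_log = 0.4),
    estimate = c("ts0", "lam", "omega_lam", "sigma_log"), model = "growth"
  ))
  expect_true(fit$converged)
  expect_equal(fit$estimates$lam, pop$lam, tolerance = 0.15)
  # objective trace is recorded and non-increasing
  expect_true(length(fit$trace) > 5)
  expect_true(all(diff(fit$trace) <= 0))
  # AIC identity
  expect_equal(fit$aic, fit$minus2ll + 2 * 4)
})

test_that("fit is invariant to animal relabelling and record order", {
  pop <- control_truth()
  tr <- simulate_trial(one_arm_design("control", 8), pop, seed = 17)
  rec <- tr$records
  init <- pop_params(ts0 = 25, lam = 0.25, omega_lam = 0.2, sigma_log = 0.5)
  est <- c("ts0", "lam", "omega_lam", "sigma_log")
  f1 <- suppressWarnings(fit_population(rec, init = init, estimate = est))
  shuffled <- rec[sample(nrow(rec)), ]
  shuffled$animal_id <- match(shuffled$animal_id, unique(rec$animal_id)) + 100
  f2 <- suppressWarnings(fit_population(shuffled, init = init, estimate = est))
  expect_equal(f1$minus2ll, f2$minus2ll, tolerance = 1e-6)
  expect_equal(unclass(f1$estimates), unclass(f2$estimates), tolerance = 1e-4)
})

test_that("model comparison applies the 3.84 likelihood-ratio threshold", {
  f_small <- structure(list(minus2ll = 100, aic = 104, estimated = c("a"),
                            n_obs = 50, n_animals = 5), class = "kpd_fit")
  f_big <- structure(list(minus2ll = 96.16, aic = 104.16,
                          estimated = c("a", "b"),
                          n_obs = 50, n_animals = 5), class = "kpd_fit")
  cmp <- compare_fits(f_small, f_big)
  expect_equal(cmp$delta_m2ll, 3.84)
  expect_equal(cmp$df, 1)
  expect_true(cmp$significant)
  # identical fits: delta 0, not significant
  cmp0 <- compare_fits(f_small, f_small, df = 1)
  expect_equal(cmp0$delta_m2ll, 0)
  expect_false(cmp0$significant)
  f_other <- structure(list(minus2ll = 1, aic = 3, estimated = "a",
                            n_obs = 51, n_animals = 5), class = "kpd_fit")
  expect_error(compare_fits(f_small, f_other), "same dataset")
})

test_that("epsilon-shrinkage is one minus the IWRES spread", {
  mk <- function(iwres) {
    structure(list(iwres = tibble::tibble(iwres = iwres)), class = "kpd_fit")
  }
  expect_equal(eps_shrinkage(mk(rep(0, 10))), 1)
  set.seed(2)
  z <- as.numeric(scale(rnorm(200))) # exactly unit sd
  expect_equal(eps_shrinkage(mk(z)), 0, tolerance = 1e-10)
  x <- rnorm(100); x <- x / sd(x) * 0.85
  expect_equal(eps_shrinkage(mk(x)), 0.15)
  expect_error(eps_shrinkage(mk(numeric(0))), "undefined")
})

test_that("bootstrap preserves arm sizes and is seed-reproducible", {
  pop <- control_truth()
  tr <- simulate_trial(one_arm_design("control", 6), pop, seed = 51)
  init <- pop_params(ts0 = 25, lam = 0.25, omega_lam = 0.2, sigma_log = 0.5)
  est <- c("ts0", "lam")
  b1 <- bootstrap_fit(tr$records, init = init, estimate = est,
                      n_replicates = 3, seed = 9)
  b2 <- bootstrap_fit(tr$records, init = init, estimate = est,
                      n_replicates = 3, seed = 9)
  expect_identical(b1$replicates, b2$replicates)
  expect_equal(nrow(b1$replicates) + b1$n_failed, 3)
  expect_true(all(c("lower", "upper") %in% names(tidy(b1))))
  expect_true(all(tidy(b1)$lower <= tidy(b1)$upper))
})

test_that("tidy and glance expose the fit in broom style", {
  pop <- control_truth()
  tr <- simulate_trial(one_arm_design("control", 6), pop, seed = 61)
  fit <- suppressWarnings(fit_population(
    tr$records, init = pop_params(ts0 = 25, lam = 0.25, omega_lam = 0.2,
                                  sigma_log = 0.5),
    estimate = c("ts0", "lam", "omega_lam", "sigma_log")
  ))
  td <- tidy(fit)
  expect_true(all(c("parameter", "estimate", "estimated") %in% names(td)))
  expect_equal(sum(td$estimated), 4)
  gl <- glance(fit)
  expect_equal(gl$n_animals, 6)
  expect_equal(gl$aic, gl$minus2ll + 2 * gl$n_params)
})
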