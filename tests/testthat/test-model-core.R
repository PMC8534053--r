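# Structural model: drug-effect terms, derivatives, ODE trajectories and
# their closed-form oracles.

test_that("drug-effect terms match their linear forms and reject bad input", {
  # no signal or zero slope: no effect
  expect_identical(effect_pic(0, 1200), 1)
  expect_identical(effect_pic(0.5, 0), 1)
  expect_identical(effect_apd1(0, 821), 1)
  expect_identical(effect_apd1(0.5, 0), 1)
  # linear forms
  expect_equal(effect_pic(0.001, 1200), 1 / 2.2)
  expect_equal(effect_apd1(0.01, 821), 9.21)
  # monotone in the signal
  tr <- seq(0, 1, by = 0.1)
  expect_true(all(diff(effect_pic(tr, 1200)) < 0))
  expect_true(all(diff(effect_apd1(tr, 821)) > 0))
  expect_error(effect_pic(-1, 10), "must be >= 0")
  expect_error(effect_apd1(1, -10), "must be >= 0")
})

test_that("derivatives reduce to unperturbed growth without drug signals", {
  p <- published_params()
  s <- c(trt_ag = 0, trt_pic = 0, trt_apd1 = 0, apc = 0, tr_pic = 0,
         tr_apd1_1 = 0, tr_apd1_2 = 0, cd8_act = 0, ts = 19.5)
  d <- derivatives(s, p)
  expect_equal(d[["ts"]], p$lam * 19.5)
  expect_equal(unname(d[names(d) != "ts"]), rep(0, 8))
})

test_that("APC production equals k_ag times the depot signal", {
  p <- published_params()
  s <- c(trt_ag = 1, trt_pic = 0, trt_apd1 = 0, apc = 0, tr_pic = 0,
         tr_apd1_1 = 0, tr_apd1_2 = 0, cd8_act = 0, ts = 19.5)
  d <- derivatives(s, p)
  expect_equal(d[["apc"]], 4.93)
  expect_equal(d[["trt_ag"]], -4.93)
  expect_error(derivatives(s[-1], p), "state must contain")
  s["ts"] <- -1
  expect_error(derivatives(s, p), ">= 0")
})

test_that("no-dose trajectory matches the exponential closed form", {
  p <- published_params()
  tr <- simulate_profile(p, times = seq(0, 40, by = 2))
  expect_equal(tr$ts, p$ts0 * exp(p$lam * tr$time), tolerance = 1e-6)
  # doubling time of the unperturbed model
  expect_equal(log(2) / p$lam, 3.573, tolerance = 1e-3)
})

test_that("drug-signal chains match the gamma-density closed forms", {
  p <- pop_params(k_ag = 4.93, k_pic = 0.721, k_apd1 = 0.1,
                  theta_pic = 0, theta_apd1 = 0)
  doses <- dose_events(c("Ag", "PIC", "aPD1"), c(0, 0, 0))
  tt <- seq(0, 30, by = 0.5)
  tr <- simulate_profile(p, doses, tt)
  # with theta_pic = 0 the APC equation is the plain 1-stage transit chain
  ag <- closed_form_transit(4.93, tt, 1)
  pic <- closed_form_transit(0.721, tt, 1)
  pd <- closed_form_transit(0.1, tt, 2)
  expect_equal(tr$trt_ag, ag$depot, tolerance = 1e-5)
  expect_equal(tr$apc, ag$transit, tolerance = 1e-5)
  expect_equal(tr$tr_pic, pic$transit, tolerance = 1e-5)
  expect_equal(tr$tr_apd1_2, pd$transit, tolerance = 1e-5)
})

test_that("closed-form transit has the stated peaks and initial condition", {
  for (k in c(0.2, 0.721, 4.93)) {
    expect_equal(unlist(closed_form_transit(k, 0, 1)[, c("depot", "transit")]),
                 c(depot = 1, transit = 0))
    # n = 1 peaks at 1/k with value exp(-1); n = 2 peaks at 2/k
    expect_equal(closed_form_transit(k, 1 / k, 1)$transit, exp(-1))
    eps <- 1e-3 / k
    peak1 <- closed_form_transit(k, 1 / k + c(-eps, 0, eps), 1)$transit
    expect_true(which.max(peak1) == 2)
    peak2 <- closed_form_transit(k, 2 / k + c(-eps, 0, eps), 2)$transit
    expect_true(which.max(peak2) == 2)
  }
  expect_error(closed_form_transit(1, 1, 3), "n_transit")
})

test_that("kill term vanishes when theta_cd8 is zero", {
  p0 <- published_params()
  p <- pop_params(ts0 = p0$ts0, lam = p0$lam, k_ag = p0$k_ag,
                  k_pic = p0$k_pic, k_apd1 = p0$k_apd1, theta_cd8 = 0,
                  theta_pic = p0$theta_pic, theta_apd1 = p0$theta_apd1)
  tt <- seq(0, 30, by = 1)
  with_doses <- simulate_profile(p, triple_doses(), tt)
  no_doses <- simulate_profile(p, times = tt)
  expect_equal(with_doses$ts, no_doses$ts, tolerance = 1e-6)
})

test_that("dropping both theta slopes reduces the full model to the core CD8 model", {
  # Eqs with E_PIC = E_aPD1 = 1 must coincide with the antigen-only
  # activation/kill system regardless of PIC/aPD1 dosing
  p_red <- pop_params(ts0 = 19.5, lam = 0.194, k_ag = 4.93, k_pic = 0.721,
                      k_apd1 = 0.1, theta_cd8 = 1.63,
                      theta_pic = 0, theta_apd1 = 0)
  p_ag <- pop_params(ts0 = 19.5, lam = 0.194, k_ag = 4.93, theta_cd8 = 1.63)
  tt <- seq(0, 60, by = 1)
  full <- simulate_profile(p_red, triple_doses(), tt)
  core <- simulate_profile(p_ag, dose_events(c("Ag", "Ag"), c(7, 14)), tt)
  expect_equal(full$ts, core$ts, tolerance = 1e-6)
  expect_equal(full$cd8_act, core$cd8_act, tolerance = 1e-6)
})

test_that("compiled and pure-R right-hand sides agree", {
  p <- published_params()
  tt <- seq(0, 60, by = 3)
  a <- simulate_profile(p, triple_doses(), tt, compiled = TRUE)
  b <- simulate_profile(p, triple_doses(), tt, compiled = FALSE)
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("states remain non-negative across random parameter draws", {
  set.seed(41)
  tt <- seq(0, 90, by = 1.5)
  for (i in 1:12) {
    p <- pop_params(
      ts0 = runif(1, 5, 50), lam = runif(1, 0.05, 0.4),
      k_ag = runif(1, 0.5, 6), k_pic = runif(1, 0.05, 4),
      k_apd1 = runif(1, 1e-4, 0.5), theta_cd8 = runif(1, 0, 5),
      theta_pic = runif(1, 0, 2000), theta_apd1 = runif(1, 0, 1000)
    )
    tr <- simulate_profile(p, triple_doses(), tt)
    expect_true(all(as.matrix(tr[, -1]) >= 0))
  }
})

test_that("stronger anti-PD1 never increases tumor volume; the PIC effect
           boosts cumulative CD8 exposure", {
  base <- published_params()
  tt <- seq(0, 90, by = 0.5)
  ts_at <- function(theta_apd1) {
    p <- unclass(base); p$theta_apd1 <- theta_apd1; class(p) <- "kpd_params"
    simulate_profile(p, triple_doses(), tt)$ts
  }
  ts_curves <- sapply(c(0, 200, 821, 2000), ts_at)
  for (j in 2:ncol(ts_curves)) {
    expect_true(all(ts_curves[, j] <= ts_curves[, j - 1] + 1e-8))
  }
  # the PIC effect slows CD8 production as well as elimination, so cumulative
  # exposure is not globally monotone in theta_pic; switching the effect on
  # (published slope vs none) must still raise it severalfold
  cum_cd8_at <- function(theta_pic) {
    p <- unclass(base); p$theta_pic <- theta_pic; class(p) <- "kpd_params"
    tr <- simulate_profile(p, triple_doses(), tt)
    auc_trajectory(tr$time, tr$cd8_act)
  }
  expect_gt(cum_cd8_at(1200), 3 * cum_cd8_at(0))
})

test_that("dose events accumulate in the matching depot", {
  p <- pop_params(k_ag = 1)
  tr <- simulate_profile(p, dose_events(c("Ag", "Ag"), c(0, 2)), c(0, 2, 4))
  # output at a dose time is the pre-dose (trough) state
  expect_equal(tr$trt_ag[2], exp(-2), tolerance = 1e-6)
  # two days later: both the decayed first dose and the second dose decay
  expect_equal(tr$trt_ag[3], (exp(-2) + 1) * exp(-2), tolerance = 1e-6)
  expect_error(dose_events("Vaccine", 1), "unknown compound")
  expect_error(dose_events("Ag", -1), ">= 0")
})
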