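---
title: "A semi-mechanistic K-PD model of immuno-oncology combinations in cold tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A semi-mechanistic K-PD model of immuno-oncology combinations in cold tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunokpd)
library(dplyr)
```

## The problem

Non-inflamed ("cold") tumors carry few infiltrated T cells, present antigen
poorly and respond badly to checkpoint-inhibitor monotherapy. A preclinical
strategy against them combines three immuno-modulators: a tumor antigen (an E7
long peptide) to prime antigen-presenting cells (APCs), a TLR-3 agonist
(polyinosinic-polycytidylic acid, "PIC") to expand and sustain the primed
CD8⁺ response, and an anti-PD1 antibody to relieve tumor resistance
mechanisms (Tregs, MDSCs, PD-1/PD-L1). `immunokpd` implements a population
pharmacodynamic model of longitudinal tumor volume under the eight mono-,
bi- and triple-therapy arms of such a mouse study, plus the machinery needed
to estimate, check and explore it when only tumor size is observed.

Because no drug plasma concentrations exist for any of the three agents, drug
input is modelled kinetically-pharmacodynamically (K-PD): each administration
deposits a unitless signal that decays by first-order kinetics and drives the
effect through one or two transit compartments. Microgram dose amounts are
design metadata only; the scale of the signal is absorbed by the effect
slopes.

## The structural model

Nine states: three depots $TRT_i$ ($i \in \{Ag, PIC, \alpha PD1\}$), the
antigen transit signal (interpreted as the APC signal), one PIC transit
stage, two anti-PD1 transit stages in series, the activated-CD8 pool, and
tumor volume $TS$ (mm³):

$$\frac{dTRT_i}{dt} = -K_i \, TRT_i, \qquad
  \frac{dTR_i}{dt} = K_i \, TRT_i - K_i \, TR_i$$

$$E_{PIC} = \frac{1}{1 + \theta_{PIC}\,TR_{PIC}}, \qquad
  E_{\alpha PD1} = 1 + \theta_{\alpha PD1}\,TR_{\alpha PD1,2}$$

$$\frac{dAPC}{dt} = K_{Ag}\,TRT_{Ag} - K_{Ag}\,APC\,E_{PIC}$$

$$\frac{dCD8_{act}}{dt} = K_{CD8}\,APC\,E_{PIC}
  - K_{CD8}\,CD8_{act}\,E_{PIC}\,\frac{R}{E_{\alpha PD1}}$$

$$\frac{dTS}{dt} = \lambda\,TS
  - \theta_{CD8}\,CD8_{act}\,\frac{E_{\alpha PD1}}{R}\,TS$$

with resistance $R = 1$ for all animals, $K_{CD8} = K_{Ag}$ (the two are not
separately identifiable), and exponential growth $\lambda$ unaffected by
treatment. With all drug signals at zero the system is plain exponential
growth from $TS_0$; with $\theta_{PIC} = \theta_{\alpha PD1} = 0$ it reduces
exactly to the antigen-only activation/kill core (a reduction asserted in
the tests).

Two deliberate readings of ambiguous notation are worth recording. First,
the kill modifier is read as *division* by $R/E_{\alpha PD1}$ (anti-PD1
*enhances* CD8 efficacy), which matches the surrounding description of the
effect and makes the anti-PD1 benefit monotone — a property the tests
assert. Second, the published initial condition ($TRT = 1$ at $t = 0$) is
generalised to repeat dosing: depots start at zero and every administration
adds one signal unit at its dose time, which reproduces the single-dose
initial condition when a dose is given at $t = 0$.

A consequence of $E_{PIC}$ multiplying CD8 *production* as well as
elimination is that cumulative CD8 exposure is **not** globally monotone in
$\theta_{PIC}$: it rises steeply from zero, peaks near slopes of a few
hundred, and declines slowly for extreme slopes that throttle activation
itself. The package implements the equations as printed; tests assert the
scientifically meaningful direction (the published slope of 1200 au⁻¹ gives
severalfold more CD8 exposure than no PIC effect).

## Numerical choices

The system is integrated with `deSolve::lsoda` at tolerances
`rtol = 1e-8`, `atol = 1e-10` — the rate constants span three orders of
magnitude ($K_{Ag} = 4.93$ vs $K_{\alpha PD1} = 2.3\times10^{-3}$ day⁻¹), so
a stiff-capable integrator with tight tolerances is used throughout. Doses
are hard integrator events (the solver restarts); the value reported at an
output time that coincides with a dose is the pre-dose (trough) state. The
right-hand side is compiled C for speed; the pure-R `derivatives()`
implementation is exported and cross-checked against it. Linear subsystems
have closed forms — depot $e^{-kt}$, $n$-stage equal-rate transit
$(kt)^n e^{-kt}/n!$ — used as independent oracles (relative tolerance
1e−5) rather than as the simulation path. States are clamped at zero on
output to remove negative round-off.

## Statistical model and estimation

Tumor volumes are analysed on the natural-log scale with additive Normal
residual error (SD $\sigma = 0.597$ log-mm³ at the published estimates).
Inter-animal variability is exponential: $p_i = p\,e^{\eta}$,
$\eta \sim N(0, \omega^2)$, on the four parameters $\lambda$,
$\theta_{CD8}$, $K_{PIC}$, $K_{\alpha PD1}$; the packaged `omega` values
are the standard deviations of those log-normal random effects, and CVs are
reported as $\sqrt{e^{\omega^2}-1}$. Volumes at or below the limit of
quantification (4 mm³) are censored and contribute the probability mass
below the limit, $\log \Phi\!\left((\log LOQ - \hat y)/\sigma\right)$ (the
M3 method); the censored term is verified against numerical quadrature.

`fit_population()` maximizes the marginal likelihood with a Laplace
approximation: per animal, the joint log-likelihood is maximized over the
random effects, and the curvature at the mode supplies the Gaussian
correction; the outer problem runs quasi-Newton on log-transformed
parameters, recording a monotone objective trace. The staged model builds
are expressed by declaring which parameters are estimated versus fixed:
the control-only growth fit (`model = "growth"`, closed-form predictor),
the antigen+PIC-as-one-compound fit (`model = "single_compound"`, whose
activation chain and kill integral also have closed forms via the
incomplete gamma function), and the general `model = "full"` ODE predictor.
A Laplace maximizer was chosen over a stochastic EM because every model
stage used here carries a single random-effect dimension per animal, where
the Laplace approximation is accurate, fast and deterministic; it is the
"equivalent marginal-likelihood maximizer" route, declared here. Parameter
uncertainty comes from the non-parametric bootstrap (`bootstrap_fit()`,
resampling animals within arm, 5th–95th percentile intervals); standard
errors from a single fit's information matrix are not attempted.
$K_{Ag}$ is never estimated in the final model: its value 4.93 day⁻¹ comes
from the published fine-tuning exercise and ships as a fixed constant.

## What the virtual-trial generator emulates

`default_design()` reproduces the eight-arm study: control 27, Ag 6, PIC 6,
αPD1 12, Ag+PIC 12, Ag+αPD1 12, PIC+αPD1 12, triple 34 (121 animals);
antigen and PIC dosed on days 7 and 14, anti-PD1 on days 7, 10 and 14 (a
day-17 subgroup flag exists, default off). "Twice weekly" observation is
made concrete as every 3.5 days from day 7, rounded down to whole days
(7, 10, 14, 17, 21, ...); the humane-endpoint cap is 1500 mm³ (the
regulatory maximum is not published; this is the conventional mouse
endpoint and only truncates late records); relapse follow-up runs to day
90. All three are configurable. The generator draws individual parameters,
integrates the model, adds log-scale residual noise, censors at the LOQ
(censored records carry the LOQ as their value), and truncates each animal
at its first observation above the cap.

What it does **not** emulate: caliper length/width pairs (volumes are
generated directly; `tumor_volume()` exists for real-data preprocessing),
operator measurement error beyond the fitted residual model, and any
responder-subpopulation structure beyond unimodal random effects. Passing
recovery tests therefore demonstrate internal consistency of estimator and
generator under the published design — not that the published estimates are
correct for real mice.

## Response classification and diagnostics

Responders are animals whose final observation is censored at the end of the
90-day follow-up with no subsequent regrowth; the "transient response" of
partial responders is operationalised as shrinkage (any observation below
50% of the running maximum, or any censored observation) followed by
regrowth above the randomization volume (the animal's first observation);
non-responders are the complement. The 50% threshold and the day-90 horizon
are exposed as arguments. With the large residual SD (±45%/+82% per
observation), noise alone occasionally triggers the shrinkage rule, so
control arms show some nominal "partial" calls but — as the tests assert —
never responders.

`npc()` is the simulation-based diagnostic: many replicate studies are
simulated at the estimates, per-arm cure and partial-response probabilities
summarized by 5th/50th/95th percentiles, and observed values overlaid
(1000 replicates reproduces the published procedure). In the self-consistency
tests the observed study is itself drawn from the truth; band membership is
then pooled over seeds, arms and metrics, because requiring all six
statistics inside their bands jointly has coverage near $0.9^6$, well below
the per-statistic 90%.

## The exploration study

`grid_exploration()` varies $K_{PIC}$ and $K_{\alpha PD1}$ over
`n_per_param` log-spaced values inside their 90% bootstrap CIs (log spacing
because the $K_{\alpha PD1}$ interval spans two orders of magnitude), all
other parameters fixed at the final estimates. Per combination and arm it
reports the response-status percentages of `n_sim` simulated animals and
two exposure metrics computed on the typical (no-random-effect, noise-free)
individual: the trapezoidal AUC of $CD8_{act}$ and of resistance inhibition
$1 - R/E_{\alpha PD1}(t)$ over days 0–90 on a dense grid (4 points/day).
Resistance inhibition has no published formula; this definition is zero
without drug, bounded below one, and integrates meaningfully. Whether the
published exposure metric used typical or per-animal trajectories is not
stated; the typical-individual choice pairs one exposure value with each
combination, and is reversible.

## Worked example

```{r example, eval = FALSE}
pop <- published_params()
design <- default_design()

trial <- simulate_trial(design, pop, seed = 1)
autoplot(trial)

calls <- classify_response(trial$records, loq = design$loq, end_time = 90)
calls |> count(arm, class)

diag <- npc(pop, design, n_replicates = 200, seed = 2, observed = trial)
autoplot(diag)
```

## Problem sizes used by the shipped checks

The packaged test-suite and acceptance-script experiments use the study's
own sample sizes where the check is about the design (27-animal control
recovery, 12-animal single-compound recovery — each reported as the median
of 3 replicate experiments, because a single small-n experiment has
estimator sampling error comparable to the tolerances being checked), and
reduced simulation sizes where the check is directional (300 virtual
animals per arm for the cure-probability contrast in the tests, 1000 in the
acceptance script; NPC self-consistency at 200 replicates on a reduced
three-arm design over 5 seeds; exploration grids of 2×2 to 4×4 in tests).
These sizes are the package's choices for routine runs; all of them scale
up by changing the corresponding arguments.

## Known limitations

* The estimator supports the staged builds used here (one random-effect
  dimension per stage is where the Laplace approximation is most accurate);
  simultaneous estimation of all four variability terms on the full ODE
  model is possible but slow and was not needed for any shipped analysis.
* The responder/partial thresholds are operational definitions of a verbal
  classification; different thresholds shift the partial/non-responder split
  (though not the cure probabilities that the headline contrast uses).
* Cumulative CD8 exposure is non-monotone in $\theta_{PIC}$ (see above) —
  a structural property of the effect acting on production and elimination
  alike, inherited from the model equations.
* The K-PD signal is scale-free: dose *amounts* cannot be explored, only
  rate constants and slopes.
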