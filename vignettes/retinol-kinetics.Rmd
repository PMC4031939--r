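---
title: "Compartmental analysis of whole-body retinol kinetics in neonatal rats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartmental analysis of whole-body retinol kinetics in neonatal rats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retkin)
```

## The model

`retkin` implements a whole-body tracer model for orally administered
[3H]retinol in neonatal rats. The system is linear: each compartment J
loses a fixed fraction L(I,J) of its content per day to compartment I,
with I = 0 denoting irreversible loss. The topology follows the oral
route of the dose:

* compartments 1 and 2 — the gastrointestinal tract (dose input at 1;
  L(0,2) is the unabsorbed fraction, L(5,2) direct secretion of
  retinol-RBP from enterocytes into plasma);
* delay element 3 — chylomicron production (a pure transport lag);
* compartment 10 — newly absorbed retinyl esters in plasma chylomicrons;
* delay element 15 — chylomicron metabolism before tissue uptake;
* compartment 4 — processing of vitamin A in extravascular tissue before
  secretion of retinol-RBP into plasma;
* compartment 5 — the plasma retinol-RBP pool, exchanging with
* compartment 6 — a single extravascular vitamin A pool, the site of
  irreversible loss L(0,6).

Because the oral dose appears in plasma both as chylomicron retinyl
esters and as retinol-RBP, the observed quantity is the tracer content
of compartments 10 **plus** 5, expressed as a fraction of the ingested
dose.

Two departures from a plain linear system carry the study's structure:

* **Time interrupt.** The control group's plasma curve steepens after
  day 8; the loss coefficient L(0,6) is piecewise constant, switching
  from 0.004 to 0.197 per day at day 8.
* **Time-varying uptake (VARA perturbation).** A single oral dose of
  vitamin A mixed with 10% retinoic acid (VARA) transiently accelerates
  the uptake of plasma retinol into tissues. This is modeled as
  L(6,5)(T) = K·[K11·(e^(−P1·T) − e^(−P2·T)) + K12]: a difference-of-
  exponentials pulse on a constant baseline. With the reference constants
  (1.1, 450, 10.1, 19.6, 80) the pulse peaks near 1.7 h and the
  coefficient settles at 88 per day, against 60.3 per day in unsupplemented
  controls.

Model objects are built with `compartmental_model()`; `oil_model()` and
`vara_model()` ship the reference coefficient sets. All rates are per
day; times are in days everywhere internally (hours appear only in
reports, e.g. the plasma transit time).

## Derived kinetic calculus

For the 5 ⇄ 6 exchange block with sole irreversible exit L(0,6), the
package computes in closed form:

* transit time t(I) = 1 / (total fractional exit rate from I) — the mean
  duration of a single pass;
* plasma residence time T(5,5) = [(L(5,6)+L(0,6))/L(0,6)] / L(6,5) — the
  expected number of plasma visits times the per-visit duration;
* fractional catabolic rate FCR = 1/T(5,5), by construction;
* recycling number ν(5) = T(5,5)/t(5). The "number of passes" convention
  is used (not passes − 1): with T(5,5) = 2.40 d and t(5) = 0.40 h it
  yields 144, matching the reference reporting; the alternative
  convention cannot.
* traced plasma mass M(5) = plasma retinol concentration × body weight ×
  0.035 ml plasma/g (µmol/L × ml gives nmol directly);
* turnover R(6,5) = L(6,5)·M(5) and disposal rate
  DR = R(6,5)·L(0,6)/(L(5,6)+L(0,6)), the compartment-6 quasi-steady-state
  split of the turnover. A full tracee simulation is deliberately avoided:
  the steady-state ratio reproduces the published DR/turnover ratios at
  every tabulated time.

Where the loss coefficient carries the day-8 interrupt, every derived
quantity is reported per segment (before/after); no time-averaged single
value is invented.

Small systematic offsets against the published tables are expected and
documented rather than corrected: L(0,6) before day 8 is printed to one
significant figure (0.004), so the closed form gives T(5,5) = 2.50 d
against the printed 2.40 d (4%), and FCR after day 8 computes to 14.90
against the printed 14.7 per day (1.4%). Likewise the printed
perturbation constants give 195–197 per day at the first two tabulation
times against the published 193–199; the package evaluates the equation
as printed and does not re-derive constants.

## Simulation

The system is a linear delay differential equation. It is integrated
with `deSolve::dede()` (adaptive lsoda with lagged state access): delays
are pure transport lags, so the flux emerging into a delay's downstream
compartment is the entry flux evaluated `duration` days earlier. Each
delay also carries an in-transit mass state so that closed systems
conserve the dose to 1e−9 (tested). Two numerical choices matter:

* The derivative is discontinuous at interrupt switch times and delay
  emergence times. These times are declared as (identity) events, which
  forces an integrator restart at the discontinuity while keeping the
  lag history; without this, the error test can stall on the kink.
* Default tolerances are rtol 1e−8 / atol 1e−12; cross-checks against an
  independent fixed-step RK4 integrator with interpolated history agree
  to 0.1% at all sampling times (tested, both for the constant-coefficient
  and the time-varying model).

`impulse_response()` supports the residence-time cross-check: the time
integral of the plasma content after a unit impulse equals the
closed-form T(5,5) for a constant-coefficient segment. With the pre-day-8
control coefficients the slow eigenvalue of the exchange block is
≈ 0.004/day, so the integral needs a ~2000-day horizon to converge to
0.1%; a 200-day horizon would still hold ~45% of the slow mode.

## Weighted fitting and uncertainty

Free coefficients are estimated by minimizing
Σ [(y_i − ŷ_i)/(FSD·y_i)]², the relative-error weighted sum of squares
with FSD = 0.05 per datum unless overridden per point. Weighting uses the
*observed* value in the denominator (the convention of the SAAM family of
tools), so the loss surface does not move with the parameters.

The optimizer is bounded Levenberg–Marquardt (`minpack.lm::nls.lm`,
lower bound 0 on coefficients, a small positive floor on delay
durations), with an optional seeded multistart. One tuning parameter is
load-bearing: the internal finite-difference step (`epsfcn = 1e-8`,
i.e. steps of ~1e−4 relative) is set to sit above the ODE objective's
noise floor; with the library default the Jacobian is dominated by
solver noise and fits stall short of the optimum even on noise-free
data.

Uncertainty is reported as fractional standard deviations (FSD =
SE/estimate) from the inverse curvature at the optimum:
cov = σ̂²(JᵀJ)⁻¹ with σ̂² = WSS/(n−k), J a central-difference Jacobian
with step max(1e−3·|p|, 1e−5) so that estimates at the zero boundary
still yield a usable column. A coefficient is declared identifiable if
its FSD < 0.5. Singular curvature flags all FSDs unidentifiable rather
than failing.

Model complexity is adjudicated by F-statistic and least-squares AIC
(n·ln(WSS/n) + 2k): an extra parameter is "justified" only if the F-test
rejects at 0.05 *and* AIC drops by more than 2. Between-group coefficient
differences use t = (v₁−v₂)/√(SEM₁²+SEM₂²) with SEM = v·FSD and df = 60
(the study's convention: (3 pups/time × 14 times − 12 parameters) × 2
treatments).

For the perturbation model only the products K·K11 and K·K12 enter the
rate, so the five-constant form is structurally redundant. The fit is
internally parameterized as (A = K·K11, B = K·K12, P1, ΔP = P2 − P1) and
the published form is reported with K held at 1.1 by convention; the
user may report at another K. A fitted ΔP at its zero bound (pulse
collapsed, P2 ≤ P1) is surfaced as a boundary diagnostic, not an error.

## The synthetic study generator

No pup-level data are public, so `generate_study()` emulates the study
design for end-to-end testing: oral dose on postnatal day 4; sampling at
1, 2.5, 4, 6, 8, 11, 15, 24 h and 2, 4, 6, 8, 11, 14 days (hours
converted at exactly 1/24); 3 pups per time per group, each euthanized
once (cross-sectional — no within-pup correlation); dose of 0.2 µCi/µl
at 0.8 µl/g body weight + 1 µl overage (2.22e6 dpm/µCi); plasma volume
0.035 ml/g; multiplicative log-normal measurement noise with mean 1 and
fractional SD 0.05, matching the relative-error weighting (an additive
Gaussian option exists for robustness checks).

Supporting draws are package choices, stated once: body weight is flat
at 10 g for 2 days, then linear to 45 g at day 11 (the study's reported
weights) continuing at that slope, with 5% log-normal per-pup jitter;
the dose residue left in the pipette tip/paper chip is Beta(2, 38)
(mean 5%) of the total; control plasma retinol is drawn near 1.2 µmol/L
(sd 0.15, the observed 0.9–1.5 range), with the VARA group transiently
elevated ~3.5-fold at dosing, decaying at 3/day to baseline by day 2.
Raw dpm fields are back-computed so that preprocessing recovers the
noisy fraction of dose exactly; a manifest (seed, design) accompanies
each dataset.

The delay durations are not published; the shipped defaults
DT(3) = DT(15) = 0.005 d (~7 min each) were chosen once so that the
generated control curve peaks at the 4 h sampling point, as observed.
With the printed (rounded) absorption coefficients the simulated peak
height is ~5.3% of the dose against the observed 3.9%; the generator
makes no claim to replicate the unpublished observed points, only the
design's statistical structure. Passing recovery tests therefore shows
the pipeline is self-consistent under the stated noise model — not that
the model is correct for real pups, where absorption kinetics, growth
and assay error need not follow these idealizations.

## Parameter recovery and a known limitation

On noise-free synthetic data the fit recovers the generating
coefficients to 0.1%. Across 20 seeded noisy replicates of the full
design, ≥90% of the coefficients declared identifiable fall within 2
fitted FSDs of truth; the pre-day-8 loss L(0,6) is typically *not*
identifiable (fitted FSD ≥ 0.5), consistent with its published FSD of
0.79.

One published robustness claim does not reproduce under these study
conditions: that ±50% changes in the fixed absorption coefficients move
L(6,5) by at most 2%. With the printed coefficient values the
chylomicron compartment contributes the bulk of the observed early
signal (its quasi-steady level is inflow/L(15,10)), so rescaling
L(2,1), L(3,2) or L(15,10) by ±50% distorts the simulated curve far
beyond the 5% weighting band — the best compensating refit is an order
of magnitude worse in WSS, and the refitted L(6,5) moves 5–30%. Only
L(5,2) and L(0,2) leave the plasma block within ~2%. The corresponding
acceptance test asserts the claim as published and fails; the most
likely explanation is that the unrounded absorption block used
internally in the original analysis (its printed values are explicitly
flagged as not identified with certainty, and the delay durations are
unpublished) distributed less of the early signal to the chylomicron
compartment.

## Problem sizes

The shipped tests and scripts run the full 14-point design; the recovery
suite uses 20 replicates of the complete two-group study, the
sensitivity suite 10 refits (5 fixed coefficients × 2 directions), and
the residence-time cross-check a 2000-day impulse horizon on a dense
12,000-point grid — sizes chosen so each property is measured on the
study's own scale.
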