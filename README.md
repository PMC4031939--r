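# retkin

Compartmental analysis of whole-body vitamin A (retinol) kinetics in
neonatal rats.

Neonates start life with marginal vitamin A stores, and oral
supplementation of newborns is an active public-health question. This
package implements a whole-body tracer analysis for orally dosed
[3H]retinol in rat pups: an eight-component linear compartmental model
(gut → chylomicron production delay → plasma chylomicron retinyl esters →
chylomicron metabolism delay → tissue processing → plasma retinol-RBP ⇄
extravascular vitamin A, with irreversible loss from the extravascular
pool), fitted to plasma tracer curves and summarized by the kinetic
calculus used in this field. It is aimed at kinetic modelers who want a
scripted, testable equivalent of the SAAM-style workflow for this class
of models.

The model is linear: compartment J loses the fraction `L(I,J)` of its
content per day to compartment I (`I = 0` is loss from the system).
The observed quantity is the plasma tracer — compartments 10 + 5 — as a
fraction of the ingested dose. Three study-specific structures are
supported:

* pure transport delays (chylomicron production and metabolism);
* a **time interrupt**: the control-group loss coefficient `L(0,6)`
  switches from 0.004 to 0.197 per day at day 8;
* a **time-varying uptake coefficient** for pups supplemented with
  vitamin A + 10% retinoic acid (VARA):
  `L(6,5)(T) = K·[K11·(e^(−P1·T) − e^(−P2·T)) + K12]`.

From a fitted coefficient set the package derives transit times
`t(I) = 1/Σ exits`, the plasma residence time
`T(5,5) = [(L(5,6)+L(0,6))/L(0,6)]/L(6,5)`, the fractional catabolic
rate `FCR = 1/T(5,5)`, the recycling number `ν(5) = T(5,5)/t(5)`, traced
masses `M(5)`, turnover `R(6,5) = L(6,5)·M(5)` and the disposal rate
`DR = R(6,5)·L(0,6)/(L(5,6)+L(0,6))`. Fitting is relative-error weighted
nonlinear least squares (5% fractional SD per datum) with uncertainty
reported as fractional standard deviations (identifiable if FSD < 0.5),
nested-model F/AIC comparison, and between-group coefficient t-tests.
A synthetic pup-level study generator reproduces the design (14 sampling
times over 14 days, 3 pups/time/group, dose and plasma-volume rules) so
the whole pipeline is testable end to end without any raw data.

## Worked example

```r
library(retkin)

m <- oil_model()               # control-group reference coefficients
kinetic_summary(m)
#> Kinetic summary (oil)
#>   t(5)       0.398 h
#>   t(6)       1.66 / 1.25 days
#>   T(5,5)     2.5 / 0.0671 days
#>   FCR(5,5)   0.399 / 14.9 per day
#>   nu(5)      151 / 4.05
```

A retinol molecule spends ~0.40 h in plasma per pass, ~2.5 days in
plasma before irreversible loss, and recycles ~150 times between plasma
and tissues before the day-8 switch; after it, the catabolic rate jumps
to ~14.9/day. (The slash-separated pairs are the before/after segments
of the day-8 loss interrupt.)

Simulate a study, fit it, and examine the VARA perturbation:

```r
design  <- study_design()                      # the 14-point, n = 3 design
records <- generate_study(design, seed = 20)   # pup-level synthetic data
curve   <- superpup_curve(records, "vara", study_times())

res <- fit_perturbation(vara_model(), curve,
                        start = perturbation_params(K = 1.1, K11 = 300,
                                                    P1 = 7, P2 = 30,
                                                    K12 = 60))
res$params
#> L(6,5)(T) = 1.1 x [371.8 (e^-9.208T - e^-19.7T) + 80.09]
#>   baseline/asymptote 88.1 per day; peak 199.8 per day at 0.07249 d
```

The fitted pulse says VARA roughly triples the plasma-to-tissue uptake
coefficient in the first two hours (peak ~200/day at ~1.7 h against
60.3/day in controls) and the effect is transient: by one day the
coefficient settles at ~88/day for the rest of the study.

The numbered scripts under `analysis/` run the full workflow
(`01_simulate_study.R` … `05_sensitivity.R`), writing their tables under
`results/`: synthetic study, per-group weighted fits with FSDs,
between-group t-tests, derived kinetic summaries, the per-time
disposal/turnover table, the uptake-coefficient tabulation, and the
fixed-coefficient sensitivity analysis.

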