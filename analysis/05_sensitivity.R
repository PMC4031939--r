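#!/usr/bin/env Rscript
# Sensitivity of the fitted plasma-kinetics coefficients to the fixed
# absorption-block values: scale each fixed coefficient by 0.5x and 1.5x,
# refit the free coefficients, and report the percent change of each
# estimate. Also demonstrates the nested-model F/AIC comparison on the
# control group (does the two-segment loss coefficient earn its extra
# parameter?).
#
# Reads results/study/; writes results/sensitivity/.

library(retkin)

study <- "results/study"
out <- "results/sensitivity"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

records <- read_pup_csv(file.path(study, "pup_records.csv"))
curve <- superpup_curve(records, "oil", study_times())
truth <- oil_model()
free <- c("L(5,4)", "L(6,5)", "L(5,6)", "L(0,6)pre", "L(0,6)post")
fixed <- c("L(2,1)", "L(3,2)", "L(15,10)", "L(5,2)", "L(0,2)")

ref <- suppressWarnings(
  fit_model(truth, curve, free, start = c(3, 40, 0.4, 0.01, 0.1)))
sens <- suppressWarnings(
  sensitivity_to_fixed(truth, curve, fixed, free, ref_fit = ref))
write.csv(sens, file.path(out, "sensitivity_fixed_absorption.csv"),
          row.names = FALSE)
cat("Max |% change| of each free coefficient over all ±50% perturbations:\n")
print(round(attr(sens, "max_abs_pct"), 2))
cat("\nNote: perturbing the chylomicron-path coefficients (L(2,1), L(3,2),\n")
cat("L(15,10)) moves L(6,5) well beyond 2% here, because with the reference\n")
cat("coefficient values the chylomicron compartment dominates the observed\n")
cat("early signal; only L(5,2) and L(0,2) leave the plasma block nearly\n")
cat("unchanged. See the methods vignette for discussion.\n")

# nested comparison: single loss value vs the two-segment interrupt
small_free <- c("L(5,4)", "L(6,5)", "L(5,6)", "L(0,6)pre")
m_single <- oil_model()
m_single$interrupts$value_after <- m_single$interrupts$value_before
fit_small <- suppressWarnings(fit_model(
  m_single, curve, small_free, start = c(3, 40, 0.4, 0.01)))
# refit with both segments tied during fitting is approximated by freeing
# only the shared pre value; the big model frees both segments
cmp <- compare_models(
  structure(list(wss = fit_small$wss, n_obs = fit_small$n_obs,
                 n_free = fit_small$n_free, aic = fit_small$aic,
                 free = small_free), class = "retkin_fit"),
  ref)
cat(sprintf("\nTwo-segment loss vs single loss: F = %.1f, p = %.2g, dAIC = %.1f -> %s\n",
            cmp$F, cmp$p, cmp$dAIC, cmp$verdict))
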