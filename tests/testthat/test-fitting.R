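# Weighted least-squares machinery: loss function arithmetic, nested-model
# statistics, group tests, and recovery of generating coefficients from
# noise-free simulated data.

test_that("weighted sum of squares uses relative-error weighting", {
  obs <- tracer_curve(1, 0.04, weight_fsd = 0.05)
  pred <- tracer_curve(1, 0.042)
  expect_equal(weighted_wss(obs, pred), 1.0)
  # perfect prediction scores zero
  expect_equal(weighted_wss(obs, obs), 0)
  # scale invariance: doubling observations and predictions changes nothing
  obs2 <- tracer_curve(1, 0.08, weight_fsd = 0.05)
  pred2 <- tracer_curve(1, 0.084)
  expect_equal(weighted_wss(obs2, pred2), weighted_wss(obs, pred))
  # mismatched grids and zero observations are rejected
  expect_error(weighted_wss(obs, tracer_curve(2, 0.042)), "time grids")
  expect_error(weighted_wss(tracer_curve(1, 0), pred), "zero observation")
})

test_that("nested-model comparison computes F and AIC as specified", {
  mk <- function(wss, k, n = 14, free = paste0("p", seq_len(k)))
    structure(list(wss = wss, n_obs = n, n_free = k,
                   aic = n * log(wss / n) + 2 * k, free = free),
              class = "retkin_fit")
  # hand arithmetic: WSS 2 -> 1 for one extra parameter, n = 14
  cmp <- compare_models(mk(2, 4), mk(1, 5, free = paste0("p", 1:5)))
  expect_equal(cmp$F, 9.0)
  # identical fits: F = 0, dAIC = +2 per extra parameter
  cmp0 <- compare_models(mk(1, 4), mk(1, 5, free = paste0("p", 1:5)))
  expect_equal(cmp0$F, 0)
  expect_equal(cmp0$dAIC, 2)
  expect_equal(cmp0$verdict, "not justified")
  # 10-fold WSS reduction at +1 parameter is decisively justified
  cmp10 <- compare_models(mk(1, 4), mk(0.1, 5, free = paste0("p", 1:5)))
  expect_equal(cmp10$dAIC, 14 * log(0.1) + 2, tolerance = 1e-12)
  expect_equal(cmp10$verdict, "justified")
  # swapping roles is rejected, not sign-flipped
  expect_error(compare_models(mk(1, 5, free = paste0("p", 1:5)), mk(2, 4)),
               "nested")
  expect_error(compare_models(mk(2, 4, n = 14), mk(1, 5, n = 10)),
               "same data")
})

test_that("between-group coefficient t-test matches the SEM arithmetic", {
  r <- group_coefficient_ttest(169.4, 0.04, 60.3, 0.07)
  expect_equal(r$t, 109.1 / sqrt((169.4 * 0.04)^2 + (60.3 * 0.07)^2),
               tolerance = 1e-3)
  expect_true(r$significant)
  r2 <- group_coefficient_ttest(5.52, 0.07, 5.06, 0.14)
  expect_equal(r2$t, 0.57, tolerance = 1e-2)
  expect_false(r2$significant)
  expect_equal(group_coefficient_ttest(5, 0.1, 5, 0.1)$t, 0)
  expect_error(group_coefficient_ttest(1, 0, 2, 0), "zero")
})

test_that("fitting noise-free simulated data recovers the generating values", {
  truth <- oil_model()
  free <- c("L(5,4)", "L(6,5)", "L(5,6)", "L(0,6)pre", "L(0,6)post")
  curve <- simulate_tracer(truth, 1, study_times(), rtol = 1e-10)
  curve <- tracer_curve(curve$time_days, curve$fraction_of_dose,
                        group = "oil", weight_fsd = 0.05)
  # start away from the generating values
  start <- c(3, 40, 0.4, 0.01, 0.1)
  fit <- fit_model(truth, curve, free, start = start)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates), unname(coef_by_label(truth, free)),
               tolerance = 1e-3)
  expect_true(all(fit$fsds < 0.5))  # well-identified on clean data
  expect_true(all(fit$estimates >= 0))
  expect_error(fit_model(truth, curve, character(0)), "at least one")
  expect_error(fit_model(truth, curve, free, start = rep(-1, 5)),
               "non-negative")
})

test_that("fit report files carry estimates, FSDs and the sidecar", {
  fit <- structure(list(estimates = c("L(6,5)" = 60), fsds = c("L(6,5)" = 0.07),
                        covariance = matrix(1, 1, 1), wss = 2, n_obs = 14,
                        n_free = 1, aic = 14 * log(2 / 14) + 2,
                        converged = TRUE, group = "oil", free = "L(6,5)"),
                   class = "retkin_fit")
  path <- withr::local_tempfile(fileext = ".csv")
  write_fit_report(fit, path)
  rep <- read.csv(path)
  expect_equal(rep$coefficient, "L(6,5)")
  expect_true(rep$identifiable)
  side <- jsonlite::read_json(sub("\\.csv$", ".json", path))
  expect_equal(side$wss, 2)
})

test_that("scaling a disconnected fixed coefficient does not move the fit", {
  # a spur compartment feeding only the outside, invisible to observation
  m <- compartmental_model(
    compartments = c(5L, 6L, 7L),
    coefficients = data.frame(to = c(6L, 5L, 0L, 0L),
                              from = c(5L, 6L, 6L, 7L),
                              value = c(60.3, 0.60, 0.004, 3),
                              fixed = c(FALSE, FALSE, FALSE, TRUE)),
    input = 5L, observation = 5L, group = "toy")
  curve <- simulate_tracer(m, 1, c(0.05, 0.1, 0.2, 0.5, 1, 2, 4, 8))
  curve <- tracer_curve(curve$time_days, curve$fraction_of_dose,
                        group = "toy")
  ref <- fit_model(m, curve, c("L(6,5)", "L(5,6)"))
  sens <- sensitivity_to_fixed(m, curve, fixed = "L(0,7)",
                               free = c("L(6,5)", "L(5,6)"), ref_fit = ref)
  expect_true(all(abs(sens$`pct_change_L(6,5)`) < 1e-4))
  expect_true(all(abs(sens$`pct_change_L(5,6)`) < 1e-4))
  # zero factor: all changes identically zero
  sens0 <- sensitivity_to_fixed(m, curve, fixed = "L(0,7)",
                                free = c("L(6,5)", "L(5,6)"),
                                factor = 0, ref_fit = ref)
  expect_true(all(abs(as.matrix(
    sens0[, grep("pct_change", names(sens0))])) < 1e-6))
})
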