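# Time-varying uptake coefficient: exact evaluation of the published
# equation, pulse shape properties, nesting in the constant model, and
# self-consistent recovery of the constants from noise-free data.

test_that("the uptake equation evaluates to the published tabulation", {
  p <- perturbation_params()  # 1.1 x [450 (e^-10.1T - e^-19.6T) + 80]
  expect_equal(signif(l65_of_t(p, 0.625), 3), 88.9)
  expect_equal(signif(l65_of_t(p, 1), 3), 88.0)
  # pulse vanishes at the endpoints: baseline K*K12 at 0 and at infinity
  expect_equal(l65_of_t(p, 0), 1.1 * 80)
  expect_equal(l65_of_t(p, 1e6), 1.1 * 80)
  expect_error(l65_of_t(p, -1), "negative")
  # the plateau: all study times >= 1 day agree to 3 significant figures
  tab <- perturbation_table(p)
  plateau <- tab$l65_per_day[tab$time_days >= 1]
  expect_true(all(signif(plateau, 3) == 88.0))
})

test_that("the pulse has a single interior maximum at the closed-form time", {
  p <- perturbation_params()
  pk <- pulse_peak(p)
  expect_equal(pk$time, log(19.6 / 10.1) / (19.6 - 10.1))
  expect_equal(pk$time, 0.0698, tolerance = 1e-2)
  grid <- seq(0, 2, by = 1e-4)
  vals <- l65_of_t(p, grid)
  expect_equal(grid[which.max(vals)], pk$time, tolerance = 1e-3)
  expect_equal(max(vals), pk$value, tolerance = 1e-6)
  # single interior maximum: increasing before, decreasing after
  expect_true(all(diff(vals[grid < pk$time]) > 0))
  expect_true(all(diff(vals[grid > pk$time]) < 0))
  # textbook case and the flat degenerate case
  expect_equal(pulse_peak(perturbation_params(1, 1, 1, 2, 1))$time, log(2))
  flat <- pulse_peak(perturbation_params(1.1, 0, 1, 2, 80))
  expect_equal(flat, list(time = 0, value = 88))
  expect_error(perturbation_params(P1 = 2, P2 = 1), "P2 > P1")
})

test_that("a collapsed pulse reduces to the constant-coefficient model", {
  base <- vara_model()
  p0 <- perturbation_params(K = 1.1, K11 = 0, P1 = 10, P2 = 20,
                            K12 = 169.4 / 1.1)
  pert <- attach_perturbation(base, p0)
  t <- study_times()
  a <- simulate_tracer(pert, 1, t, rtol = 1e-10)
  b <- simulate_tracer(base, 1, t, rtol = 1e-10)
  expect_equal(a$fraction_of_dose, b$fraction_of_dose, tolerance = 1e-8)
})

test_that("time-varying solution matches the independent integrator", {
  p <- perturbation_params()
  m <- attach_perturbation(vara_model(), p)
  cv <- simulate_tracer(m, 1, study_times())
  pars <- list(L21 = 11.5, L02 = 0.02, L52 = 0.00, L32 = 1980, L1510 = 647,
               L54 = 5.52, L65 = function(t) l65_of_t(p, t), L56 = 0.83,
               L06 = 0.008, DT3 = 0.005, DT15 = 0.005)
  oracle <- rk4_oral_curve(pars, study_times(), h = 5e-4)
  expect_equal(cv$fraction_of_dose, oracle, tolerance = 1e-3)
})

test_that("noise-free perturbation data returns the generating constants", {
  truth <- perturbation_params()
  m <- attach_perturbation(vara_model(), truth)
  cv <- simulate_tracer(m, 1, study_times(), rtol = 1e-10)
  curve <- tracer_curve(cv$time_days, cv$fraction_of_dose, group = "vara",
                        weight_fsd = 0.05)
  start <- perturbation_params(K = 1.1, K11 = 300, P1 = 7, P2 = 30,
                               K12 = 60)
  res <- fit_perturbation(vara_model(), curve, start = start)
  # products are identifiable to 1%, rates to 5%
  expect_equal(res$params$K * res$params$K11, 1.1 * 450, tolerance = 0.01)
  expect_equal(res$params$K * res$params$K12, 1.1 * 80, tolerance = 0.01)
  expect_equal(res$params$P1, 10.1, tolerance = 0.05)
  expect_equal(res$params$P2, 19.6, tolerance = 0.05)
  expect_false(res$boundary_diagnostic)
  # optimum at least as good as the truth's own weighted loss
  pred <- simulate_tracer(attach_perturbation(vara_model(), truth), 1,
                          study_times())
  wss_truth <- weighted_wss(curve, pred)
  expect_lte(res$fit$wss, wss_truth * 1.05 + 1e-10)
})
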