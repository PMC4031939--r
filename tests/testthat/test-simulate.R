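test_that("single-pool decay matches the closed form", {
  m <- single_pool(lambda = 2)
  t <- c(0.1, 0.5, 1, 2, 3)
  cv <- simulate_tracer(m, 1, t, rtol = 1e-10, atol = 1e-14)
  expect_equal(cv$fraction_of_dose, exp(-2 * t), tolerance = 1e-8)
})

test_that("mass is conserved in a closed exchange system", {
  m <- closed_two_pool()
  t <- seq(0.01, 5, length.out = 40)
  cont <- simulate_contents(m, 1, t, rtol = 1e-11, atol = 1e-14)
  total <- cont$q5 + cont$q6 + cont$loss
  expect_true(all(abs(total - 1) < 1e-9))
  expect_true(all(abs(cont$loss) < 1e-12))
})

test_that("mass balance holds with delays when losses are removed", {
  # full oral topology, all losses to the outside removed
  m <- compartmental_model(
    compartments = c(1L, 2L, 10L, 4L, 5L, 6L),
    coefficients = data.frame(
      to    = c(2L, 5L, 3L, 15L, 5L, 6L, 5L),
      from  = c(1L, 2L, 2L, 10L, 4L, 5L, 6L),
      value = c(5.09, 0.44, 18.6, 82.6, 5.06, 60.3, 0.60)),
    delays = data.frame(id = c(3L, 15L), duration = c(0.005, 0.005),
                        downstream = c(10L, 4L)),
    input = 1L, observation = c(5L, 10L))
  t <- c(0.003, 0.006, 0.05, 0.2, 1, 5, 10)
  cont <- simulate_contents(m, 1, t, rtol = 1e-11, atol = 1e-14)
  total <- rowSums(cont[, c("q1", "q2", "q10", "q4", "q5", "q6",
                            "delay3", "delay15", "loss")])
  expect_true(all(abs(total - 1) < 1e-9))
})

test_that("simulation is linear in the dose", {
  m <- oil_model()
  t <- study_times()
  c1 <- simulate_tracer(m, 0.5, t)
  c2 <- simulate_tracer(m, 1, t)
  expect_equal(2 * c1$fraction_of_dose, c2$fraction_of_dose,
               tolerance = 1e-9)
})

test_that("contents are continuous across the interrupt switch", {
  m <- oil_model()
  eps <- 1e-6
  cont <- simulate_contents(m, 1, c(8 - eps, 8 + eps), rtol = 1e-10,
                            atol = 1e-14)
  expect_equal(cont$q5[2], cont$q5[1], tolerance = 1e-5)
  expect_equal(cont$q6[2], cont$q6[1], tolerance = 1e-5)
  # but the observed slope steepens: day 9-10 decline much faster than 6-7
  cv <- simulate_tracer(m, 1, c(6, 7, 9, 10))
  drop_before <- log(cv$fraction_of_dose[1] / cv$fraction_of_dose[2])
  drop_after <- log(cv$fraction_of_dose[3] / cv$fraction_of_dose[4])
  expect_gt(drop_after, 10 * drop_before)
})

test_that("nothing emerges downstream of a delay before its duration", {
  d <- 0.4
  m <- compartmental_model(
    compartments = c(1L, 2L),
    coefficients = data.frame(to = c(3L, 0L), from = c(1L, 2L),
                              value = c(5, 1)),
    delays = data.frame(id = 3L, duration = d, downstream = 2L),
    input = 1L, observation = 2L)
  t <- c(0.1, 0.2, 0.39, 0.41, 0.6, 1)
  cont <- simulate_contents(m, 1, t, rtol = 1e-10, atol = 1e-14)
  expect_true(all(cont$q2[t < d] == 0))
  expect_true(all(cont$q2[t > d + 0.01] > 0))
  # in-transit mass is bounded by what has entered
  expect_true(all(cont$delay3 >= 0 & cont$delay3 <= 1 + 1e-9))
})

test_that("adaptive solution matches an independent fixed-step integrator", {
  cv <- simulate_tracer(oil_model(), 1, study_times())
  oracle <- rk4_oral_curve(oracle_oil_params(), study_times(), h = 0.002)
  expect_equal(cv$fraction_of_dose, oracle, tolerance = 1e-3)
})

test_that("invalid simulation inputs are rejected", {
  m <- oil_model()
  expect_error(simulate_tracer(m, 1, c(2, 1)), "non-increasing")
  expect_error(simulate_tracer(m, 0, 1:3), "dose_fraction")
  expect_error(simulate_contents(m, 1, c(1, 2), start_compartment = 99),
               "start compartment")
  expect_error(impulse_response(m, 5L, horizon = -1), "horizon")
})
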