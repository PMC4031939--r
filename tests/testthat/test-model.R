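test_that("rate matrix entries reflect the coefficient table and interrupt", {
  m <- oil_model()
  A1 <- build_rate_matrix(m, t = 1)
  expect_equal(A1["6", "5"], 60.3)
  expect_equal(A1["5", "6"], 0.60)
  expect_equal(A1["6", "6"], -(0.60 + 0.004))
  # loss interrupt has fired by day 10
  A10 <- build_rate_matrix(m, t = 10)
  expect_equal(A10["6", "6"], -(0.60 + 0.197))
  expect_equal(A10["6", "5"], 60.3)
  # column sums: only compartments with a loss or delay routing leak mass
  # compartment 5 feeds only compartment 6
  expect_equal(sum(A1[, "5"]), 0)
})

test_that("a single-compartment model yields a 1x1 decay matrix", {
  m <- single_pool(lambda = 0.7)
  A <- build_rate_matrix(m)
  expect_equal(dim(A), c(1L, 1L))
  expect_equal(A[1, 1], -0.7)
})

test_that("model validation rejects malformed definitions", {
  cf <- data.frame(to = 0L, from = 1L, value = 1)
  expect_error(compartmental_model(1L, data.frame(to = 0L, from = 1L,
                                                  value = -1)),
               "negative")
  expect_error(compartmental_model(1L, data.frame(to = 1L, from = 1L,
                                                  value = 1)),
               "itself")
  expect_error(compartmental_model(1L, rbind(cf, cf)), "more than once")
  expect_error(compartmental_model(1L, data.frame(to = 0L, from = 2L,
                                                  value = 1)),
               "unknown source")
  expect_error(compartmental_model(1L, cf, observation = 9L), "observation")
  expect_error(compartmental_model(
    1L, cf, delays = data.frame(id = 3L, duration = -1, downstream = 1L)),
    "duration")
})

test_that("coefficient labels round-trip through update and extraction", {
  m <- oil_model()
  labs <- c("L(6,5)", "L(0,6)pre", "L(0,6)post", "DT(3)")
  vals <- c(55, 0.01, 0.3, 0.02)
  m2 <- update_model(m, labs, vals)
  expect_equal(unname(coef_by_label(m2, labs)), vals)
  expect_equal(coef_value(m2, 6L, 5L, 1), 55)
  expect_equal(coef_value(m2, 0L, 6L, 1), 0.01)
  expect_equal(coef_value(m2, 0L, 6L, 9), 0.3)
  expect_error(update_model(m, "L(9,9)", 1), "no constant coefficient")
  expect_error(update_model(m, "bogus", 1), "unrecognized")
})

test_that("model definition files round-trip losslessly", {
  m <- oil_model()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_yaml(m, path)
  m2 <- read_model_yaml(path)
  expect_equal(m2$compartments, m$compartments)
  expect_equal(m2$coefficients$value, m$coefficients$value)
  expect_equal(m2$coefficients$fixed, m$coefficients$fixed)
  expect_equal(m2$delays$duration, m$delays$duration)
  expect_equal(m2$interrupts$value_after, m$interrupts$value_after)
  expect_equal(m2$observation, m$observation)
  expect_equal(m2$group, m$group)
  # simulated behavior identical
  t <- study_times()
  expect_equal(simulate_tracer(m2, 1, t)$fraction_of_dose,
               simulate_tracer(m, 1, t)$fraction_of_dose, tolerance = 1e-12)
})

test_that("tracer curve CSV round-trips and validates", {
  cv <- tracer_curve(c(0.1, 0.5, 2), c(0.03, 0.02, 0.01), group = "oil")
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracer_csv(cv, path)
  cv2 <- read_tracer_csv(path, "oil")
  expect_equal(cv2$time_days, cv$time_days)
  expect_equal(cv2$fraction_of_dose, cv$fraction_of_dose)
  # shuffled time column is rejected with row information
  bad <- read.csv(path)
  bad <- bad[c(2, 1, 3), ]
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_tracer_csv(path), "row")
  expect_error(tracer_curve(c(1, 1), c(0.1, 0.1)), "increasing")
  expect_error(tracer_curve(1, 1.5), "fraction")
})
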