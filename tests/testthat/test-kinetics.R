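# Closed-form kinetic calculus checked against hand arithmetic on the
# reference coefficient sets, plus numeric/analytic cross-checks.

test_that("plasma transit time is the reciprocal total exit rate", {
  expect_equal(transit_time(oil_model(), 5L) * 24, 24 / 60.3,
               tolerance = 1e-12)
  expect_equal(round(transit_time(oil_model(), 5L) * 24, 2), 0.40)
  expect_equal(round(transit_time(vara_model(), 5L) * 24, 2), 0.14)
  # any compartment with a single unit exit rate: one day
  expect_equal(transit_time(single_pool(1), 1L), 1)
  expect_error(transit_time(plasma_block(L65 = 0, L56 = 0, L06 = 0), 5L),
               "zero total exit rate")
})

test_that("plasma residence time follows the visit calculus", {
  T55 <- residence_time_plasma(oil_model())
  expect_named(T55, c("before", "after"))
  expect_equal(unname(T55["before"]), ((0.60 + 0.004) / 0.004) / 60.3,
               tolerance = 1e-12)
  expect_equal(unname(T55["before"]), 2.504, tolerance = 1e-3)
  # post-interrupt segment: FCR near the published 14.7/day
  expect_equal(1 / unname(T55["after"]), 14.90, tolerance = 1e-3)
  # no recycling limit: residence equals single transit
  expect_equal(residence_time_plasma(plasma_block(L56 = 0, L06 = 0.1)),
               1 / 60.3)
  # no irreversible exit: infinite with warning
  expect_warning(
    out <- residence_time_plasma(plasma_block(L06 = 0)), "infinite")
  expect_identical(out, Inf)
})

test_that("recycling numbers reproduce the reference values", {
  expect_equal(recycling_number(2.40, 0.40 / 24), 144)
  expect_equal(recycling_number(0.60, 0.14 / 24), 102.857, tolerance = 1e-4)
  expect_equal(recycling_number(1.5, 1.5), 1)
  expect_error(recycling_number(1, 0), "transit")
})

test_that("pool mass, turnover and disposal close the published loop", {
  expect_equal(plasma_pool_mass(1.0, 10), 0.35)
  # day-11 turnover 117 nmol/day corresponds to M(5) = 117/60.3 nmol,
  # which a 45 g pup reaches at 1.234 umol/L
  M5 <- plasma_pool_mass(117 / 60.3 / (45 * 0.035), 45)
  expect_equal(turnover_rate(M5, 60.3), 117)
  expect_error(plasma_pool_mass(0, 10), "> 0")
  # disposal under the compartment-6 steady-state split
  expect_equal(disposal_rate(117, 0.197, 0.60), 28.92, tolerance = 1e-3)
  expect_equal(disposal_rate(42.3, 0.004, 0.60), 0.280, tolerance = 1e-2)
  expect_equal(disposal_rate(10, 0.5, 0), 10)   # no return path: all lost
  expect_error(disposal_rate(10, 0, 0), "> 0")
  expect_equal(turnover_rate(0, 60.3), 0)
})

test_that("disposal never exceeds turnover and responds to the loss rate", {
  for (L06 in c(0.001, 0.01, 0.1, 1, 10))
    expect_lte(disposal_rate(50, L06, 0.6), 50)
  # increasing the loss coefficient strictly decreases residence time
  # and recycling number
  T55 <- vapply(c(0.004, 0.04, 0.4), function(L06)
    residence_time_plasma(plasma_block(L06 = L06)), numeric(1))
  expect_true(all(diff(T55) < 0))
  nu <- recycling_number(T55, 1 / 60.3)
  expect_true(all(diff(nu) < 0))
})

test_that("body-weight scaling of the disposal rate is linear per gram", {
  expect_equal(scale_disposal_to_body_weight(20, 45, 3500), 20 / 45 * 3.5,
               tolerance = 1e-12)
  expect_equal(round(scale_disposal_to_body_weight(20, 45, 3500), 2), 1.56)
  expect_equal(round(scale_disposal_to_body_weight(30, 45, 3500), 2), 2.33)
  expect_equal(scale_disposal_to_body_weight(7, 45, 45), 0.007)
  expect_error(scale_disposal_to_body_weight(1, 0, 10), "> 0")
})

test_that("closed-form residence time matches the impulse-response integral", {
  # pre-day-8 coefficients held constant (no interrupt); the slow
  # eigenvalue is ~0.004/day, so the horizon must span ~2000 days for the
  # integral to converge to 0.1%
  m <- plasma_block(L65 = 60.3, L56 = 0.60, L06 = 0.004)
  ir <- impulse_response(m, 5L, horizon = 2000)
  expect_equal(residence_integral(ir, 5L), residence_time_plasma(m),
               tolerance = 1e-3)
  # single pool at lambda = 2/day integrates to 1/2 day
  ir1 <- impulse_response(single_pool(2), 1L, horizon = 20)
  expect_equal(residence_integral(ir1, 1L), 0.5, tolerance = 1e-4)
  # loss-free system: divergence is reported
  irc <- impulse_response(closed_two_pool(), 5L, horizon = 5)
  expect_error(residence_integral(irc, 5L), "diverges")
})

test_that("kinetic summary is internally consistent", {
  ks <- kinetic_summary(oil_model())
  expect_equal(ks$fcr_per_day * ks$T55_days, c(before = 1, after = 1))
  expect_equal(ks$nu5, ks$T55_days / (ks$t5_h / 24))
  expect_true(all(unlist(ks[c("t5_h", "t6_days", "T55_days",
                              "fcr_per_day", "nu5")]) >= 0))
  df <- as.data.frame(ks)
  expect_equal(nrow(df), 2)
  expect_equal(df$fcr_per_day, unname(ks$fcr_per_day))
  # vara model has no interrupt: single-segment summary
  ksv <- kinetic_summary(vara_model())
  expect_length(ksv$T55_days, 1)
  expect_equal(ksv$T55_days, ((0.83 + 0.008) / 0.008) / 169.4)
})

test_that("disposal table uses the coefficient segment active at each time", {
  m <- oil_model()
  tab <- disposal_table(m, c(4, 11), retinol_conc_uM = c(1.2, 1.234),
                        body_weight_g = c(17.8, 45))
  # pre-interrupt row uses L(0,6) = 0.004, post uses 0.197
  expect_equal(tab$dr_nmol_day[1] / tab$turnover_nmol_day[1],
               0.004 / 0.604, tolerance = 1e-12)
  expect_equal(tab$dr_nmol_day[2] / tab$turnover_nmol_day[2],
               0.197 / 0.797, tolerance = 1e-12)
  expect_equal(tab$turnover_nmol_day[2], 60.3 * plasma_pool_mass(1.234, 45))
})
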