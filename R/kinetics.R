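# Derived kinetic calculus: transit/residence times, recycling numbers,
# fractional catabolic and disposal rates, traced masses and transfer rates,
# computed in closed form from fractional transfer coefficients.

#' Mean transit time of a compartment
#'
#' Mean of the distribution of times a retinol molecule entering the
#' compartment spends there during a single pass before leaving (reversibly
#' or irreversibly): the reciprocal of the summed fractional exit rates.
#'
#' @param model a [compartmental_model()].
#' @param compartment compartment id.
#' @param t evaluation time, days (resolves interrupts/hooks).
#' @return transit time in days.
#' @export
transit_time <- function(model, compartment, t = 0) {
  if (!compartment %in% model$compartments) stop("unknown compartment id")
  pairs <- .all_pairs(model)
  exits <- pairs[pairs$from == compartment, , drop = FALSE]
  if (!nrow(exits)) stop("compartment has no exit coefficient")
  tot <- sum(vapply(seq_len(nrow(exits)), function(i)
    coef_value(model, exits$to[i], exits$from[i], t), numeric(1)))
  if (tot <= 0) stop("zero total exit rate")
  1 / tot
}

#' Mean residence time of retinol in plasma
#'
#' Average total time a retinol molecule spends in the plasma retinol-RBP
#' compartment (5) before irreversible loss, for the exchange topology
#' 5 <-> 6 with sole irreversible exit L(0,6) from the extravascular pool:
#' the expected number of plasma visits, \eqn{(L(5,6)+L(0,6))/L(0,6)},
#' times the per-visit duration \eqn{1/L(6,5)}. When L(0,6) carries a time
#' interrupt, one value is returned per coefficient segment.
#'
#' @param model a [compartmental_model()] with the 5/6 exchange block.
#' @return named numeric vector of residence times in days (one element,
#'   or `before`/`after` when an interrupt exists). `Inf` with a warning
#'   when L(0,6) = 0 (no irreversible exit).
#' @export
residence_time_plasma <- function(model) {
  L65 <- coef_value(model, 6L, 5L, 0)
  L56 <- coef_value(model, 5L, 6L, 0)
  ir <- model$interrupts
  i <- which(ir$to == 0L & ir$from == 6L)
  one <- function(L06) {
    if (L06 == 0) {
      warning("L(0,6) = 0: no irreversible exit, residence time is infinite")
      return(Inf)
    }
    ((L56 + L06) / L06) / L65
  }
  if (length(i)) {
    c(before = one(ir$value_before[i]), after = one(ir$value_after[i]))
  } else {
    one(coef_value(model, 0L, 6L, 0))
  }
}

#' Recycling number
#'
#' Average number of passes a retinol molecule makes through a compartment
#' before irreversible loss: residence time divided by single-pass transit
#' time, both in the same unit.
#'
#' @param T_res mean residence time, days.
#' @param t_transit mean transit time, days.
#' @return dimensionless recycling number.
#' @export
recycling_number <- function(T_res, t_transit) {
  if (any(t_transit <= 0)) stop("transit time must be > 0")
  if (any(T_res < 0)) stop("residence time must be >= 0")
  T_res / t_transit
}

#' Plasma retinol pool mass
#'
#' Traced mass M(5) from the plasma retinol concentration and the estimated
#' plasma volume (0.035 ml plasma per g body weight). With concentration in
#' umol/L (= nmol/ml) and volume in ml the product is directly in nmol.
#'
#' @param retinol_conc_uM plasma retinol concentration, umol/L.
#' @param body_weight_g pup body weight, g.
#' @param plasma_ml_per_g plasma volume factor, ml/g.
#' @return pool mass, nmol.
#' @export
plasma_pool_mass <- function(retinol_conc_uM, body_weight_g,
                             plasma_ml_per_g = 0.035) {
  if (any(retinol_conc_uM <= 0) || any(body_weight_g <= 0))
    stop("concentration and body weight must be > 0")
  retinol_conc_uM * body_weight_g * plasma_ml_per_g
}

#' Plasma retinol turnover rate
#'
#' R(6,5): retinol mass transferred from plasma (compartment 5) to the
#' extravascular pool (compartment 6) per day, \eqn{L(6,5) \times M(5)}.
#'
#' @param M5_nmol plasma pool mass, nmol.
#' @param L65 plasma-to-tissue transfer coefficient, per day.
#' @return turnover, nmol/day.
#' @export
turnover_rate <- function(M5_nmol, L65) {
  if (any(M5_nmol < 0) || any(L65 < 0)) stop("inputs must be >= 0")
  L65 * M5_nmol
}

#' Retinol disposal rate
#'
#' R(0,6): retinol irreversibly lost from the extravascular pool per day.
#' Under quasi-steady state of compartment 6 (inflow = outflow) the loss is
#' the fraction \eqn{L(0,6)/(L(5,6)+L(0,6))} of the plasma turnover.
#'
#' @param R65_nmol_day turnover rate R(6,5), nmol/day.
#' @param L06,L56 loss and return coefficients of the extravascular pool,
#'   per day, taken from the coefficient segment active at the evaluation
#'   time.
#' @return disposal rate, nmol/day.
#' @export
disposal_rate <- function(R65_nmol_day, L06, L56) {
  if (any(L06 + L56 <= 0)) stop("L(5,6) + L(0,6) must be > 0")
  R65_nmol_day * L06 / (L56 + L06)
}

#' Scale a disposal rate to another body weight
#'
#' Linear per-gram scaling of an absolute disposal rate (e.g. from a 45 g
#' rat pup to a 3.5 kg human infant), converted from nmol/day to umol/day.
#'
#' @param dr_nmol_day disposal rate, nmol/day.
#' @param bw_from_g,bw_to_g body weights, g.
#' @return scaled disposal rate, umol/day.
#' @export
scale_disposal_to_body_weight <- function(dr_nmol_day, bw_from_g, bw_to_g) {
  if (any(bw_from_g <= 0) || any(bw_to_g <= 0))
    stop("body weights must be > 0")
  dr_nmol_day * (bw_to_g / bw_from_g) / 1000
}

#' Summarize the derived kinetic parameters of a fitted model
#'
#' Computes the plasma and extravascular transit times, the plasma
#' residence time(s), fractional catabolic rate(s) (reciprocal of the
#' residence time) and recycling number(s) from a model's coefficients.
#' When L(0,6) carries a time interrupt, segment-resolved values are
#' reported (before/after the switch), mirroring the two-segment loss.
#'
#' @param model a [compartmental_model()].
#' @return object of class `kinetic_summary`: list with `t5_h`, `t6_days`
#'   (per segment when interrupted), `T55_days`, `fcr_per_day`, `nu5` and
#'   the group label.
#' @export
kinetic_summary <- function(model) {
  t5 <- transit_time(model, 5L)
  T55 <- residence_time_plasma(model)
  L56 <- coef_value(model, 5L, 6L, 0)
  ir <- model$interrupts
  i <- which(ir$to == 0L & ir$from == 6L)
  t6 <- if (length(i)) {
    c(before = 1 / (L56 + ir$value_before[i]),
      after = 1 / (L56 + ir$value_after[i]))
  } else 1 / (L56 + coef_value(model, 0L, 6L, 0))
  structure(list(group = model$group,
                 t5_h = t5 * 24,
                 t6_days = t6,
                 T55_days = T55,
                 fcr_per_day = 1 / T55,
                 nu5 = recycling_number(T55, t5)),
            class = "kinetic_summary")
}

#' @export
print.kinetic_summary <- function(x, ...) {
  cat(sprintf("Kinetic summary (%s)\n", x$group))
  fmt <- function(v) paste(sprintf("%.3g", v), collapse = " / ")
  cat("  t(5)      ", fmt(x$t5_h), "h\n")
  cat("  t(6)      ", fmt(x$t6_days), "days\n")
  cat("  T(5,5)    ", fmt(x$T55_days), "days\n")
  cat("  FCR(5,5)  ", fmt(x$fcr_per_day), "per day\n")
  cat("  nu(5)     ", fmt(x$nu5), "\n")
  invisible(x)
}

#' @export
as.data.frame.kinetic_summary <- function(x, ...) {
  seg <- function(v) if (length(v) == 2) v else c(v, v)
  data.frame(group = x$group,
             segment = c("before_day8", "after_day8"),
             t5_h = rep(x$t5_h, 2),
             t6_days = seg(x$t6_days),
             T55_days = seg(x$T55_days),
             fcr_per_day = seg(x$fcr_per_day),
             nu5 = seg(x$nu5),
             row.names = NULL)
}

#' Per-time disposal and turnover table
#'
#' Tabulates the traced plasma mass M(5), the turnover rate R(6,5) and the
#' disposal rate R(0,6) at each sampling time, using the coefficient
#' segment active at that time.
#'
#' @param model a [compartmental_model()] with the 5/6 block.
#' @param times sampling times, days.
#' @param retinol_conc_uM plasma retinol concentration at each time, umol/L.
#' @param body_weight_g body weight at each time, g.
#' @return data.frame with columns `time_days`, `M5_nmol`,
#'   `turnover_nmol_day`, `dr_nmol_day`.
#' @export
disposal_table <- function(model, times, retinol_conc_uM, body_weight_g) {
  L65 <- vapply(times, function(t) coef_value(model, 6L, 5L, t), numeric(1))
  L56 <- vapply(times, function(t) coef_value(model, 5L, 6L, t), numeric(1))
  L06 <- vapply(times, function(t) coef_value(model, 0L, 6L, t), numeric(1))
  M5 <- plasma_pool_mass(retinol_conc_uM, body_weight_g)
  R65 <- turnover_rate(M5, L65)
  data.frame(time_days = times, M5_nmol = M5, turnover_nmol_day = R65,
             dr_nmol_day = disposal_rate(R65, L06, L56))
}

#' Write a kinetic summary report
#'
#' Flat CSV with units in the column headers.
#'
#' @param summary a [kinetic_summary()].
#' @param path output CSV.
#' @export
write_kinetic_summary <- function(summary, path) {
  utils::write.csv(as.data.frame(summary), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
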