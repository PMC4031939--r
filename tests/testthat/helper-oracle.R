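# Independent fixed-step RK4 integrator for the full oral-dose topology,
# with the two transport delays handled by linear interpolation on the
# stored solution history. Hand-coded equations (not the package's system
# assembly), used as a cross-solver oracle.
#
# p: list with L21, L02, L52, L32, L1510, L54, L65 (value or function of t),
#    L56, L06 (function of t), DT3, DT15.
# Returns fraction-of-dose (q10 + q5) at the requested times.
rk4_oral_curve <- function(p, times, h = 0.002, dose = 1) {
  horizon <- max(times)
  nstep <- ceiling(horizon / h)
  grid <- seq(0, by = h, length.out = nstep + 1)
  hist <- matrix(0, nstep + 1, 6)  # q1 q2 q10 q4 q5 q6
  hist[1, ] <- c(dose, 0, 0, 0, 0, 0)

  L65 <- if (is.function(p$L65)) p$L65 else function(t) p$L65
  L06 <- if (is.function(p$L06)) p$L06 else function(t) p$L06

  lagval <- function(t, col, upto) {
    if (t <= 0) return(0)
    i <- floor(t / h) + 1
    if (i >= upto) i <- upto - 1
    w <- (t - grid[i]) / h
    (1 - w) * hist[i, col] + w * hist[i + 1, col]
  }

  deriv <- function(t, y, upto) {
    lag2 <- lagval(t - p$DT3, 2, upto)
    lag10 <- lagval(t - p$DT15, 3, upto)
    c(-p$L21 * y[1],
      p$L21 * y[1] - (p$L02 + p$L52 + p$L32) * y[2],
      p$L32 * lag2 - p$L1510 * y[3],
      p$L1510 * lag10 - p$L54 * y[4],
      p$L52 * y[2] + p$L54 * y[4] + p$L56 * y[6] - L65(t) * y[5],
      L65(t) * y[5] - (p$L56 + L06(t)) * y[6])
  }

  for (s in seq_len(nstep)) {
    t <- grid[s]; y <- hist[s, ]
    k1 <- deriv(t, y, s + 1)
    k2 <- deriv(t + h / 2, y + h / 2 * k1, s + 1)
    k3 <- deriv(t + h / 2, y + h / 2 * k2, s + 1)
    k4 <- deriv(t + h, y + h * k3, s + 1)
    hist[s + 1, ] <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }

  vapply(times, function(tt) {
    i <- floor(tt / h) + 1
    if (i > nstep) i <- nstep
    w <- (tt - grid[i]) / h
    (1 - w) * (hist[i, 3] + hist[i, 5]) + w * (hist[i + 1, 3] + hist[i + 1, 5])
  }, numeric(1))
}

# Table-style oil parameter list matching the shipped reference model.
oracle_oil_params <- function() {
  list(L21 = 5.09, L02 = 0.43, L52 = 0.44, L32 = 18.6, L1510 = 82.6,
       L54 = 5.06, L65 = 60.3, L56 = 0.60,
       L06 = function(t) if (t <= 8) 0.004 else 0.197,
       DT3 = 0.005, DT15 = 0.005)
}

# Small closed two-pool exchange model (5 <-> 6), no losses, no delays.
closed_two_pool <- function(L65 = 60.3, L56 = 0.60) {
  compartmental_model(
    compartments = c(5L, 6L),
    coefficients = data.frame(to = c(6L, 5L), from = c(5L, 6L),
                              value = c(L65, L56)),
    input = 5L, observation = 5L, group = "closed")
}

# Single-pool decay model with loss rate lambda.
single_pool <- function(lambda = 2) {
  compartmental_model(
    compartments = 1L,
    coefficients = data.frame(to = 0L, from = 1L, value = lambda),
    input = 1L, observation = 1L, group = "single")
}

# Plasma/extravascular exchange block with irreversible loss, no delays.
plasma_block <- function(L65 = 60.3, L56 = 0.60, L06 = 0.004) {
  compartmental_model(
    compartments = c(5L, 6L),
    coefficients = data.frame(to = c(6L, 5L, 0L), from = c(5L, 6L, 6L),
                              value = c(L65, L56, L06)),
    input = 5L, observation = 5L, group = "block")
}
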