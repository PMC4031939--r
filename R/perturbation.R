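# Nonsteady-state VARA model: a time-varying plasma-to-tissue uptake
# coefficient L(6,5)(T) = K * [K11 * (exp(-P1 T) - exp(-P2 T)) + K12],
# a transient pulse (difference of exponentials) on a constant baseline.

#' Parameters of the time-varying uptake coefficient
#'
#' The five constants of
#' \eqn{L(6,5)(T) = K [K_{11} (e^{-P_1 T} - e^{-P_2 T}) + K_{12}]}:
#' overall scale `K` (dimensionless), pulse amplitude `K11` (per day),
#' rise/decay rates `P1 < P2` (per day) and baseline `K12` (per day).
#' Only the products K*K11 and K*K12 enter the rate, so K is conventionally
#' fixed (at 1.1 in the published fit) and the pulse and baseline absorb
#' the scale.
#'
#' @param K,K11,P1,P2,K12 the constants; defaults are the published VARA
#'   estimates.
#' @return object of class `perturbation_params`.
#' @export
perturbation_params <- function(K = 1.1, K11 = 450, P1 = 10.1, P2 = 19.6,
                                K12 = 80) {
  if (K < 0 || K11 < 0 || K12 < 0) stop("K, K11, K12 must be >= 0")
  if (K11 > 0 && !(P2 > P1 && P1 > 0))
    stop("pulse rates must satisfy P2 > P1 > 0")
  structure(list(K = K, K11 = K11, P1 = P1, P2 = P2, K12 = K12),
            class = "perturbation_params")
}

#' @export
print.perturbation_params <- function(x, ...) {
  cat(sprintf("L(6,5)(T) = %.4g x [%.4g (e^-%.4gT - e^-%.4gT) + %.4g]\n",
              x$K, x$K11, x$P1, x$P2, x$K12))
  pk <- pulse_peak(x)
  cat(sprintf("  baseline/asymptote %.4g per day; peak %.4g per day at %.4g d\n",
              x$K * x$K12, pk$value, pk$time))
  invisible(x)
}

#' Evaluate the time-varying uptake coefficient
#'
#' @param p a [perturbation_params()].
#' @param T time after dose, days (vectorized, must be >= 0).
#' @return L(6,5) at each time, per day.
#' @export
l65_of_t <- function(p, T) {
  if (any(T < 0)) stop("negative time")
  p$K * (p$K11 * (exp(-p$P1 * T) - exp(-p$P2 * T)) + p$K12)
}

#' Peak of the uptake pulse
#'
#' Closed form: the difference of exponentials peaks at
#' \eqn{\ln(P_2/P_1)/(P_2 - P_1)}. A flat function (`K11 = 0`) reports its
#' baseline at time 0.
#'
#' @param p a [perturbation_params()].
#' @return list with `time` (days) and `value` (per day).
#' @export
pulse_peak <- function(p) {
  if (p$K11 == 0) return(list(time = 0, value = p$K * p$K12))
  if (p$P2 <= p$P1) stop("pulse rates must satisfy P2 > P1")
  tpk <- log(p$P2 / p$P1) / (p$P2 - p$P1)
  list(time = tpk, value = l65_of_t(p, tpk))
}

#' Attach the time-varying uptake coefficient to a model
#'
#' Replaces the constant L(6,5) (if present) with a hook evaluating the
#' perturbation equation, turning the constant-coefficient model into the
#' nonsteady-state one.
#'
#' @param model a [compartmental_model()].
#' @param p a [perturbation_params()].
#' @return the model with the hook attached and `p` stored as
#'   `$perturbation`.
#' @export
attach_perturbation <- function(model, p) {
  stopifnot(inherits(p, "perturbation_params"))
  i <- which(model$coefficients$to == 6L & model$coefficients$from == 5L)
  if (length(i)) model$coefficients <- model$coefficients[-i, ]
  model$tv_hooks[[.pair_key(6L, 5L)]] <-
    list(to = 6L, from = 5L, fn = function(t) l65_of_t(p, t))
  model$perturbation <- p
  model
}

#' Tabulate the uptake coefficient at the study times
#'
#' @param p a [perturbation_params()].
#' @param times tabulation times, days (default the 14 study times).
#' @return data.frame with columns `time_days`, `l65_per_day`.
#' @export
perturbation_table <- function(p, times = study_times()) {
  data.frame(time_days = times, l65_per_day = l65_of_t(p, times))
}

#' Fit the nonsteady-state uptake model to a VARA tracer curve
#'
#' Jointly estimates the perturbation constants (and optionally other free
#' transfer coefficients) by the same relative-error weighted criterion as
#' [fit_model()]. Because only the products K*K11 and K*K12 are structurally
#' identifiable, the fit is internally parameterized as
#' (A = K*K11, B = K*K12, P1, dP = P2 - P1) and the published five-constant
#' form is reported with K held at `fix_K`.
#'
#' @param model a [compartmental_model()] for the VARA topology (the
#'   constant L(6,5), if any, is replaced during fitting).
#' @param curve observed VARA [tracer_curve()].
#' @param start a [perturbation_params()] giving start values (default the
#'   published constants).
#' @param free_lij additional coefficient labels to free alongside the
#'   perturbation constants.
#' @param fix_K the conventional scale at which K is reported.
#' @param multistart,seed,rtol,maxiter as in [fit_model()].
#' @return list with `params` (a [perturbation_params()]), `fit` (estimates
#'   of the internal parameters with FSDs, wss, aic) and
#'   `boundary_diagnostic` (`TRUE` when the fitted pulse collapses,
#'   dP at the zero boundary).
#' @export
fit_perturbation <- function(model, curve, start = perturbation_params(),
                             free_lij = character(), fix_K = start$K,
                             multistart = 1, seed = NULL, rtol = 1e-8,
                             maxiter = 100) {
  times <- curve$time_days
  p0 <- c(A = start$K * start$K11, B = start$K * start$K12,
          P1 = start$P1, dP = start$P2 - start$P1)
  if (length(free_lij)) p0 <- c(p0, coef_by_label(model, free_lij))
  npert <- 4L

  build <- function(pars) {
    pp <- perturbation_params(K = 1, K11 = pars[1], P1 = pars[3],
                              P2 = pars[3] + pars[4] + 1e-12, K12 = pars[2])
    m2 <- attach_perturbation(model, pp)
    if (length(free_lij))
      m2 <- update_model(m2, free_lij, pars[-seq_len(npert)])
    m2
  }
  resid_fn <- function(pars) {
    pred <- simulate_tracer(build(pmax(pars, 0)), 1, times, rtol = rtol)
    .weighted_residuals(curve, pred$fraction_of_dose)
  }

  starts <- list(p0)
  if (multistart > 1) {
    if (!is.null(seed)) set.seed(seed)
    for (i in seq_len(multistart - 1))
      starts[[i + 1]] <- p0 * exp(stats::rnorm(length(p0), 0, 0.3))
  }
  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = s, lower = rep(0, length(s)), fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                           ftol = 1e-12, ptol = 1e-12,
                                           epsfcn = 1e-8)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  if (!best$info %in% 1:4)
    warning("perturbation fit did not meet convergence criteria: ",
            best$message)

  est <- pmax(best$par, 0)
  names(est) <- names(p0)
  n <- nrow(curve); k <- length(est)
  wss <- best$deviance
  J <- .num_jacobian(resid_fn, est)
  cov <- try(solve(crossprod(J)) * wss / (n - k), silent = TRUE)
  fsds <- if (inherits(cov, "try-error")) rep(NA_real_, k)
          else sqrt(pmax(diag(cov), 0)) / est
  names(fsds) <- names(est)

  boundary <- est[["dP"]] < 1e-8
  if (boundary)
    warning("fitted P2 <= P1 (pulse collapsed): boundary diagnostic")

  params <- perturbation_params(K = fix_K, K11 = est[["A"]] / fix_K,
                                P1 = est[["P1"]],
                                P2 = est[["P1"]] + max(est[["dP"]], 1e-9),
                                K12 = est[["B"]] / fix_K)
  list(params = params,
       fit = list(estimates = est, fsds = fsds, wss = wss,
                  n_obs = n, n_free = k,
                  aic = n * log(wss / n) + 2 * k,
                  converged = best$info %in% 1:4,
                  free_lij = if (length(free_lij))
                    est[-seq_len(npert)] else NULL),
       boundary_diagnostic = boundary)
}
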