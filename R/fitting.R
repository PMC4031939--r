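# Weighted nonlinear least squares estimation of fractional transfer
# coefficients against group-mean tracer curves, with fractional-SD
# reporting, nested-model comparison, between-group coefficient tests and
# the fixed-coefficient sensitivity analysis.

#' Weighted sum of squares between observed and predicted curves
#'
#' Relative-error weighting: each residual is divided by `fsd * y_obs`, so
#' a point predicted within its assigned fractional SD contributes about 1.
#'
#' @param observed,predicted [tracer_curve()]s on identical time grids.
#' @return the weighted sum of squares (dimensionless).
#' @export
weighted_wss <- function(observed, predicted) {
  if (nrow(observed) != nrow(predicted) ||
      any(abs(observed$time_days - predicted$time_days) > 1e-9))
    stop("observed and predicted curves are on different time grids")
  sum(.weighted_residuals(observed, predicted$fraction_of_dose)^2)
}

.weighted_residuals <- function(observed, predicted_values) {
  y <- observed$fraction_of_dose
  fsd <- observed$weight_fsd
  if (any(y == 0 & fsd > 0))
    stop("zero observation with relative weighting: weight undefined")
  (y - predicted_values) / (fsd * y)
}

#' Fit free coefficients of a compartmental model to a tracer curve
#'
#' Minimizes the relative-error weighted sum of squares over the named free
#' coefficients by bounded Levenberg-Marquardt (non-negativity enforced by
#' a lower bound of zero). Fractional standard deviations are computed from
#' the inverse curvature of the weighted residual surface at the optimum:
#' \eqn{cov = \hat\sigma^2 (J'J)^{-1}} with
#' \eqn{\hat\sigma^2 = WSS/(n-k)}, FSD = SE/estimate. A coefficient whose
#' curvature is singular is flagged unidentifiable (FSD `NA`).
#'
#' @param model a [compartmental_model()] providing topology and fixed
#'   coefficient values.
#' @param curve observed [tracer_curve()] (group means, fraction of dose).
#' @param free character vector of coefficient labels to estimate, e.g.
#'   `c("L(5,4)", "L(6,5)", "L(5,6)", "L(0,6)pre", "L(0,6)post")`.
#' @param start named or unnamed numeric start values (defaults to the
#'   model's current values for the free labels).
#' @param multistart number of seeded random restarts (log-normal jitter
#'   around `start`); 1 fits once from `start`.
#' @param seed RNG seed for multistart jitter.
#' @param rtol solver tolerance used inside the objective.
#' @param maxiter maximum Levenberg-Marquardt iterations per start.
#' @return object of class `retkin_fit`: estimates, fsds, covariance, wss,
#'   n_obs, n_free, aic, convergence flag, the fitted model.
#' @export
fit_model <- function(model, curve, free, start = NULL, multistart = 1,
                      seed = NULL, rtol = 1e-8, maxiter = 100) {
  if (!length(free)) stop("at least one free coefficient is required")
  if (is.null(start)) start <- coef_by_label(model, free)
  start <- as.numeric(start)
  if (length(start) != length(free)) stop("start length != free length")
  if (any(!is.finite(start)) || any(start < 0))
    stop("start values must be finite and non-negative")

  times <- curve$time_days
  # transfer coefficients may sit at zero; delay durations must stay
  # strictly positive
  lower <- ifelse(grepl("^DT\\(", free), 1e-6, 0)
  resid_fn <- function(pars) {
    m2 <- update_model(model, free, pmax(pars, lower))
    pred <- simulate_tracer(m2, 1, times, rtol = rtol)
    .weighted_residuals(curve, pred$fraction_of_dose)
  }

  starts <- list(start)
  if (multistart > 1) {
    if (!is.null(seed)) set.seed(seed)
    for (i in seq_len(multistart - 1))
      starts[[i + 1]] <- start * exp(stats::rnorm(length(start), 0, 0.5))
  }

  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = pmax(s, lower), lower = lower, fn = resid_fn,
      # epsfcn reflects the relative noise of the ODE objective, so the
      # finite-difference step stays above the solver's error floor
      control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                           ftol = 1e-12, ptol = 1e-12,
                                           epsfcn = 1e-8)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  converged <- best$info %in% 1:4
  if (!converged)
    warning("fit did not meet convergence criteria (nls.lm info = ",
            best$info, "): ", best$message)

  est <- pmax(best$par, lower)
  names(est) <- free
  n <- nrow(curve); k <- length(free)
  if (k >= n) stop("more free coefficients than observations")
  wss <- best$deviance
  J <- .num_jacobian(resid_fn, est)
  JtJ <- crossprod(J)
  sigma2 <- wss / (n - k)
  cov <- try(solve(JtJ) * sigma2, silent = TRUE)
  if (inherits(cov, "try-error")) {
    cov <- matrix(NA_real_, k, k)
    fsds <- rep(NA_real_, k)
    warning("singular curvature at optimum: FSDs unidentifiable")
  } else {
    fsds <- sqrt(pmax(diag(cov), 0)) / est
  }
  names(fsds) <- free
  dimnames(cov) <- list(free, free)

  structure(list(estimates = est, fsds = fsds, covariance = cov,
                 wss = wss, n_obs = n, n_free = k,
                 aic = n * log(wss / n) + 2 * k,
                 converged = converged,
                 group = attr(curve, "group"),
                 free = free,
                 model = update_model(model, free, est)),
            class = "retkin_fit")
}

# central-difference Jacobian of a residual function; the step is floored
# so it stays meaningful for estimates at (or near) the zero boundary and
# above the ODE objective's noise floor
.num_jacobian <- function(fn, pars, rel_step = 1e-3, min_step = 1e-5) {
  f0 <- fn(pars)
  J <- matrix(0, length(f0), length(pars))
  for (j in seq_along(pars)) {
    h <- max(abs(pars[j]) * rel_step, min_step)
    up <- pars; up[j] <- up[j] + h
    dn <- pars; dn[j] <- max(dn[j] - h, 0)
    J[, j] <- (fn(up) - fn(dn)) / (up[j] - dn[j])
  }
  J
}

#' @export
print.retkin_fit <- function(x, ...) {
  cat(sprintf("Weighted NLS fit (%s): wss = %.4g, n = %d, k = %d, AIC = %.2f%s\n",
              x$group, x$wss, x$n_obs, x$n_free, x$aic,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(data.frame(estimate = x$estimates, fsd = x$fsds,
                   identifiable = !is.na(x$fsds) & x$fsds < 0.5))
  invisible(x)
}

#' Compare nested fits by F-statistic and AIC
#'
#' Tests whether the added parameters of the bigger model are justified:
#' \eqn{F = [(WSS_s - WSS_b)/(k_b - k_s)] / [WSS_b/(n - k_b)]} with
#' AIC in the least-squares form \eqn{n \ln(WSS/n) + 2k}. The verdict is
#' "justified" only when the F-test rejects at 0.05 and the bigger model
#' lowers AIC by more than 2 units.
#'
#' @param fit_small,fit_big [fit_model()] results on the same data, the
#'   small model's free coefficients a strict subset of the big model's.
#' @return list with `F`, `p`, `dAIC` (big minus small) and `verdict`.
#' @export
compare_models <- function(fit_small, fit_big) {
  if (fit_small$n_obs != fit_big$n_obs)
    stop("fits are not on the same data")
  if (fit_big$n_free <= fit_small$n_free ||
      !all(fit_small$free %in% fit_big$free))
    stop("models are not nested (small must be a strict subset of big)")
  n <- fit_big$n_obs
  dk <- fit_big$n_free - fit_small$n_free
  Fstat <- ((fit_small$wss - fit_big$wss) / dk) /
    (fit_big$wss / (n - fit_big$n_free))
  p <- stats::pf(max(Fstat, 0), dk, n - fit_big$n_free, lower.tail = FALSE)
  dAIC <- fit_big$aic - fit_small$aic
  list(F = Fstat, p = p, dAIC = dAIC,
       verdict = if (p < 0.05 && dAIC < -2) "justified" else "not justified")
}

#' Between-group test of a transfer coefficient
#'
#' Unpaired t-statistic on two coefficient estimates reported with
#' fractional SDs: \eqn{t = (v_1 - v_2)/\sqrt{SEM_1^2 + SEM_2^2}} with
#' \eqn{SEM_i = v_i \times FSD_i}, referred to Student's t with the given
#' degrees of freedom (60 by default, the study's convention from
#' (3 pups/time x 14 times - 12 parameters) x 2 treatments).
#'
#' @param v1,v2 coefficient estimates.
#' @param fsd1,fsd2 their fractional SDs.
#' @param df degrees of freedom.
#' @return list with `t`, `p`, `significant` (two-sided, 0.05).
#' @export
group_coefficient_ttest <- function(v1, fsd1, v2, fsd2, df = 60) {
  if (any(c(fsd1, fsd2) < 0)) stop("FSDs must be >= 0")
  sem1 <- v1 * fsd1; sem2 <- v2 * fsd2
  if (sem1 == 0 && sem2 == 0) stop("both SEMs are zero: t undefined")
  t <- (v1 - v2) / sqrt(sem1^2 + sem2^2)
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, p = p, significant = p < 0.05)
}

#' Sensitivity of free estimates to fixed coefficients
#'
#' Scales each fixed coefficient by (1 - factor) and (1 + factor), refits
#' the free coefficients (warm-started at the reference estimates), and
#' reports the percent change of every free estimate relative to the
#' reference fit. A refit that fails to converge is recorded per row, not
#' fatal.
#'
#' @param model a [compartmental_model()].
#' @param curve observed [tracer_curve()].
#' @param fixed character labels of fixed coefficients to perturb.
#' @param free character labels of free coefficients (as in [fit_model()]).
#' @param factor perturbation fraction (0.5 scales by 0.5x and 1.5x).
#' @param ref_fit optional converged reference [fit_model()] result; fitted
#'   here if missing.
#' @param ... passed to [fit_model()].
#' @return data.frame with one row per (fixed coefficient, direction),
#'   percent change columns per free coefficient, and a `converged` flag;
#'   attribute `max_abs_pct` gives the per-free-coefficient maxima.
#' @export
sensitivity_to_fixed <- function(model, curve, fixed, free, factor = 0.5,
                                 ref_fit = NULL, ...) {
  if (factor < 0) stop("factor must be >= 0")
  if (is.null(ref_fit)) ref_fit <- fit_model(model, curve, free, ...)
  ref <- ref_fit$estimates
  base_vals <- coef_by_label(model, fixed)
  rows <- list()
  for (f in fixed) for (s in c(1 - factor, 1 + factor)) {
    m2 <- update_model(model, f, base_vals[f] * s)
    fit <- try(fit_model(m2, curve, free, start = ref, ...), silent = TRUE)
    ok <- !inherits(fit, "try-error") && fit$converged
    pct <- if (inherits(fit, "try-error")) rep(NA_real_, length(free))
           else 100 * (fit$estimates - ref) / ifelse(ref > 0, ref, NA_real_)
    rows[[length(rows) + 1]] <- data.frame(
      fixed_coefficient = f, scale = s, t(pct), converged = ok,
      check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  names(out)[3:(2 + length(free))] <- paste0("pct_change_", free)
  attr(out, "max_abs_pct") <- apply(
    abs(as.matrix(out[, paste0("pct_change_", free), drop = FALSE])),
    2, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  out
}

#' Write a fit report
#'
#' CSV with one row per coefficient (estimate, FSD, identifiability under
#' the FSD < 0.5 rule) and a JSON sidecar carrying the covariance matrix,
#' WSS and AIC.
#'
#' @param fit a [fit_model()] result.
#' @param path output CSV path; the sidecar gets extension `.json`.
#' @export
write_fit_report <- function(fit, path) {
  df <- data.frame(coefficient = fit$free,
                   group = fit$group,
                   estimate_per_day = fit$estimates,
                   fsd = fit$fsds,
                   identifiable = !is.na(fit$fsds) & fit$fsds < 0.5)
  utils::write.csv(df, path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(list(group = fit$group, wss = fit$wss,
                            n_obs = fit$n_obs, n_free = fit$n_free,
                            aic = fit$aic, converged = fit$converged,
                            covariance = fit$covariance),
                       side, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
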