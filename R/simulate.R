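# Forward solution of the delay-differential tracer system.
#
# State layout: real compartments (model order), then one in-transit mass
# state per delay element, then cumulative irreversible loss. Delays are
# pure transport lags: material entering a delay at time s emerges into the
# downstream compartment at s + duration, so the emergent flux needs the
# lagged source content, obtained from the integrator's stored history.

.assemble_system <- function(model) {
  ids <- model$compartments
  n <- length(ids)
  idx <- function(id) match(id, ids)

  # constant-coefficient part split into: rate matrix over real
  # compartments, per-delay inflow edges, and loss coefficients
  A <- matrix(0, n, n)
  loss_const <- numeric(n)
  delay_in <- vector("list", nrow(model$delays))  # per delay: (from_idx, value)
  if (nrow(model$delays)) names(delay_in) <- as.character(model$delays$id)
  cf <- model$coefficients
  for (k in seq_len(nrow(cf))) {
    to <- cf$to[k]; from <- cf$from[k]; v <- cf$value[k]
    j <- idx(from)
    A[j, j] <- A[j, j] - v
    if (to == 0L) {
      loss_const[j] <- loss_const[j] + v
    } else if (to %in% ids) {
      A[idx(to), j] <- A[idx(to), j] + v
    } else { # into a delay
      key <- as.character(to)
      delay_in[[key]] <- rbind(delay_in[[key]], c(j, v))
    }
  }
  if (nrow(model$delays)) {
    bad <- vapply(delay_in, is.null, TRUE)
    if (any(bad)) stop("delay element(s) with no inflow coefficient: ",
                       paste(names(delay_in)[bad], collapse = ", "))
  }

  # time-dependent pieces (interrupts, hooks); delay-inflow pairs must be
  # constant for the lagged-flux bookkeeping to stay exact
  td <- list()
  ir <- model$interrupts
  for (k in seq_len(nrow(ir))) {
    if (!(ir$to[k] %in% c(0L, ids)))
      stop("time interrupt on a delay-inflow coefficient is not supported")
    td[[length(td) + 1L]] <- list(
      from = idx(ir$from[k]),
      to = if (ir$to[k] == 0L) 0L else idx(ir$to[k]),
      fn = local({
        sw <- ir$switch_time[k]; vb <- ir$value_before[k]; va <- ir$value_after[k]
        function(t) if (t <= sw) vb else va
      }))
  }
  for (h in model$tv_hooks) {
    if (!(h$to %in% c(0L, ids)))
      stop("time-varying hook on a delay-inflow coefficient is not supported")
    td[[length(td) + 1L]] <- list(from = idx(h$from),
                                  to = if (h$to == 0L) 0L else idx(h$to),
                                  fn = h$fn)
  }

  nd <- nrow(model$delays)
  durations <- model$delays$duration
  downstream_idx <- if (nd) vapply(model$delays$downstream, idx, 0L) else integer()

  deriv <- function(t, y, parms) {
    q <- y[seq_len(n)]
    dq <- as.vector(A %*% q)
    dloss <- sum(loss_const * q)
    dd <- numeric(nd)
    for (d in seq_len(nd)) {
      edges <- delay_in[[d]]
      influx_now <- sum(edges[, 2] * q[edges[, 1]])
      tl <- t - durations[d]
      influx_lag <- if (tl > 1e-12) {
        s <- 0
        for (e in seq_len(nrow(edges)))
          s <- s + edges[e, 2] * deSolve::lagvalue(tl, edges[e, 1])
        s
      } else 0
      dq[downstream_idx[d]] <- dq[downstream_idx[d]] + influx_lag
      dd[d] <- influx_now - influx_lag
    }
    for (e in td) {
      v <- e$fn(t)
      if (v < 0) stop("time-dependent coefficient negative at t = ", t)
      flux <- v * q[e$from]
      dq[e$from] <- dq[e$from] - flux
      if (e$to == 0L) dloss <- dloss + flux else dq[e$to] <- dq[e$to] + flux
    }
    list(c(dq, dd, dloss))
  }

  list(deriv = deriv, n = n, nd = nd, ids = ids,
       state_names = c(paste0("q", ids),
                       if (nd) paste0("delay", model$delays$id), "loss"))
}

# internal event times the integration grid must contain
.event_times <- function(model, horizon) {
  ev <- c(model$interrupts$switch_time, model$delays$duration)
  if (nrow(model$delays) == 2)  # cascaded delays: second emergence
    ev <- c(ev, sum(model$delays$duration))
  ev[ev > 0 & ev < horizon]
}

#' Solve a model for the contents of every compartment
#'
#' Integrates the delay-differential tracer system from a bolus dose placed
#' in `start_compartment` at time zero and returns the content of every
#' compartment, the in-transit mass of every delay element, and the
#' cumulative irreversible loss, at the requested times.
#'
#' @param model a [compartmental_model()].
#' @param dose dose placed in `start_compartment` at t = 0 (fraction of
#'   ingested dose; the system is linear so any positive scale works).
#' @param times strictly increasing non-negative output times, days.
#' @param start_compartment where the bolus goes; defaults to the model's
#'   input site.
#' @param rtol,atol integrator tolerances.
#' @return data.frame with column `time` followed by one column per state.
#' @export
simulate_contents <- function(model, dose, times,
                              start_compartment = model$input,
                              rtol = 1e-8, atol = 1e-12) {
  if (any(diff(times) <= 0)) stop("non-increasing times")
  if (any(times < 0)) stop("negative times")
  if (!start_compartment %in% model$compartments)
    stop("start compartment not in model")
  sys <- .assemble_system(model)
  horizon <- max(times)
  events <- .event_times(model, horizon)
  grid <- sort(unique(round(c(0, times, events), 10)))
  y0 <- numeric(sys$n + sys$nd + 1L)
  y0[match(start_compartment, model$compartments)] <- dose
  # the derivative is discontinuous at interrupt switches and delay
  # emergences; declaring them as (identity) events restarts the
  # integrator there instead of letting the error test stall on the kink
  ev <- if (length(events))
    list(func = function(t, y, parms) y,
         time = sort(unique(round(events, 10))))
  out <- deSolve::dede(y0, grid, sys$deriv, parms = NULL,
                       rtol = rtol, atol = atol, events = ev)
  keep <- match(round(times, 10), out[, 1])
  if (anyNA(keep))
    stop("integration failed before reaching all requested times ",
         "(solver returned early)")
  res <- as.data.frame(out[keep, , drop = FALSE])
  names(res) <- c("time", sys$state_names)
  rownames(res) <- NULL
  res
}

#' Simulate the observed plasma tracer curve
#'
#' Forward solution of the model observed through its observation map (the
#' sum of the mapped compartments' contents, here plasma retinol-RBP plus
#' plasma chylomicron retinyl esters), as a fraction of the ingested dose.
#'
#' @inheritParams simulate_contents
#' @param dose_fraction bolus size as a fraction of the ingested dose,
#'   in (0, 1].
#' @return a [tracer_curve()] at the requested times.
#' @export
simulate_tracer <- function(model, dose_fraction = 1, times = study_times(),
                            rtol = 1e-8, atol = 1e-12) {
  if (dose_fraction <= 0 || dose_fraction > 1)
    stop("dose_fraction must be in (0, 1]")
  # the system is linear: solve once for a unit dose and scale, so that
  # doubling the dose doubles every output exactly
  res <- simulate_contents(model, 1, times, rtol = rtol, atol = atol)
  obs_cols <- paste0("q", model$observation)
  vals <- dose_fraction * rowSums(res[, obs_cols, drop = FALSE])
  tracer_curve(times, pmin(pmax(vals, 0), 1), group = model$group)
}

#' Impulse response of every compartment
#'
#' Places a unit tracer bolus in `start_compartment` at t = 0 and returns
#' all compartment contents on a dense grid covering the horizon. The grid
#' is fine over the first day (transients driven by the fast exchange
#' rates) and coarser thereafter.
#'
#' @inheritParams simulate_contents
#' @param start_compartment compartment receiving the unit impulse.
#' @param horizon length of the response, days; must exceed 0.
#' @param n_fine,n_coarse grid sizes for the first day and the remainder.
#' @return object of class `impulse_response`: list with `times`, the
#'   contents data.frame, and the model.
#' @export
impulse_response <- function(model, start_compartment, horizon,
                             n_fine = 4000, n_coarse = 8000,
                             rtol = 1e-8, atol = 1e-12) {
  if (horizon <= 0) stop("horizon must be > 0")
  t_split <- min(1, horizon / 2)
  times <- sort(unique(c(seq(0, t_split, length.out = n_fine),
                         seq(t_split, horizon, length.out = n_coarse))))
  cont <- simulate_contents(model, 1, times,
                            start_compartment = start_compartment,
                            rtol = rtol, atol = atol)
  structure(list(times = cont$time, contents = cont, model = model),
            class = "impulse_response")
}

#' Time-integral of a compartment's impulse response
#'
#' Trapezoidal integral of the content of one compartment over the response
#' horizon. For a constant-coefficient system with an irreversible exit
#' this equals the mean residence time in that compartment for material
#' entering at the impulse site. If the system has no irreversible loss the
#' integral diverges and the function signals non-convergence; it also
#' checks that the response has decayed at the horizon (relative tail below
#' `tail_tol`), warning otherwise.
#'
#' @param ir an [impulse_response()].
#' @param compartment compartment id to integrate.
#' @param tail_tol maximum tolerated content at the horizon relative to the
#'   peak content before the integral is declared unconverged.
#' @return the integral, days.
#' @export
residence_integral <- function(ir, compartment, tail_tol = 1e-3) {
  model <- ir$model
  total_loss <- 0
  cf <- model$coefficients
  total_loss <- sum(cf$value[cf$to == 0L])
  if (nrow(model$interrupts))
    total_loss <- total_loss + sum(pmin(model$interrupts$value_before,
                                        model$interrupts$value_after))
  hook_loss <- any(vapply(model$tv_hooks, function(h) h$to == 0L, TRUE))
  if (total_loss == 0 && !hook_loss)
    stop("system has no irreversible loss: residence integral diverges")
  col <- paste0("q", compartment)
  if (!col %in% names(ir$contents)) stop("unknown compartment id")
  y <- ir$contents[[col]]
  x <- ir$times
  if (max(y) > 0 && y[length(y)] / max(y) > tail_tol)
    warning("impulse response has not decayed at the horizon; ",
            "integral is truncated")
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}
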