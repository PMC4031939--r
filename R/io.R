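#' Plasma tracer response curve
#'
#' A set of paired observation times (days) and plasma tracer values
#' expressed as fraction of the ingested dose, for one treatment group,
#' with an optional per-point weighting fractional standard deviation
#' (default 0.05, the relative error assigned to each datum for weighted
#' fitting).
#'
#' @param times strictly increasing non-negative times, days.
#' @param values fraction of ingested dose, in \[0, 1\].
#' @param group `"oil"`, `"vara"` or another label.
#' @param weight_fsd scalar or per-point fractional SD used as fitting
#'   weight.
#' @param n optional per-point number of pups averaged.
#' @return data.frame of class `tracer_curve` with columns `time_days`,
#'   `fraction_of_dose`, `weight_fsd` and optionally `n`; the group is
#'   stored as an attribute.
#' @export
tracer_curve <- function(times, values, group = NA_character_,
                         weight_fsd = 0.05, n = NULL) {
  if (length(times) != length(values)) stop("times and values differ in length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(times < 0)) stop("negative times")
  if (any(values < -1e-12) || any(values > 1 + 1e-12))
    stop("fraction of dose must lie in [0, 1]")
  out <- data.frame(time_days = as.numeric(times),
                    fraction_of_dose = as.numeric(values),
                    weight_fsd = rep_len(weight_fsd, length(times)))
  if (!is.null(n)) out$n <- rep_len(as.integer(n), length(times))
  attr(out, "group") <- group
  class(out) <- c("tracer_curve", "data.frame")
  out
}

#' @export
print.tracer_curve <- function(x, ...) {
  cat(sprintf("Tracer curve (%s), %d points, %.3g to %.3g days\n",
              attr(x, "group"), nrow(x), min(x$time_days), max(x$time_days)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Read tracer curves from CSV
#'
#' Canonical dialect: comma-separated with header
#' `group,time_days,fraction_of_dose[,weight_fsd]`, fractions as decimals.
#' Validation failures are reported with the offending data rows.
#'
#' @param path CSV file.
#' @param group optional group to extract; default reads the first group
#'   present. Use [read_tracer_groups()] for all groups.
#' @return a [tracer_curve()].
#' @export
read_tracer_csv <- function(path, group = NULL) {
  curves <- read_tracer_groups(path)
  if (is.null(group)) return(curves[[1]])
  if (!group %in% names(curves))
    stop("group '", group, "' not present in ", path)
  curves[[group]]
}

#' @rdname read_tracer_csv
#' @export
read_tracer_groups <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "time_days", "fraction_of_dose")
  if (!all(need %in% names(df)))
    stop("tracer CSV must have header columns ", paste(need, collapse = ","))
  for (col in c("time_days", "fraction_of_dose"))
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))
      stop("non-numeric ", col, " at data row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  out <- list()
  for (g in unique(df$group)) {
    sub <- df[df$group == g, ]
    if (any(diff(sub$time_days) <= 0)) {
      bad <- which(diff(sub$time_days) <= 0) + 1
      stop("times not strictly increasing for group '", g,
           "' at data row(s) ", paste(which(df$group == g)[bad], collapse = ", "))
    }
    out[[g]] <- tracer_curve(sub$time_days, sub$fraction_of_dose, group = g,
                             weight_fsd = if ("weight_fsd" %in% names(sub))
                               sub$weight_fsd else 0.05)
  }
  out
}

#' Write a tracer curve to CSV
#'
#' @param curve a [tracer_curve()].
#' @param path output file.
#' @export
write_tracer_csv <- function(curve, path) {
  df <- data.frame(group = attr(curve, "group"),
                   time_days = curve$time_days,
                   fraction_of_dose = curve$fraction_of_dose,
                   weight_fsd = curve$weight_fsd)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a model definition file
#'
#' Serializes a [compartmental_model()] to a structured YAML file
#' (compartments, delays, coefficients with fixed/free status, interrupts,
#' input, observation map). Time-varying hooks are not serialized; attach
#' them programmatically after reading.
#'
#' @param model a [compartmental_model()].
#' @param path output file.
#' @export
write_model_yaml <- function(model, path) {
  if (length(model$tv_hooks))
    warning("time-varying hooks are not serialized")
  obj <- list(
    group = model$group,
    compartments = as.integer(model$compartments),
    input = model$input,
    observation = as.integer(model$observation),
    coefficients = lapply(seq_len(nrow(model$coefficients)), function(i)
      list(to = model$coefficients$to[i], from = model$coefficients$from[i],
           value = model$coefficients$value[i],
           status = if (model$coefficients$fixed[i]) "fixed" else "free")),
    delays = lapply(seq_len(nrow(model$delays)), function(i)
      list(id = model$delays$id[i], duration = model$delays$duration[i],
           downstream = model$delays$downstream[i],
           status = if (model$delays$fixed[i]) "fixed" else "free")),
    interrupts = lapply(seq_len(nrow(model$interrupts)), function(i)
      list(to = model$interrupts$to[i], from = model$interrupts$from[i],
           switch_time = model$interrupts$switch_time[i],
           value_before = model$interrupts$value_before[i],
           value_after = model$interrupts$value_after[i])))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read a model definition file
#'
#' @param path YAML file written by [write_model_yaml()] (or hand-written
#'   in the same layout).
#' @return a [compartmental_model()].
#' @export
read_model_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  getdf <- function(entries, cols) {
    if (!length(entries)) return(NULL)
    do.call(rbind, lapply(entries, function(e)
      as.data.frame(e[cols], stringsAsFactors = FALSE)))
  }
  cf <- getdf(obj$coefficients, c("to", "from", "value", "status"))
  cf$fixed <- cf$status == "fixed"; cf$status <- NULL
  dl <- getdf(obj$delays, c("id", "duration", "downstream", "status"))
  if (!is.null(dl)) { dl$fixed <- dl$status == "fixed"; dl$status <- NULL }
  ir <- getdf(obj$interrupts,
              c("to", "from", "switch_time", "value_before", "value_after"))
  compartmental_model(compartments = obj$compartments, coefficients = cf,
                      delays = dl, interrupts = ir, input = obj$input,
                      observation = obj$observation,
                      group = if (is.null(obj$group)) NA_character_ else obj$group)
}
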