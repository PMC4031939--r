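# Conversion of raw pup-level measurements (dose dpm, residue dpm, plasma
# tracer concentration, body weight) into group-mean tracer curves and
# plasma pool masses.

#' Ingested dose
#'
#' Radioactivity actually ingested: total dose dpm minus the dpm remaining
#' in the pipette tip and muzzle-blot paper chip.
#'
#' @param dose_total_dpm,residue_dpm dpm; residue must not exceed total.
#' @return ingested dose, dpm.
#' @export
ingested_dose <- function(dose_total_dpm, residue_dpm) {
  if (any(residue_dpm > dose_total_dpm))
    stop("residue dpm exceeds total dose dpm")
  if (any(dose_total_dpm < 0) || any(residue_dpm < 0))
    stop("dpm values must be >= 0")
  dose_total_dpm - residue_dpm
}

#' Fraction of the ingested dose in plasma
#'
#' Total plasma dpm (tracer concentration times the estimated plasma
#' volume, body weight x 0.035 ml/g) divided by the ingested dose. A value
#' above 1 is physically implausible and triggers a warning, but is still
#' returned.
#'
#' @param records pup-record data.frame with columns `body_weight_g`,
#'   `dose_dpm`, `residue_dpm`, `plasma_dpm_per_ml`.
#' @param plasma_ml_per_g plasma volume factor, ml/g.
#' @return numeric vector, fraction of ingested dose per record.
#' @export
fraction_of_dose <- function(records, plasma_ml_per_g = 0.035) {
  ing <- ingested_dose(records$dose_dpm, records$residue_dpm)
  if (any(ing <= 0)) stop("ingested dose must be > 0")
  frac <- records$plasma_dpm_per_ml * records$body_weight_g *
    plasma_ml_per_g / ing
  if (any(frac > 1))
    warning(sum(frac > 1), " record(s) with fraction of dose > 1 ",
            "(physically implausible)")
  frac
}

#' Group-mean ("super-pup") tracer curve
#'
#' Arithmetic mean fraction of dose per scheduled time within one group,
#' with the per-time pup count recorded and the default 0.05 weighting FSD
#' attached. Cross-sectional design: each pup contributes one time point.
#'
#' @param records pup-record data.frame (see [read_pup_csv()] columns).
#' @param group group label to aggregate.
#' @param times scheduled times, days; defaults to the times present.
#'   A scheduled time with no records is an error.
#' @param weight_fsd fractional SD attached to each mean as fitting weight.
#' @return a [tracer_curve()] with per-time `n`.
#' @export
superpup_curve <- function(records, group, times = NULL, weight_fsd = 0.05) {
  sub <- records[records$group == group, ]
  if (!nrow(sub)) stop("no records for group '", group, "'")
  sub$frac <- fraction_of_dose(sub)
  if (is.null(times)) times <- sort(unique(sub$time_days))
  means <- numeric(length(times)); ns <- integer(length(times))
  for (i in seq_along(times)) {
    sel <- abs(sub$time_days - times[i]) < 1e-9
    if (!any(sel)) stop("no records at scheduled time ", times[i],
                        " for group '", group, "'")
    means[i] <- mean(sub$frac[sel])
    ns[i] <- sum(sel)
  }
  tracer_curve(times, means, group = group, weight_fsd = weight_fsd, n = ns)
}

.pup_cols <- c("pup_id", "group", "time_days", "body_weight_g", "dose_dpm",
               "residue_dpm", "plasma_dpm_per_ml", "plasma_retinol_uM")

#' Read pup-level records from CSV
#'
#' Dialect: comma-separated, header
#' `pup_id,group,time_days,body_weight_g,dose_dpm,residue_dpm,plasma_dpm_per_ml,plasma_retinol_uM`.
#' Malformed rows are reported by data row number.
#'
#' @param path CSV file.
#' @return validated data.frame of pup records.
#' @export
read_pup_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.pup_cols, names(df))
  if (length(missing_cols))
    stop("pup CSV missing column(s): ", paste(missing_cols, collapse = ", "))
  for (col in setdiff(.pup_cols, c("pup_id", "group"))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v))
      stop("non-numeric ", col, " at data row(s) ",
           paste(utils::head(which(is.na(v)), 5), collapse = ", "))
    df[[col]] <- v
    if (any(v < 0))
      stop("negative ", col, " at data row(s) ",
           paste(utils::head(which(v < 0), 5), collapse = ", "))
  }
  bad <- which(df$residue_dpm > df$dose_dpm)
  if (length(bad))
    stop("residue exceeds dose at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  df
}

#' Write pup-level records to CSV
#'
#' @param records pup-record data.frame.
#' @param path output file.
#' @export
write_pup_csv <- function(records, path) {
  utils::write.csv(records[, .pup_cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
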