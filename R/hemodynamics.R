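#' Time-averaged mean velocity from a pulsed-wave Doppler trace
#'
#' Integrates an instantaneous-velocity trace over time (trapezoidal rule)
#' and divides by the total duration, giving the time-averaged mean velocity
#' (TAMV) in cm/s. Negative (retrograde) velocities are retained in the
#' integral: the full Doppler signal is integrated, not its envelope.
#'
#' @param time_s numeric vector of sample times (s), strictly increasing.
#' @param velocity_cm_s numeric vector of instantaneous velocities (cm/s),
#'   same length as `time_s`.
#' @return TAMV in cm/s (scalar).
#' @examples
#' time_averaged_mean_velocity(0:10, rep(10, 11))      # constant -> 10
#' time_averaged_mean_velocity(c(0, 2), c(0, 20))      # linear ramp -> 10
#' @export
time_averaged_mean_velocity <- function(time_s, velocity_cm_s) {
  if (length(time_s) != length(velocity_cm_s)) {
    stop("time and velocity vectors must have equal length")
  }
  if (length(time_s) < 2L) {
    stop("velocity trace must contain at least 2 points")
  }
  if (any(!is.finite(time_s)) || any(!is.finite(velocity_cm_s))) {
    stop("velocity trace contains non-finite values")
  }
  if (any(diff(time_s) <= 0)) {
    stop("trace times must be strictly increasing")
  }
  pracma::trapz(time_s, velocity_cm_s) / (time_s[length(time_s)] - time_s[1L])
}

#' Volumetric blood flow from a Doppler vessel scan
#'
#' Converts a lumen diameter and a velocity trace into volumetric flow:
#' `lumen_area = pi * (d / 2)^2` (cm^2), `q_abs = TAMV * area * 60` (mL/min),
#' and flow normalized per 100 mL of limb volume,
#' `f_norm = q_abs / limb_volume * 100`. Duplicate diameter acquisitions are
#' averaged arithmetically before the area computation. Scans with fewer
#' than `min_cycles` cardiac cycles are flagged `"insufficient_cycles"` and
#' return NA flows unless `override = TRUE`.
#'
#' @param diameter_cm lumen diameter(s), cm; multiple values are averaged.
#' @param time_s,velocity_cm_s the Doppler velocity trace (see
#'   [time_averaged_mean_velocity()]).
#' @param limb_volume_ml limb volume used for normalization (mL). The study
#'   design reports balances per 100 mL of limb; how limb volume was
#'   obtained is an input here, never assumed.
#' @param n_cardiac_cycles number of cardiac cycles covered by the trace.
#' @param min_cycles acceptance threshold for a scan (default 8).
#' @param override keep flows from under-sampled scans (default `FALSE`).
#' @return data.frame with one row: `tamv_cm_s`, `area_cm2`, `q_ml_min`,
#'   `f_per100ml`, `limb_volume_ml`, `flag` ("ok" or "insufficient_cycles").
#' @examples
#' compute_flow(0.40, 0:9, rep(10, 10), limb_volume_ml = 1000,
#'              n_cardiac_cycles = 10)
#' @export
compute_flow <- function(diameter_cm, time_s, velocity_cm_s, limb_volume_ml,
                         n_cardiac_cycles = Inf, min_cycles = 8,
                         override = FALSE) {
  stopifnot(all(diameter_cm > 0), limb_volume_ml > 0)
  d <- mean(diameter_cm)
  tamv <- time_averaged_mean_velocity(time_s, velocity_cm_s)
  area <- pi * (d / 2)^2
  q <- tamv * area * 60
  f <- q / limb_volume_ml * 100
  flag <- if (n_cardiac_cycles < min_cycles) "insufficient_cycles" else "ok"
  if (flag != "ok" && !override) {
    q <- NA_real_
    f <- NA_real_
  }
  data.frame(tamv_cm_s = tamv, area_cm2 = area, q_ml_min = q,
             f_per100ml = f, limb_volume_ml = limb_volume_ml,
             flag = flag, stringsAsFactors = FALSE)
}

#' Reduce a table of vessel scans to flow measurements
#'
#' Reads the scan index (`subject_id`, `timepoint_min`, `diameter_cm`,
#' `n_cycles`, `trace_file`), loads each two-column trace CSV
#' (`time_s`, `velocity_cm_s`), and applies [compute_flow()].
#'
#' @param scans data.frame or path to a TSV with the columns above.
#' @param limb_volume_ml limb volume (mL), recycled across scans.
#' @param trace_dir directory that trace files are relative to (default the
#'   directory of the scan file, or `"."` for an in-memory table).
#' @param override keep under-sampled scans (see [compute_flow()]).
#' @return data.frame: subject_id, timepoint_min, tamv_cm_s, area_cm2,
#'   q_ml_min, f_per100ml, flag.
#' @export
flow_table <- function(scans, limb_volume_ml, trace_dir = NULL,
                       override = FALSE) {
  if (is.character(scans)) {
    if (is.null(trace_dir)) trace_dir <- dirname(scans)
    scans <- utils::read.delim(scans, stringsAsFactors = FALSE)
  }
  if (is.null(trace_dir)) trace_dir <- "."
  need <- c("subject_id", "timepoint_min", "diameter_cm", "n_cycles",
            "trace_file")
  if (!all(need %in% names(scans))) {
    stop("scan table is missing columns: ",
         paste(setdiff(need, names(scans)), collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(scans)), function(i) {
    tr <- utils::read.csv(file.path(trace_dir, scans$trace_file[i]))
    fl <- compute_flow(scans$diameter_cm[i], tr$time_s, tr$velocity_cm_s,
                       limb_volume_ml = limb_volume_ml,
                       n_cardiac_cycles = scans$n_cycles[i],
                       override = override)
    cbind(data.frame(subject_id = scans$subject_id[i],
                     timepoint_min = scans$timepoint_min[i],
                     stringsAsFactors = FALSE),
          fl)
  })
  do.call(rbind, rows)
}
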