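#' Primed-continuous dosing plan for the clamp protocol
#'
#' Converts per-kg / per-m2 protocol rates into absolute pump rates for one
#' subject. The protocol: a primed (0-5 min: 128.2, 5-10 min:
#' 71.8 mU m-2 min-1), continuous (50 mU m-2 min-1 from 10 min) insulin
#' infusion; a primed (0.5 mg/kg), continuous (0.5 mg/kg/h) ring-labelled
#' phenylalanine tracer; a primed (0.46 mL/kg), continuous (1.38 mL/kg/h)
#' 10% amino-acid mixture spiked with 7% tracer; potassium chloride at
#' 1 mL/kg/h; and variable 20% dextrose, whose rate is set by the
#' euglycaemic controller rather than the plan. The tracer prime is
#' book-kept as an impulse at t = 0.
#'
#' @param mass_kg body mass (kg).
#' @param bsa_m2 body surface area (m2); required for insulin.
#' @param duration_min clamp duration (default 180 min).
#' @param agents subset of `c("insulin", "tracer_phe", "amino_mix", "kcl",
#'   "dextrose")` to include.
#' @return data.frame: `agent`, `type` ("prime" or "continuous"),
#'   `start_min`, `end_min`, `amount`, `units`. Prime rows carry the total
#'   amount at `start_min`; continuous rows an absolute rate.
#' @examples
#' plan <- build_dosing_plan(mass_kg = 70, bsa_m2 = 1.8)
#' subset(plan, agent == "insulin")
#' @export
build_dosing_plan <- function(mass_kg, bsa_m2 = NULL, duration_min = 180,
                              agents = c("insulin", "tracer_phe",
                                         "amino_mix", "kcl", "dextrose")) {
  stopifnot(mass_kg > 0, duration_min > 0)
  agents <- match.arg(agents, several.ok = TRUE)
  rows <- list()
  add <- function(agent, type, start, end, amount, units) {
    rows[[length(rows) + 1L]] <<- data.frame(
      agent = agent, type = type, start_min = start, end_min = end,
      amount = amount, units = units, stringsAsFactors = FALSE)
  }
  if ("insulin" %in% agents) {
    if (is.null(bsa_m2)) {
      stop("body surface area (bsa_m2) required for insulin dosing")
    }
    stopifnot(bsa_m2 > 0)
    add("insulin", "continuous", 0, 5, 128.2 * bsa_m2, "mU/min")
    add("insulin", "continuous", 5, 10, 71.8 * bsa_m2, "mU/min")
    add("insulin", "continuous", 10, duration_min, 50 * bsa_m2, "mU/min")
  }
  if ("tracer_phe" %in% agents) {
    add("tracer_phe", "prime", 0, 0, 0.5 * mass_kg, "mg")
    add("tracer_phe", "continuous", 0, duration_min, 0.5 * mass_kg, "mg/h")
  }
  if ("amino_mix" %in% agents) {
    add("amino_mix", "prime", 0, 0, 0.46 * mass_kg, "mL")
    add("amino_mix", "continuous", 0, duration_min, 1.38 * mass_kg, "mL/h")
  }
  if ("kcl" %in% agents) {
    add("kcl", "continuous", 0, duration_min, 1 * mass_kg, "mL/h")
  }
  if ("dextrose" %in% agents) {
    add("dextrose", "continuous", 0, duration_min, NA_real_,
        "mL/h (controller-set)")
  }
  out <- do.call(rbind, rows)
  stopifnot(all(out$amount >= 0, na.rm = TRUE))
  out
}

#' Glucose disposal rate from a clamp infusion log
#'
#' Converts the 20% dextrose pump rate into a mass-specific glucose
#' infusion rate, `GIR = rate_mL_h * 0.2 g/mL * 1000 / 60 / mass_kg`
#' (mg kg-1 min-1), and averages it over the steady-state window. By
#' convention the steady-state mean infusion rate is reported as the
#' glucose disposal rate (GDR); no glucose-space or urinary-loss correction
#' is applied.
#'
#' @param log data.frame (or CSV path) with columns `time_min`,
#'   `pump_ml_h`, `glucose_mmol_l`.
#' @param mass_kg body mass (kg).
#' @param window two-element numeric, `[start, end]` minutes (default the
#'   final 30 min of the log).
#' @param dextrose_g_ml dextrose concentration (default 0.2 g/mL, "20%").
#' @return list of class `"gdr_result"`: `gdr` (mg kg-1 min-1),
#'   `mean_glucose` (mmol/L), `cv_glucose` (%), `window`, `n_readings`.
#' @examples
#' log <- data.frame(time_min = seq(0, 180, 5), pump_ml_h = 210,
#'                   glucose_mmol_l = 5)
#' gdr_from_log(log, mass_kg = 70)$gdr  # 10
#' @export
gdr_from_log <- function(log, mass_kg, window = NULL, dextrose_g_ml = 0.2) {
  if (is.character(log)) log <- utils::read.csv(log)
  stopifnot(mass_kg > 0, all(log$pump_ml_h >= 0))
  if (is.null(window)) window <- c(max(log$time_min) - 30, max(log$time_min))
  if (window[1] < min(log$time_min) || window[2] > max(log$time_min)) {
    stop("window [", window[1], ", ", window[2], "] outside log span")
  }
  sel <- log$time_min >= window[1] & log$time_min <= window[2]
  if (sum(sel) < 2L) stop("steady-state window covers fewer than 2 readings")
  gir <- log$pump_ml_h[sel] * dextrose_g_ml * 1000 / 60 / mass_kg
  g <- log$glucose_mmol_l[sel]
  res <- list(gdr = mean(gir),
              mean_glucose = mean(g),
              cv_glucose = stats::sd(g) / mean(g) * 100,
              window = window,
              n_readings = sum(sel))
  class(res) <- "gdr_result"
  res
}

#' @export
print.gdr_result <- function(x, ...) {
  cat(sprintf(
    "GDR %.3f mg/kg/min over [%g, %g] min (glucose %.3f mmol/L, CV %.2f%%)\n",
    x$gdr, x$window[1], x$window[2], x$mean_glucose, x$cv_glucose))
  invisible(x)
}

#' Simulate a hyperinsulinaemic-euglycaemic clamp subject
#'
#' Closed-loop simulation of a single well-mixed glucose pool held at the
#' euglycaemic target by a proportional-integral (PI) controller that
#' adjusts the 20% dextrose pump every 5 min, mirroring bedside practice.
#' Euler integration at 1-min steps:
#' \deqn{dG/dt = (EGP + GIR - D(G)) / (V \cdot 180.156)}
#' with rates in mg kg-1 min-1, `D(G) = disposal_truth * G / target`
#' (disposal proportional to glycaemia around the operating point), and `V`
#' the glucose distribution volume (L/kg). Endogenous glucose production
#' defaults to 0, i.e., fully suppressed by clamp insulin, so the
#' steady-state infusion rate identifies `disposal_truth`. Optional
#' measurement noise perturbs only the glucose readings the controller and
#' log see, never the true state; runs are reproducible under a fixed seed.
#' The simulation aborts with a diagnostic if glucose leaves [2, 10] mmol/L.
#'
#' @param mass_kg body mass (kg).
#' @param disposal_truth true insulin-stimulated disposal at target
#'   glycaemia (mg kg-1 min-1).
#' @param egp endogenous glucose production (mg kg-1 min-1, default 0).
#' @param glucose_volume_l_kg glucose distribution volume (default
#'   0.16 L/kg).
#' @param target_mmol_l euglycaemic target (default 5.0 mmol/L).
#' @param kp,ki PI controller gains: `kp` in (mg kg-1 min-1) per (mmol/L)
#'   error, `ki` per (mmol/L x min) of accumulated error. Defaults settle a
#'   noise-free run well before minute 120 across the physiological
#'   disposal range.
#' @param duration_min clamp duration (default 180).
#' @param noise_cv coefficient of variation of the bedside glucose reading
#'   (default 0 = noise-free).
#' @param seed integer seed for measurement noise.
#' @return list of class `"clamp_sim"`: `log` (data.frame `time_min`,
#'   `pump_ml_h`, `glucose_mmol_l` on the 5-min grid), `state` (1-min true
#'   glucose and GIR), `mass_balance` (cumulative infused / disposed / EGP
#'   mg/kg and pool change), and the parameters.
#' @examples
#' sim <- simulate_clamp(70, disposal_truth = 8)
#' gdr_from_log(sim$log, 70, window = c(150, 180))$gdr
#' @export
simulate_clamp <- function(mass_kg, disposal_truth, egp = 0,
                           glucose_volume_l_kg = 0.16, target_mmol_l = 5.0,
                           kp = 2.5, ki = 0.18, duration_min = 180,
                           noise_cv = 0, seed = 1L) {
  stopifnot(mass_kg > 0, disposal_truth >= 0, egp >= 0,
            glucose_volume_l_kg > 0, target_mmol_l > 0, duration_min >= 10)
  dt <- 1
  times <- seq(0, duration_min, by = dt)
  n <- length(times)
  vol_mg <- glucose_volume_l_kg * GLUCOSE_MG_PER_MMOL  # mg/kg per mmol/L
  g <- numeric(n)
  gir <- numeric(n)
  g[1] <- target_mmol_l
  integral <- 0
  gir_now <- 0
  cum_inf <- 0
  cum_disp <- 0
  cum_egp <- 0
  log_t <- c()
  log_gir <- c()
  log_g <- c()
  rng <- NULL
  if (noise_cv > 0) {
    rng <- split_seed(seed, "clamp_glucose_meas")[[1]]
    set.seed(rng)
  }
  for (i in seq_len(n)) {
    t <- times[i]
    if (t %% 5 == 0) {
      g_meas <- g[i]
      if (noise_cv > 0) g_meas <- g_meas * (1 + stats::rnorm(1, 0, noise_cv))
      err <- target_mmol_l - g_meas
      integral <- integral + err * 5
      gir_now <- max(0, kp * err + ki * integral)
      log_t <- c(log_t, t)
      log_gir <- c(log_gir, gir_now)
      log_g <- c(log_g, g_meas)
    }
    gir[i] <- gir_now
    if (i < n) {
      disp <- disposal_truth * g[i] / target_mmol_l
      g[i + 1] <- g[i] + dt * (egp + gir_now - disp) / vol_mg
      cum_inf <- cum_inf + gir_now * dt
      cum_disp <- cum_disp + disp * dt
      cum_egp <- cum_egp + egp * dt
      if (g[i + 1] < 2 || g[i + 1] > 10) {
        stop(sprintf(paste0("clamp controller diverged: glucose %.2f mmol/L",
                            " at t = %g min (bounds [2, 10])"),
                     g[i + 1], times[i + 1]))
      }
    }
  }
  res <- list(
    log = data.frame(time_min = log_t,
                     pump_ml_h = log_gir * mass_kg * 60 / (0.2 * 1000),
                     glucose_mmol_l = log_g),
    state = data.frame(time_min = times, glucose_mmol_l = g,
                       gir_mg_kg_min = gir),
    mass_balance = list(cum_infused_mg_kg = cum_inf,
                        cum_disposed_mg_kg = cum_disp,
                        cum_egp_mg_kg = cum_egp,
                        pool_change_mg_kg = (g[n] - g[1]) * vol_mg),
    params = list(mass_kg = mass_kg, disposal_truth = disposal_truth,
                  egp = egp, glucose_volume_l_kg = glucose_volume_l_kg,
                  target_mmol_l = target_mmol_l, kp = kp, ki = ki,
                  duration_min = duration_min, noise_cv = noise_cv,
                  seed = seed))
  class(res) <- "clamp_sim"
  res
}

#' @export
print.clamp_sim <- function(x, ...) {
  ss <- x$state$glucose_mmol_l[x$state$time_min >= x$params$duration_min - 30]
  cat(sprintf(paste0("Clamp simulation: disposal %.1f mg/kg/min, ",
                     "steady-state glucose %.3f mmol/L (target %.1f)\n"),
              x$params$disposal_truth, mean(ss), x$params$target_mmol_l))
  invisible(x)
}
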