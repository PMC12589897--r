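#' Simulate a steady-state virtual forearm
#'
#' Forward inversion of the two-pool arteriovenous tracer model: given true
#' flow, arterial state and true kinetics, the implied venous state is
#' \deqn{c_v = c_a - NB/f, \qquad
#'       e_v = e_a \frac{c_a f - Rd}{c_v f}}
#' so that [two_pool_kinetics()] applied to the noise-free output recovers
#' (nb, rd, ra) exactly. With noise, independent multiplicative mean-one
#' log-normal perturbations are applied per channel (concentrations,
#' enrichments, flow) with the stated coefficients of variation; any
#' concentration driven non-positive is truncated at a small positive floor
#' (1e-6) and flagged. Glucose channels are simulated analogously from a
#' true glucose uptake.
#'
#' @param f true blood flow (mL/min per 100 mL limb).
#' @param c_a true arterialized tracee concentration (umol/L).
#' @param e_a true arterialized enrichment (TTR).
#' @param rd_true,ra_true true rates of disappearance / appearance
#'   (nmol/min per 100 mL); `nb_true = rd_true - ra_true`.
#' @param glu_a true arterialized glucose (mmol/L, default 5.0).
#' @param glucose_uptake_true true forearm glucose uptake
#'   (umol/min per 100 mL, default 0.6).
#' @param n_samples number of paired samples to emit (default 5, matching a
#'   30-min steady-state window sampled five times).
#' @param cv_conc,cv_enrich,cv_flow per-channel noise CVs (default 0).
#' @param seed integer seed; all channels draw from sub-streams derived
#'   from it.
#' @return list: `samples` (data.frame `c_a_umol_l`, `c_v_umol_l`, `ttr_a`,
#'   `ttr_v`, `glu_a_mmol_l`, `glu_v_mmol_l`, `floored`), `flows` (numeric,
#'   one per sample), `truth` (named list of all true values).
#' @examples
#' fa <- simulate_forearm(f = 3, c_a = 60, e_a = 0.08,
#'                        rd_true = 40, ra_true = 15)
#' fa$samples[1, c("c_v_umol_l", "ttr_v")]  # 51.6667, 0.0722581
#' @export
simulate_forearm <- function(f, c_a, e_a, rd_true, ra_true,
                             glu_a = 5.0, glucose_uptake_true = 0.6,
                             n_samples = 5, cv_conc = 0, cv_enrich = 0,
                             cv_flow = 0, seed = 1L) {
  stopifnot(f > 0, c_a > 0, e_a > 0, rd_true >= 0, ra_true >= 0,
            n_samples >= 1)
  nb_true <- rd_true - ra_true
  c_v <- c_a - nb_true / f
  if (c_v <= 0) {
    stop("unphysical implied venous state: c_v = ", signif(c_v, 6),
         " <= 0 (nb too large for the given c_a and f)")
  }
  e_v <- e_a * (c_a * f - rd_true) / (c_v * f)
  if (e_v <= 0 || e_v > e_a) {
    stop("unphysical implied venous enrichment: e_v = ", signif(e_v, 6),
         " not in (0, e_a = ", e_a, "]")
  }
  glu_v <- glu_a - glucose_uptake_true / f
  if (glu_v <= 0) {
    stop("unphysical implied venous glucose: glu_v = ", signif(glu_v, 6))
  }

  seeds <- split_seed(seed, c("conc_a", "conc_v", "enr_a", "enr_v",
                              "glu_a", "glu_v", "flow"))
  draw <- function(label, true, cv) {
    set.seed(seeds[[label]])
    true * lognorm_noise(n_samples, cv)
  }
  floor_pos <- function(x) pmax(x, 1e-6)
  ca_s <- draw("conc_a", c_a, cv_conc)
  cv_s <- draw("conc_v", c_v, cv_conc)
  floored <- ca_s < 1e-6 | cv_s < 1e-6
  samples <- data.frame(
    c_a_umol_l = floor_pos(ca_s),
    c_v_umol_l = floor_pos(cv_s),
    ttr_a = draw("enr_a", e_a, cv_enrich),
    ttr_v = draw("enr_v", e_v, cv_enrich),
    glu_a_mmol_l = floor_pos(draw("glu_a", glu_a, cv_conc)),
    glu_v_mmol_l = floor_pos(draw("glu_v", glu_v, cv_conc)),
    floored = floored)
  flows <- draw("flow", f, cv_flow)
  list(samples = samples, flows = flows,
       truth = list(f = f, c_a = c_a, c_v = c_v, e_a = e_a, e_v = e_v,
                    rd = rd_true, ra = ra_true, nb = nb_true,
                    glu_a = glu_a, glu_v = glu_v,
                    glucose_uptake = glucose_uptake_true))
}

#' Simulate a Doppler vessel scan with known flow
#'
#' Builds a pulsatile velocity trace (raised-cosine cardiac cycles at 1 Hz,
#' sampled at 100 Hz) whose time-averaged mean velocity equals `tamv_cm_s`
#' by construction, paired with a lumen diameter. Feeding the result to
#' [compute_flow()] recovers `tamv * pi (d/2)^2 * 60` exactly up to
#' trapezoidal quadrature error (the modulation integrates to zero over
#' whole cycles).
#'
#' @param tamv_cm_s target time-averaged mean velocity (cm/s).
#' @param diameter_cm lumen diameter (cm).
#' @param n_cycles number of 1-s cardiac cycles (default 10).
#' @param pulsatility peak modulation as a fraction of the mean (default
#'   0.8).
#' @param fs_hz sampling rate (default 100 Hz).
#' @return list: `time_s`, `velocity_cm_s`, `diameter_cm`, `n_cycles`.
#' @export
simulate_vessel_scan <- function(tamv_cm_s, diameter_cm, n_cycles = 10,
                                 pulsatility = 0.8, fs_hz = 100) {
  stopifnot(tamv_cm_s >= 0, diameter_cm > 0, n_cycles >= 1)
  t <- seq(0, n_cycles, by = 1 / fs_hz)
  v <- tamv_cm_s * (1 + pulsatility * cos(2 * pi * t))
  list(time_s = t, velocity_cm_s = v, diameter_cm = diameter_cm,
       n_cycles = n_cycles)
}
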