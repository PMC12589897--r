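#' Default calibration for the synthetic mouse cohort
#'
#' A three-group (healthy reference; calorically restricted + unilaterally
#' immobilized control; the same plus continuous salbutamol), two-limb
#' (mobile / immobilized) cohort. Group x limb means are defined as a
#' healthy baseline times cell multipliers; the multipliers encode the
#' study-level effect sizes this generator is calibrated to (caloric
#' restriction atrophy of roughly a quarter of muscle mass, an additional
#' 10-17% immobilization loss, ~10% salbutamol hypertrophy in the mobile
#' limb only, halved-to-two-thirds-reduced synthesis rates with a large
#' salbutamol rescue in the immobilized limb, and ~10% label-retention
#' shifts in the carbon-14 ratio). They are calibration inputs for a
#' simulator with known truth, not reproduction claims about any real
#' cohort.
#'
#' Protein turnover couples two endpoints through a shared per-animal-limb
#' latent: higher turnover raises the D2O fractional synthesis rate and
#' lowers the tissue 14C/12C ratio (faster washout of the pre-loaded
#' label), yielding a negative correlation between the two by construction.
#'
#' @param n_per_group animals per group (default 15).
#' @return config list: `n_per_group`, `groups`, `baselines`,
#'   `cell_multipliers` (data.frame endpoint/group/limb/mult), `noise`
#'   (CVs and latent SDs), `label_days`, `urine` (day grid, decay profile
#'   and group excretion multipliers), `fibres` (counts, type proportions,
#'   log-scale spread).
#' @export
cohort_defaults <- function(n_per_group = 15) {
  stopifnot(n_per_group >= 2)
  cell <- function(endpoint, mults) {
    # mults: healthy, control.mobile, control.immob, salb.mobile, salb.immob
    data.frame(
      endpoint = endpoint,
      group = c("healthy", "control", "control", "salbutamol", "salbutamol"),
      limb = c("mobile", "mobile", "immobilized", "mobile", "immobilized"),
      mult = mults, stringsAsFactors = FALSE)
  }
  cm <- rbind(
    cell("quadriceps_mass_mg",
         c(1, 0.77, 0.77 * 0.83, 0.77 * 1.09, 0.77 * 0.83)),
    cell("gastrocnemius_mass_mg",
         c(1, 0.74, 0.74 * 0.90, 0.74 * 1.10, 0.74 * 0.90)),
    cell("fsr_cum_pct",
         c(1, 0.46, 0.37, 0.46 * 1.27, 0.37 * 2.46)),
    cell("ratio_14c_12c",
         c(1, 1.11, 1.09, 1.11 * 0.95, 1.09 * 0.87)),
    data.frame(endpoint = "grip_n",
               group = c("healthy", "control", "salbutamol"),
               limb = "n/a", mult = c(1, 0.73, 0.73),
               stringsAsFactors = FALSE))
  list(
    n_per_group = n_per_group,
    groups = c("healthy", "control", "salbutamol"),
    baselines = list(quadriceps_mass_mg = 200, gastrocnemius_mass_mg = 150,
                     fsr_cum_pct = 7.0, ratio_14c_12c = 5e-12,
                     grip_n = 1.9, e_body_water_mpe = 3.0,
                     carbon_fraction = 0.45, urine_activity = 250,
                     csa_um2 = c(I = 1400, II = 1600)),
    noise = list(cv_mass = 0.08, cv_grip_between = 0.10,
                 cv_grip_trial = 0.06, cv_bodywater = 0.04,
                 cv_carbon_fraction = 0.02, cv_urine = 0.15,
                 sd_turnover_fsr = 0.15, cv_fsr_indep = 0.12,
                 sd_turnover_ratio = 0.05, cv_ratio_indep = 0.04,
                 sd_urine_turnover = 0.10),
    label_days = 13,
    urine = list(days = c(0, 3, 7, 10, 13),
                 profile = c(1, 0.80, 0.60, 0.50, 0.45),
                 excretion_mult = c(healthy = 1, control = 1.30,
                                    salbutamol = 1.15)),
    fibres = list(n_per_type = 40, type_prop_I = 0.4, sdlog = 0.35,
                  csa_mult = data.frame(
                    group = c("healthy", "control", "control",
                              "salbutamol", "salbutamol"),
                    limb = c("mobile", "mobile", "immobilized",
                             "mobile", "immobilized"),
                    mult = c(1, 0.80, 0.70, 0.88, 0.70),
                    stringsAsFactors = FALSE)),
    cell_multipliers = cm)
}

#' Simulate a calibrated mouse cohort with known ground truth
#'
#' Draws per-animal endpoints around the group x limb means implied by
#' [cohort_defaults()] (or a modified config), with mean-one multiplicative
#' log-normal noise per channel, and emits every table the downstream
#' pipeline consumes. The fractional synthesis rate and the 14C/12C ratio
#' of each animal x limb share a turnover latent with opposite sign, and
#' urinary label excretion increases with the same latent. The healthy
#' reference group has no immobilized limb; its limb-resolved endpoints
#' carry `limb = "mobile"`. D2O enrichments are emitted such that
#' [cumulative_fsr()] applied to them reproduces each animal's simulated
#' FSR exactly.
#'
#' @param config generator configuration (default [cohort_defaults()]).
#' @param seed master integer seed; every channel draws from a derived
#'   sub-stream.
#' @return list of class `"mouse_cohort"`: `cohort` (long endpoint table
#'   with columns unit_id, group, occasion, limb, endpoint, value), `d2o`,
#'   `ams`, `urine`, `grip`, `fibres` (input-shaped data.frames), and
#'   `truth` (the config plus the realized group x limb means).
#' @export
simulate_mouse_cohort <- function(config = cohort_defaults(), seed = 1L) {
  stopifnot(config$n_per_group >= 2,
            all(config$cell_multipliers$mult > 0))
  n <- config$n_per_group
  base <- config$baselines
  nz <- config$noise
  cm <- config$cell_multipliers
  seeds <- split_seed(seed, c("latent", "mass", "fsr", "ratio", "grip",
                              "bodywater", "carbon", "drymass", "urine",
                              "fibres"))
  animals <- data.frame(
    unit_id = sprintf("m%02d", seq_len(3 * n)),
    group = rep(config$groups, each = n),
    stringsAsFactors = FALSE)
  limbs_of <- function(grp) if (grp == "healthy") "mobile" else
    c("mobile", "immobilized")
  al <- do.call(rbind, lapply(seq_len(nrow(animals)), function(i) {
    data.frame(unit_id = animals$unit_id[i], group = animals$group[i],
               limb = limbs_of(animals$group[i]), stringsAsFactors = FALSE)
  }))
  cell_mean <- function(endpoint, grp, limb) {
    b <- base[[endpoint]]
    b * cm$mult[cm$endpoint == endpoint & cm$group == grp & cm$limb == limb]
  }

  # shared turnover latent, one per animal x limb
  set.seed(seeds[["latent"]])
  al$z <- stats::rnorm(nrow(al))

  set.seed(seeds[["fsr"]])
  w <- stats::rnorm(nrow(al))
  fsr_mean <- mapply(cell_mean, "fsr_cum_pct", al$group, al$limb)
  al$fsr_cum_pct <- fsr_mean *
    exp(nz$sd_turnover_fsr * al$z - nz$sd_turnover_fsr^2 / 2) *
    exp(nz$cv_fsr_indep * w - nz$cv_fsr_indep^2 / 2)

  set.seed(seeds[["ratio"]])
  u <- stats::rnorm(nrow(al))
  ratio_mean <- mapply(cell_mean, "ratio_14c_12c", al$group, al$limb)
  al$ratio_14c_12c <- ratio_mean *
    exp(-nz$sd_turnover_ratio * al$z - nz$sd_turnover_ratio^2 / 2) *
    exp(nz$cv_ratio_indep * u - nz$cv_ratio_indep^2 / 2)

  set.seed(seeds[["mass"]])
  for (ep in c("quadriceps_mass_mg", "gastrocnemius_mass_mg")) {
    al[[ep]] <- mapply(cell_mean, ep, al$group, al$limb) *
      lognorm_noise(nrow(al), nz$cv_mass)
  }

  # grip strength: animal-level, five trials each
  set.seed(seeds[["grip"]])
  grip_true <- vapply(animals$group, function(g)
    cell_mean("grip_n", g, "n/a"), numeric(1)) *
    lognorm_noise(nrow(animals), nz$cv_grip_between)
  trials <- matrix(grip_true, nrow(animals), 5) *
    matrix(lognorm_noise(nrow(animals) * 5, nz$cv_grip_trial),
           nrow(animals), 5)
  grip <- data.frame(animal_id = animals$unit_id, stringsAsFactors = FALSE)
  grip[paste0("f", 1:5)] <- as.data.frame(trials)

  # D2O table, constructed so cumulative_fsr() recovers al$fsr_cum_pct
  set.seed(seeds[["bodywater"]])
  bw <- base$e_body_water_mpe * lognorm_noise(nrow(animals), nz$cv_bodywater)
  names(bw) <- animals$unit_id
  d2o <- data.frame(animal_id = al$unit_id, limb = al$limb,
                    e_bw_mpe = unname(bw[al$unit_id]),
                    stringsAsFactors = FALSE)
  d2o$e_ala_mpe <- al$fsr_cum_pct / 100 * d2o$e_bw_mpe * 3.7
  d2o$label_days <- config$label_days

  # AMS table
  set.seed(seeds[["carbon"]])
  cf <- base$carbon_fraction * lognorm_noise(nrow(al), nz$cv_carbon_fraction)
  set.seed(seeds[["drymass"]])
  ams <- data.frame(animal_id = al$unit_id, limb = al$limb,
                    ratio_14c_12c = al$ratio_14c_12c,
                    carbon_fraction = cf,
                    dry_mass_mg = stats::runif(nrow(al), 3, 8),
                    stringsAsFactors = FALSE)

  # urine: excretion rises with group-level turnover and the animal latent
  set.seed(seeds[["urine"]])
  zbar <- tapply(al$z, al$unit_id, mean)[animals$unit_id]
  udays <- config$urine$days
  urine <- do.call(rbind, lapply(seq_len(nrow(animals)), function(i) {
    g <- animals$group[i]
    act <- base$urine_activity * config$urine$profile *
      lognorm_noise(length(udays), nz$cv_urine)
    post <- udays > 0
    act[post] <- act[post] * config$urine$excretion_mult[[g]] *
      exp(nz$sd_urine_turnover * zbar[i])
    data.frame(animal_id = animals$unit_id[i], day = udays, activity = act,
               stringsAsFactors = FALSE)
  }))

  # per-fibre CSA tables (soleus-like type I/II mixture)
  set.seed(seeds[["fibres"]])
  fb <- config$fibres
  fibres <- do.call(rbind, lapply(seq_len(nrow(al)), function(i) {
    mult <- fb$csa_mult$mult[fb$csa_mult$group == al$group[i] &
                               fb$csa_mult$limb == al$limb[i]]
    n_i <- round(2 * fb$n_per_type * fb$type_prop_I)
    n_ii <- 2 * fb$n_per_type - n_i
    ty <- c(rep("I", n_i), rep("II", n_ii))
    mu <- log(base$csa_um2[ty] * mult) - fb$sdlog^2 / 2
    data.frame(animal_id = al$unit_id[i], limb = al$limb[i], fibre_type = ty,
               csa_um2 = stats::rlnorm(length(ty), mu, fb$sdlog),
               stringsAsFactors = FALSE)
  }))
  rownames(fibres) <- NULL

  long <- function(ep, value, limb, occasion = "terminal",
                   unit = al$unit_id, grp = al$group) {
    data.frame(unit_id = unit, group = grp, occasion = occasion,
               limb = limb, endpoint = ep, value = value,
               stringsAsFactors = FALSE)
  }
  cohort <- rbind(
    long("quadriceps_mass_mg", al$quadriceps_mass_mg, al$limb),
    long("gastrocnemius_mass_mg", al$gastrocnemius_mass_mg, al$limb),
    long("fsr_cum_pct", al$fsr_cum_pct, al$limb),
    long("ratio_14c_12c", al$ratio_14c_12c, al$limb),
    long("grip_n", apply(trials, 1, grip_score), "n/a",
         unit = animals$unit_id, grp = animals$group))
  rownames(cohort) <- NULL

  truth_means <- cm
  truth_means$mean <- mapply(cell_mean, cm$endpoint, cm$group, cm$limb)

  out <- list(cohort = cohort, d2o = d2o, ams = ams, urine = urine,
              grip = grip, fibres = fibres,
              truth = list(config = config, seed = seed,
                           cell_means = truth_means))
  class(out) <- "mouse_cohort"
  out
}

#' @export
print.mouse_cohort <- function(x, ...) {
  cat("Synthetic mouse cohort:",
      length(unique(x$cohort$unit_id)), "animals,",
      length(unique(x$cohort$endpoint)), "endpoints, seed",
      x$truth$seed, "\n")
  invisible(x)
}
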