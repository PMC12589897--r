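#' Write a complete synthetic study fixture to disk
#'
#' Generates every input the analysis pipeline consumes, with known ground
#' truth, and writes it as plain-text files: Doppler scan index + velocity
#' traces, paired arteriovenous samples, clamp infusion logs, D2O and AMS
#' tables, urine series, grip trials, per-fibre CSA tables, per-animal
#' muscle masses, and a `truth.yaml` manifest recording every true value
#' and the seed. Byte-identical across runs with the same seed.
#'
#' The human arm of the fixture carries two virtual subjects measured in
#' postabsorptive and clamp phases (five paired samples and five Doppler
#' scans per phase, the clamp scans in the final 30 min steady state); the
#' mouse arm is one [simulate_mouse_cohort()] draw.
#'
#' @param dir output directory.
#' @param seed master integer seed.
#' @param force overwrite an existing non-empty directory (default FALSE).
#' @param cohort_config mouse-cohort configuration
#'   (default [cohort_defaults()]).
#' @return (invisibly) the truth manifest as a list.
#' @export
make_fixture_bundle <- function(dir, seed = 1L, force = FALSE,
                                cohort_config = cohort_defaults()) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    stop("output directory ", dir,
         " exists and is not empty (use force = TRUE to overwrite)")
  }
  dir.create(file.path(dir, "traces"), recursive = TRUE,
             showWarnings = FALSE)
  wcsv <- function(x, name) utils::write.csv(
    x, file.path(dir, name), row.names = FALSE, quote = FALSE)

  limb_volume_ml <- 1000
  subjects <- data.frame(
    subject_id = c("s01", "s02"),
    mass_kg = c(70, 75),
    disposal_truth = c(8.4, 10.3),
    stringsAsFactors = FALSE)
  phases <- data.frame(
    phase = c("postabsorptive", "clamp"),
    f = c(2.5, 3.5), c_a = c(42, 91), e_a = c(0.065, 0.08),
    rd = c(30, 55), ra = c(38, 30),
    glu_a = c(5.0, 5.0), glucose_uptake = c(0.3, 2.0),
    stringsAsFactors = FALSE)
  timepoints <- list(postabsorptive = c(-30, -22, -15, -8, 0),
                     clamp = c(150, 157, 165, 172, 180))
  seeds <- split_seed(seed, c(outer(subjects$subject_id, phases$phase,
                                    paste, sep = "_"),
                              "cohort", "clamp_s01", "clamp_s02"))

  av <- list()
  scans <- list()
  truth_forearm <- list()
  for (i in seq_len(nrow(subjects))) {
    for (j in seq_len(nrow(phases))) {
      sid <- subjects$subject_id[i]
      ph <- phases$phase[j]
      fa <- simulate_forearm(
        f = phases$f[j], c_a = phases$c_a[j], e_a = phases$e_a[j],
        rd_true = phases$rd[j], ra_true = phases$ra[j],
        glu_a = phases$glu_a[j],
        glucose_uptake_true = phases$glucose_uptake[j],
        n_samples = 5, cv_conc = 0.02, cv_enrich = 0.015, cv_flow = 0.08,
        seed = seeds[[paste(sid, ph, sep = "_")]])
      s <- fa$samples
      s$subject_id <- sid
      s$phase <- ph
      s$time_min <- timepoints[[ph]]
      av[[length(av) + 1L]] <-
        s[, c("subject_id", "phase", "time_min", "c_a_umol_l", "c_v_umol_l",
              "ttr_a", "ttr_v", "glu_a_mmol_l", "glu_v_mmol_l")]
      # Doppler scans whose computed normalized flow equals the simulated
      # per-sample flows
      d <- 0.40
      area <- pi * (d / 2)^2
      for (k in seq_along(fa$flows)) {
        tamv <- fa$flows[k] * limb_volume_ml / (100 * area * 60)
        sc <- simulate_vessel_scan(tamv, d, n_cycles = 10)
        fname <- sprintf("traces/%s_%s_%02d.csv", sid, ph, k)
        utils::write.csv(
          data.frame(time_s = sc$time_s, velocity_cm_s = sc$velocity_cm_s),
          file.path(dir, fname), row.names = FALSE, quote = FALSE)
        scans[[length(scans) + 1L]] <- data.frame(
          subject_id = sid, timepoint_min = timepoints[[ph]][k],
          diameter_cm = d, n_cycles = sc$n_cycles, trace_file = fname,
          stringsAsFactors = FALSE)
      }
      truth_forearm[[paste(sid, ph, sep = "_")]] <- fa$truth
    }
  }
  wcsv(do.call(rbind, av), "av_samples.csv")
  utils::write.table(do.call(rbind, scans), file.path(dir,
                                                      "vessel_scans.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  clamp_logs <- lapply(seq_len(nrow(subjects)), function(i) {
    sim <- simulate_clamp(
      mass_kg = subjects$mass_kg[i],
      disposal_truth = subjects$disposal_truth[i],
      noise_cv = 0.01,
      seed = seeds[[paste0("clamp_", subjects$subject_id[i])]])
    cbind(data.frame(subject_id = subjects$subject_id[i],
                     body_mass_kg = subjects$mass_kg[i],
                     stringsAsFactors = FALSE),
          sim$log)
  })
  wcsv(do.call(rbind, clamp_logs), "clamp_log.csv")

  mc <- simulate_mouse_cohort(cohort_config, seed = seeds[["cohort"]])
  wcsv(mc$d2o, "d2o.csv")
  wcsv(mc$ams, "ams.csv")
  wcsv(mc$urine, "urine.csv")
  wcsv(mc$grip, "grip.csv")
  wcsv(mc$fibres, "fibres.csv")
  animals <- unique(mc$cohort[, c("unit_id", "group")])
  wcsv(animals, "animals.csv")
  mass_wide <- mc$cohort[mc$cohort$endpoint %in%
                           c("quadriceps_mass_mg", "gastrocnemius_mass_mg"), ]
  mass_tab <- stats::reshape(
    mass_wide[, c("unit_id", "limb", "endpoint", "value")],
    idvar = c("unit_id", "limb"), timevar = "endpoint",
    direction = "wide")
  names(mass_tab) <- sub("^value\\.", "", names(mass_tab))
  names(mass_tab)[1] <- "animal_id"
  wcsv(mass_tab, "muscle_mass.csv")

  truth <- list(
    seed = seed,
    limb_volume_ml = limb_volume_ml,
    noise = list(cv_conc = 0.02, cv_enrich = 0.015, cv_flow = 0.08,
                 clamp_noise_cv = 0.01),
    subjects = lapply(seq_len(nrow(subjects)), function(i)
      as.list(subjects[i, ])),
    forearm = truth_forearm,
    cohort_cell_means = lapply(seq_len(nrow(mc$truth$cell_means)),
                               function(i)
                                 as.list(mc$truth$cell_means[i, ])),
    cohort_n_per_group = cohort_config$n_per_group)
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(truth)
}

#' Resolve a pipeline configuration
#'
#' Accepts a YAML path or a list; fills defaults for every input file
#' (fixture-bundle layout) and parameter.
#'
#' @param config list or YAML file path. Required key: `input_dir` (a
#'   fixture-bundle directory) unless every file path is given explicitly
#'   under `inputs`. Optional: `out_dir`, `limb_volume_ml`, `gdr_window`,
#'   `bin_width`, `seed`.
#' @return resolved config list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults_in <- c(vessel_scans = "vessel_scans.tsv",
                   av_samples = "av_samples.csv",
                   clamp_log = "clamp_log.csv",
                   d2o = "d2o.csv", ams = "ams.csv", urine = "urine.csv",
                   grip = "grip.csv", fibres = "fibres.csv",
                   animals = "animals.csv",
                   muscle_mass = "muscle_mass.csv")
  inputs <- as.list(config$inputs %||% list())
  for (nm in names(defaults_in)) {
    if (is.null(inputs[[nm]])) {
      if (is.null(config$input_dir)) {
        stop("config must provide input_dir or inputs$", nm)
      }
      inputs[[nm]] <- file.path(config$input_dir, defaults_in[[nm]])
    }
  }
  list(inputs = inputs,
       input_dir = config$input_dir %||% NULL,
       out_dir = config$out_dir %||% "results",
       limb_volume_ml = config$limb_volume_ml %||% 1000,
       gdr_window = config$gdr_window %||% c(150, 180),
       bin_width = config$bin_width %||% 500,
       seed = as.integer(config$seed %||% 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full study pipeline
#'
#' Executes every analysis stage in order -- Doppler flow, arteriovenous
#' balance and two-pool kinetics, clamp glucose disposal rate, D2O
#' fractional synthesis, AMS carbon-14, urine normalization, grip and
#' myofibre phenotyping, and group contrasts -- and writes one tidy CSV per
#' stage plus a run log (`run_log.yaml` with the config fingerprint and
#' seed; no timestamps, so outputs are byte-identical across reruns).
#' Any stage whose input file is missing or invalid aborts with the stage
#' name.
#'
#' @param config pipeline configuration (list or YAML path); see
#'   [pipeline_config()].
#' @return (invisibly) named list of the stage result data.frames and
#'   `out_dir`.
#' @export
run_full_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  stage <- function(name, files, fun) {
    for (f in files) {
      if (!file.exists(f)) {
        stop("stage '", name, "' failed: input file not found: ", f)
      }
    }
    tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  wcsv <- function(x, name) {
    utils::write.csv(x, file.path(cfg$out_dir, name), row.names = FALSE,
                     quote = FALSE)
    x
  }
  inp <- cfg$inputs

  results$flow <- stage("hemodynamics", inp$vessel_scans, function() {
    wcsv(flow_table(inp$vessel_scans, cfg$limb_volume_ml), "flow.csv")
  })

  results$kinetics <- stage("av_balance",
                            c(inp$av_samples), function() {
    samples <- utils::read.csv(inp$av_samples)
    flows <- results$flow
    # assign scan timepoints to phases: t <= 0 postabsorptive, else clamp
    flows$phase <- ifelse(flows$timepoint_min <= 0, "postabsorptive",
                          "clamp")
    wcsv(kinetics_table(samples, flows), "kinetics.csv")
  })

  results$gdr <- stage("clamp_protocol", inp$clamp_log, function() {
    log <- utils::read.csv(inp$clamp_log)
    rows <- lapply(unique(log$subject_id), function(sid) {
      sl <- log[log$subject_id == sid, ]
      g <- gdr_from_log(sl[, c("time_min", "pump_ml_h", "glucose_mmol_l")],
                        mass_kg = sl$body_mass_kg[1],
                        window = cfg$gdr_window)
      data.frame(subject_id = sid, gdr_mg_kg_min = g$gdr,
                 mean_glucose_mmol_l = g$mean_glucose,
                 cv_glucose_pct = g$cv_glucose,
                 window_start = g$window[1], window_end = g$window[2],
                 stringsAsFactors = FALSE)
    })
    wcsv(do.call(rbind, rows), "gdr.csv")
  })

  results$fsr <- stage("isotope_turnover_fsr", inp$d2o, function() {
    d2o <- utils::read.csv(inp$d2o)
    fsr <- cumulative_fsr(d2o$e_ala_mpe, d2o$e_bw_mpe,
                          label_days = d2o$label_days)
    wcsv(cbind(d2o[, c("animal_id", "limb")], fsr), "fsr.csv")
  })

  results$c14 <- stage("isotope_turnover_ams", inp$ams, function() {
    ams <- utils::read.csv(inp$ams)
    tc <- total_14c(ams$ratio_14c_12c, ams$carbon_fraction, ams$dry_mass_mg)
    wcsv(cbind(ams[, c("animal_id", "limb", "ratio_14c_12c")], tc),
         "c14.csv")
  })

  results$urine <- stage("isotope_turnover_urine", inp$urine, function() {
    wcsv(normalize_urine(inp$urine)$normalized, "urine_normalized.csv")
  })

  results$grip <- stage("phenotyping_grip", inp$grip, function() {
    wcsv(grip_table(inp$grip), "grip_scores.csv")
  })

  results$csa <- stage("phenotyping_fibres", inp$fibres, function() {
    fibres <- utils::read.csv(inp$fibres)
    rows <- lapply(unique(fibres$limb), function(lb) {
      d <- csa_distribution(fibres[fibres$limb == lb, ],
                            bin_width = cfg$bin_width)
      cbind(limb = lb, d$bins)
    })
    wcsv(do.call(rbind, rows), "csa_bins.csv")
  })

  results$contrasts <- stage(
    "study_contrasts",
    c(inp$animals, inp$muscle_mass), function() {
      animals <- utils::read.csv(inp$animals)
      cohort <- build_cohort_table(animals,
                                   muscle_mass = inp$muscle_mass,
                                   fsr = results$fsr, c14 = results$c14,
                                   grip = results$grip)
      wcsv(cohort, "cohort.csv")
      wcsv(standard_contrasts(cohort), "contrasts.csv")
    })

  # fingerprint and record only the analysis-relevant configuration: the
  # output location must not change the bytes of the results
  cfg_log <- cfg[setdiff(names(cfg), "out_dir")]
  log <- list(package = "limbflux",
              version = as.character(utils::packageVersion("limbflux")),
              seed = cfg$seed,
              config_hash = config_hash(cfg_log),
              config = cfg_log,
              rows = lapply(results, NROW))
  yaml::write_yaml(log, file.path(cfg$out_dir, "run_log.yaml"))
  results$out_dir <- cfg$out_dir
  invisible(results)
}

#' Assemble a long-format cohort endpoint table from stage outputs
#'
#' Joins per-animal muscle masses, FSR, 14C ratios and grip scores to the
#' group assignment table, producing the long cohort format consumed by
#' [group_contrast()] and [standard_contrasts()].
#'
#' @param animals data.frame with `unit_id`, `group`.
#' @param muscle_mass data.frame or CSV path: `animal_id`, `limb`,
#'   `quadriceps_mass_mg`, `gastrocnemius_mass_mg`.
#' @param fsr data.frame: `animal_id`, `limb`, `fsr_cum_pct`.
#' @param c14 data.frame: `animal_id`, `limb`, `ratio_14c_12c`.
#' @param grip data.frame: `animal_id`, `grip_n`.
#' @return long data.frame: unit_id, group, occasion, limb, endpoint, value.
#' @export
build_cohort_table <- function(animals, muscle_mass, fsr, c14, grip) {
  if (is.character(muscle_mass)) muscle_mass <- utils::read.csv(muscle_mass)
  grp <- stats::setNames(animals$group, animals$unit_id)
  long <- function(id, limb, endpoint, value) {
    data.frame(unit_id = id, group = unname(grp[as.character(id)]),
               occasion = "terminal", limb = limb, endpoint = endpoint,
               value = value, stringsAsFactors = FALSE)
  }
  out <- rbind(
    long(muscle_mass$animal_id, muscle_mass$limb, "quadriceps_mass_mg",
         muscle_mass$quadriceps_mass_mg),
    long(muscle_mass$animal_id, muscle_mass$limb, "gastrocnemius_mass_mg",
         muscle_mass$gastrocnemius_mass_mg),
    long(fsr$animal_id, fsr$limb, "fsr_cum_pct", fsr$fsr_cum_pct),
    long(c14$animal_id, c14$limb, "ratio_14c_12c", c14$ratio_14c_12c),
    long(grip$animal_id, "n/a", "grip_n", grip$grip_n))
  rownames(out) <- NULL
  out
}
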