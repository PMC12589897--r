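test_that("forearm inversion produces the implied venous state", {
  fa <- simulate_forearm(f = 3, c_a = 60, e_a = 0.08, rd_true = 40,
                         ra_true = 15)
  expect_equal(fa$truth$c_v, 51.6667, tolerance = 1e-4)
  expect_equal(fa$truth$e_v, 0.072258, tolerance = 1e-5)
  k <- two_pool_kinetics(fa$samples$c_a_umol_l, fa$samples$c_v_umol_l,
                         fa$samples$ttr_a, fa$samples$ttr_v, fa$flows)
  expect_equal(unique(k$rd), 40, tolerance = 1e-9)
  expect_equal(unique(k$ra), 15, tolerance = 1e-9)
  # rd = ra: zero net balance with ongoing turnover dilutes venous
  # enrichment below arterial at equal concentrations
  eq <- simulate_forearm(3, 60, 0.08, 20, 20)
  expect_equal(eq$truth$c_v, 60)
  expect_lt(eq$truth$e_v, 0.08)
  # rd = ra = 0: venous state equals arterial state
  z <- simulate_forearm(3, 60, 0.08, 0, 0)
  expect_equal(z$truth$c_v, z$truth$c_a)
  expect_equal(z$truth$e_v, z$truth$e_a)
})

test_that("unphysical forearm truths are rejected with the violated bound", {
  # nb too large: implied venous concentration non-positive
  expect_error(simulate_forearm(1, 30, 0.08, 40, 0), "c_v")
  # rd above c_a * f: implied venous enrichment non-positive
  expect_error(simulate_forearm(1, 30, 0.08, 31, 15), "e_v")
  expect_error(simulate_forearm(3, 60, 0.08, 40, 15,
                                glucose_uptake_true = 50), "glu_v")
})

test_that("noise widens estimator dispersion monotonically", {
  # common random numbers: same seed across the CV grid
  cvs <- c(0, 0.02, 0.05, 0.10)
  spread <- vapply(cvs, function(cv) {
    rd <- vapply(1:40, function(i) {
      fa <- simulate_forearm(3, 60, 0.08, 40, 15, n_samples = 5,
                             cv_conc = cv, cv_enrich = cv, seed = i)
      window_summary(fa$samples, fa$flows)$mean[["rd"]]
    }, numeric(1))
    stats::sd(rd)
  }, numeric(1))
  expect_true(all(diff(spread) > 0))
})

test_that("simulated vessel scans integrate back to the target TAMV", {
  sc <- simulate_vessel_scan(12.5, 0.42, n_cycles = 10)
  expect_equal(time_averaged_mean_velocity(sc$time_s, sc$velocity_cm_s),
               12.5, tolerance = 1e-9)
})

test_that("cohort generator couples FSR and label retention negatively", {
  mc <- simulate_mouse_cohort(seed = 42)
  fsr <- mc$cohort[mc$cohort$endpoint == "fsr_cum_pct", ]
  ratio <- mc$cohort[mc$cohort$endpoint == "ratio_14c_12c", ]
  m <- merge(fsr, ratio, by = c("unit_id", "limb"))
  cc <- fsr_turnover_correlation(m$value.x, m$value.y)
  expect_identical(cc$sign, "negative")
  expect_equal(cc$n, 75)  # 15 healthy limbs + 2 x 30 intervention limbs
})

test_that("cohort D2O and AMS tables round-trip through the estimators", {
  mc <- simulate_mouse_cohort(seed = 9)
  fsr <- cumulative_fsr(mc$d2o$e_ala_mpe, mc$d2o$e_bw_mpe)
  truth <- mc$cohort[mc$cohort$endpoint == "fsr_cum_pct", ]
  key_d2o <- paste(mc$d2o$animal_id, mc$d2o$limb)
  key_truth <- paste(truth$unit_id, truth$limb)
  expect_equal(fsr$fsr_cum_pct, truth$value[match(key_d2o, key_truth)],
               tolerance = 1e-9)
  expect_true(all(total_14c(mc$ams$ratio_14c_12c, mc$ams$carbon_fraction,
                            mc$ams$dry_mass_mg)$flag == "ok"))
})

test_that("cohort generation is deterministic per seed", {
  a <- simulate_mouse_cohort(seed = 4)
  b <- simulate_mouse_cohort(seed = 4)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$fibres, b$fibres)
  c <- simulate_mouse_cohort(seed = 5)
  expect_false(identical(a$cohort$value, c$cohort$value))
})

test_that("urine output reflects higher excretion under atrophy", {
  cfg <- cohort_defaults()
  cfg$noise$cv_urine <- 0
  cfg$noise$sd_urine_turnover <- 0
  mc <- simulate_mouse_cohort(cfg, seed = 6)
  nu <- normalize_urine(mc$urine)$normalized
  nu <- merge(nu, unique(mc$cohort[, c("unit_id", "group")]),
              by.x = "animal_id", by.y = "unit_id")
  d3 <- nu[nu$day == 3, ]
  m <- tapply(d3$pct_of_day0, d3$group, mean)
  expect_gt(m[["control"]], m[["healthy"]])
  expect_gt(m[["control"]], m[["salbutamol"]])
  expect_true(all(nu$pct_of_day0[nu$day == 0] == 100))
})
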