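test_that("time-averaged mean velocity matches closed-form integrals", {
  # constant signal
  expect_equal(time_averaged_mean_velocity(0:10, rep(10, 11)), 10)
  # linear ramp 0 -> 20 over any duration averages to 10 by symmetry
  expect_equal(time_averaged_mean_velocity(c(0, 3.7), c(0, 20)), 10)
  expect_equal(time_averaged_mean_velocity(seq(0, 1, 0.1),
                                           seq(0, 20, 2)), 10)
  # v(t) = 10 + 5 sin(2 pi t) over exactly 2 periods at 100 Hz: the
  # sinusoid integrates to zero, leaving the 10 cm/s mean
  t <- seq(0, 2, by = 0.01)
  v <- 10 + 5 * sin(2 * pi * t)
  expect_equal(time_averaged_mean_velocity(t, v), 10, tolerance = 0.01 / 10)
})

test_that("degenerate velocity traces are rejected", {
  expect_error(time_averaged_mean_velocity(1, 10), "at least 2")
  expect_error(time_averaged_mean_velocity(c(0, 2, 1), c(1, 2, 3)),
               "strictly increasing")
  expect_error(time_averaged_mean_velocity(c(0, 0, 1), c(1, 2, 3)),
               "strictly increasing")
  expect_error(time_averaged_mean_velocity(c(0, 1), c(1, NA)),
               "non-finite")
})

test_that("flow computation matches hand arithmetic", {
  t <- 0:9
  v <- rep(10, 10)
  fl <- compute_flow(0.40, t, v, limb_volume_ml = 1000,
                     n_cardiac_cycles = 10)
  expect_equal(fl$area_cm2, pi * 0.2^2)
  expect_equal(fl$q_ml_min, pi * 0.2^2 * 10 * 60)  # 75.39822...
  expect_equal(fl$q_ml_min, 75.40, tolerance = 1e-4)
  expect_equal(fl$f_per100ml, fl$q_ml_min / 1000 * 100)
  expect_equal(fl$f_per100ml, 7.540, tolerance = 1e-4)
  # zero velocity -> zero flow
  z <- compute_flow(0.40, t, rep(0, 10), 1000, 10)
  expect_equal(z$q_ml_min, 0)
  expect_equal(z$f_per100ml, 0)
  # duplicate diameter acquisitions are averaged before area
  fl2 <- compute_flow(c(0.38, 0.42), t, v, 1000, 10)
  expect_equal(fl2$area_cm2, pi * 0.2^2)
})

test_that("under-sampled scans are flagged and excluded unless overridden", {
  t <- 0:9
  v <- rep(10, 10)
  fl <- compute_flow(0.4, t, v, 1000, n_cardiac_cycles = 5)
  expect_identical(fl$flag, "insufficient_cycles")
  expect_true(is.na(fl$q_ml_min) && is.na(fl$f_per100ml))
  fl2 <- compute_flow(0.4, t, v, 1000, n_cardiac_cycles = 5,
                      override = TRUE)
  expect_identical(fl2$flag, "insufficient_cycles")
  expect_equal(fl2$q_ml_min, pi * 0.2^2 * 10 * 60)
})

test_that("flow is linear in velocity and quadratic in diameter", {
  set.seed(11)
  t <- sort(runif(50, 0, 8))
  v <- runif(50, -5, 40)  # retrograde samples retained in the integral
  base <- compute_flow(0.4, t, v, 1000, 10)
  dbl <- compute_flow(0.4, t, 2 * v, 1000, 10)
  expect_identical(dbl$q_ml_min, 2 * base$q_ml_min)
  wide <- compute_flow(0.8, t, v, 1000, 10)
  expect_equal(wide$q_ml_min, 4 * base$q_ml_min, tolerance = 1e-9)
})

test_that("normalized flow is invariant to splitting a trace", {
  # splitting one trace into two equal-duration halves (sharing the
  # junction sample) and averaging their f_norm reproduces the full-trace
  # value
  set.seed(3)
  t <- seq(0, 2, 0.01)
  v <- 12 + 4 * sin(2 * pi * t) + rnorm(length(t), 0, 0.5)
  mid <- which(t == 1)
  full <- compute_flow(0.4, t, v, 1000, 10)
  a <- compute_flow(0.4, t[1:mid], v[1:mid], 1000, 10)
  b <- compute_flow(0.4, t[mid:length(t)], v[mid:length(t)], 1000, 10)
  expect_equal(full$f_per100ml, (a$f_per100ml + b$f_per100ml) / 2,
               tolerance = 1e-12)
})

test_that("flow_table reads scan indices and trace files", {
  dir <- withr::local_tempdir()
  sc <- simulate_vessel_scan(8, 0.4, n_cycles = 10)
  write.csv(data.frame(time_s = sc$time_s,
                       velocity_cm_s = sc$velocity_cm_s),
            file.path(dir, "tr1.csv"), row.names = FALSE)
  idx <- data.frame(subject_id = "s01", timepoint_min = -30,
                    diameter_cm = 0.4, n_cycles = 10,
                    trace_file = "tr1.csv")
  write.table(idx, file.path(dir, "vessel_scans.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  ft <- flow_table(file.path(dir, "vessel_scans.tsv"),
                   limb_volume_ml = 1000)
  expect_equal(ft$tamv_cm_s, 8, tolerance = 1e-9)
  expect_equal(ft$q_ml_min, 8 * pi * 0.2^2 * 60, tolerance = 1e-9)
  expect_error(flow_table(idx[, -5], 1000), "missing columns")
})
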