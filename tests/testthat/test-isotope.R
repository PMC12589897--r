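test_that("cumulative FSR follows the precursor-product formula", {
  expect_equal(cumulative_fsr(0.30, 3.0)$fsr_cum_pct,
               0.30 / (3.0 * 3.7) * 100)          # 2.7027...
  expect_equal(cumulative_fsr(0.30, 3.0)$fsr_cum_pct, 2.7027,
               tolerance = 1e-4)
  expect_equal(cumulative_fsr(0, 3.0)$fsr_cum_pct, 0)
  # inverse proportionality to the precursor over a grid
  bw <- c(0.5, 1, 2, 4, 8)
  f <- cumulative_fsr(0.3, bw)$fsr_cum_pct
  expect_equal(f, f[2] * 1 / bw * bw[2], tolerance = 1e-12)
  expect_equal(cumulative_fsr(0.3, bw / 2)$fsr_cum_pct, 2 * f)
  # scale invariance to shared enrichment units
  expect_equal(cumulative_fsr(0.3 * 10, 3 * 10)$fsr_cum_pct,
               cumulative_fsr(0.3, 3)$fsr_cum_pct)
  # per-day rate
  expect_equal(cumulative_fsr(0.30, 3.0, label_days = 13)$fsr_per_day,
               0.30 / (3.0 * 3.7) * 100 / 13)
  expect_error(cumulative_fsr(0.3, 0), "must be > 0")
})

test_that("product enrichment above the precursor-equivalent is flagged", {
  expect_warning(res <- cumulative_fsr(12, 3.0), "super_precursor")
  expect_identical(res$flag, "super_precursor")
  expect_gt(res$fsr_cum_pct, 100)  # still reported
})

test_that("total 14C combines ratio, carbon fraction and dry mass", {
  expect_equal(total_14c(0, 0.45, 5)$total_14c_mol, 0)
  r <- total_14c(2e-12, 0.45, 5)
  expect_equal(r$total_14c_mol, (0.005 * 0.45 / 12) * 2e-12)  # 3.75e-16
  expect_identical(r$flag, "ok")
  # extensive vs intensive: doubling mass doubles the total, not the
  # per-mg value
  r2 <- total_14c(2e-12, 0.45, 10)
  expect_equal(r2$total_14c_mol, 2 * r$total_14c_mol)
  expect_equal(r2$c14_mol_per_mg, r$c14_mol_per_mg)
  expect_identical(r2$flag, "mass_out_of_protocol")
  expect_identical(total_14c(2e-12, 0.45, 2)$flag, "mass_out_of_protocol")
})

test_that("urine series are normalized to Day 0 per animal", {
  u <- data.frame(animal_id = rep(c("a", "b", "c"), each = 3),
                  day = rep(c(0, 3, 7), 3),
                  activity = c(200, 180, 150, 50, 50, 50, 0, 10, 10))
  res <- normalize_urine(u)
  a <- res$normalized[res$normalized$animal_id == "a", ]
  expect_equal(a$pct_of_day0, c(100, 90, 75))
  b <- res$normalized[res$normalized$animal_id == "b", ]
  expect_equal(b$pct_of_day0, c(100, 100, 100))  # constant series
  expect_equal(res$excluded$animal_id, "c")      # zero Day 0
  expect_identical(res$excluded$reason, "nonpositive_day0")
  # single-day series
  one <- normalize_urine(data.frame(animal_id = "x", day = 0,
                                    activity = 42))
  expect_equal(one$normalized$pct_of_day0, 100)
  # missing day 0
  m <- normalize_urine(data.frame(animal_id = "y", day = 3, activity = 9))
  expect_identical(m$excluded$reason, "missing_day0")
})

test_that("urine normalization is idempotent", {
  u <- data.frame(animal_id = "a", day = c(0, 3, 7),
                  activity = c(200, 180, 150))
  once <- normalize_urine(u)$normalized
  again <- normalize_urine(data.frame(animal_id = once$animal_id,
                                      day = once$day,
                                      activity = once$pct_of_day0))
  expect_equal(again$normalized$pct_of_day0, once$pct_of_day0)
})

test_that("FSR-turnover correlation reports signed rank correlation", {
  fsr <- c(1, 2, 3, 4, 5)
  expect_equal(fsr_turnover_correlation(fsr, 10 - fsr)$rho, -1)
  expect_identical(fsr_turnover_correlation(fsr, 10 - fsr)$sign,
                   "negative")
  expect_equal(fsr_turnover_correlation(fsr, exp(fsr))$rho, 1)
  # independent noise: coefficient near zero (seeded)
  set.seed(31)
  x <- rnorm(200)
  y <- rnorm(200)
  expect_lt(abs(fsr_turnover_correlation(x, y)$rho), 0.15)
  # degenerate inputs
  expect_identical(fsr_turnover_correlation(rep(1, 5), 1:5)$sign,
                   "undefined")
  expect_error(fsr_turnover_correlation(1:2, 2:1), "at least 3")
})
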