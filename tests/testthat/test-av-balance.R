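test_that("net balance and glucose uptake are the AV gradient times flow", {
  expect_equal(net_balance(60, 60, 3), 0)
  expect_equal(net_balance(60, 50, 3), 30)
  expect_equal(net_balance(50, 60, 3), -30)  # net release
  expect_equal(glucose_uptake(5.0, 5.0, 3), 0)
  expect_equal(glucose_uptake(5.0, 4.8, 3), 0.6)  # 0.2 umol/mL x 3
  expect_equal(glucose_uptake(5.0, 4.8, 6), 2 * glucose_uptake(5.0, 4.8, 3))
  expect_error(net_balance(60, 50, -1))
})

test_that("two-pool kinetics honour the worked examples", {
  # equal enrichments: no venous dilution, so no release
  k <- two_pool_kinetics(60, 55, 0.08, 0.08, 3)
  expect_equal(k$nb, 15)
  expect_equal(k$rd, 15)
  expect_equal(k$ra, 0)
  # forward-simulated truth (rd = 40, nb = 25, ra = 15)
  k2 <- two_pool_kinetics(60, 51.6666666666667, 0.08, 0.0722580645161290, 3)
  expect_equal(k2$rd, 40, tolerance = 1e-9)
  expect_equal(k2$ra, 15, tolerance = 1e-9)
  expect_equal(k2$nb, 25, tolerance = 1e-9)
  # identical arterial and venous state
  k3 <- two_pool_kinetics(60, 60, 0.08, 0.08, 3)
  expect_equal(unlist(k3), c(nb = 0, rd = 0, ra = 0))
  expect_error(two_pool_kinetics(60, 55, 0, 0.07, 3), "e_a must be > 0")
})

test_that("nb = rd - ra and noise-free recovery hold over random sets", {
  sets <- random_two_pool_sets(2000, seed = 101)
  k <- two_pool_kinetics(sets$c_a, sets$c_v, sets$e_a, sets$e_v, sets$f)
  expect_true(all(abs(k$nb - (k$rd - k$ra)) < 1e-9))
  expect_true(all(abs(k$rd - sets$rd) <= 1e-9 * pmax(1, abs(sets$rd))))
  expect_true(all(abs(k$ra - sets$ra) <= 1e-9 * pmax(1, abs(sets$ra))))
})

test_that("venous enrichment dilution drives rd and ra together", {
  # rising e_v means less venous tracer dilution, i.e. less unlabelled
  # efflux: both rd and ra fall strictly, reaching ra = 0 at e_v = e_a,
  # while nb is independent of enrichment
  e_v <- seq(0.01, 0.08, by = 0.005)
  k <- two_pool_kinetics(60, 52, 0.08, e_v, 3)
  expect_true(all(diff(k$rd) < 0))
  expect_true(all(diff(k$ra) < 0))
  expect_equal(k$ra[length(e_v)], 0)
  expect_equal(k$nb, rep(k$nb[1], length(e_v)))  # nb independent of e_v
})

test_that("kinetics commute with concentration unit rescaling", {
  # converting concentration units before vs after the computation gives
  # results on the corresponding scale
  k <- two_pool_kinetics(60, 52, 0.08, 0.07, 3)
  k_scaled <- two_pool_kinetics(60e3, 52e3, 0.08, 0.07, 3)
  expect_equal(k_scaled$rd / 1e3, k$rd, tolerance = 1e-12)
  expect_equal(k_scaled$nb / 1e3, k$nb, tolerance = 1e-12)
})

test_that("window summary aggregates per-sample kinetics", {
  s1 <- data.frame(c_a_umol_l = 60, c_v_umol_l = 52, ttr_a = 0.08,
                   ttr_v = 0.07, glu_a_mmol_l = 5, glu_v_mmol_l = 4.8)
  five <- s1[rep(1, 5), ]
  w <- window_summary(five, flows = 3)
  one <- window_summary(s1, flows = 3)
  expect_equal(w$mean[["rd"]], one$mean[["rd"]])
  expect_equal(w$se[["rd"]], 0)
  expect_equal(w$n, 5)
  # mean nb is the arithmetic mean of per-sample nb
  fa <- simulate_forearm(3, 60, 0.08, 40, 15, n_samples = 5,
                         cv_conc = 0.05, cv_enrich = 0.03, seed = 5)
  w2 <- window_summary(fa$samples, fa$flows)
  expect_equal(w2$mean[["nb"]], mean(w2$per_sample$nb))
  expect_error(window_summary(s1[0, ], 3), "no samples")
  expect_error(window_summary(s1, numeric(0)), "no flow")
})

test_that("per-sample and mean-first estimators agree when noise-free", {
  fa <- simulate_forearm(3, 60, 0.08, 40, 15, n_samples = 5)
  a <- window_summary(fa$samples, fa$flows, estimator = "per_sample")
  b <- window_summary(fa$samples, fa$flows, estimator = "mean_first")
  expect_equal(a$mean[c("nb", "rd", "ra")], b$mean[c("nb", "rd", "ra")],
               tolerance = 1e-12)
})

test_that("noisy steady-state windows recover truth within sampling error", {
  fa <- simulate_forearm(3, 60, 0.08, 40, 15, n_samples = 5,
                         cv_conc = 0.02, cv_enrich = 0.015, cv_flow = 0.08,
                         seed = 77)
  w <- window_summary(fa$samples, fa$flows)
  expect_lt(abs(w$mean[["rd"]] - 40), 3 * max(w$se[["rd"]], 40 * 0.08))
  expect_lt(abs(w$mean[["nb"]] - 25), 3 * max(w$se[["nb"]], 25 * 0.08))
})
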