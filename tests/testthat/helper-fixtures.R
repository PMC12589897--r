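# Random physical two-pool parameter sets (vectorized) with the implied
# noise-free venous state. Physicality: rd < c_a * f keeps e_v > 0 and
# ra >= 0 keeps e_v <= e_a.
random_two_pool_sets <- function(n, seed) {
  set.seed(seed)
  f <- runif(n, 1, 6)
  c_a <- runif(n, 20, 150)
  e_a <- runif(n, 0.02, 0.12)
  rd <- runif(n, 0, 0.8 * c_a * f)
  ra <- runif(n, 0, 60)
  nb <- rd - ra
  c_v <- c_a - nb / f
  e_v <- e_a * (c_a * f - rd) / (c_v * f)
  data.frame(f = f, c_a = c_a, e_a = e_a, rd = rd, ra = ra, nb = nb,
             c_v = c_v, e_v = e_v)
}

make_constant_log <- function(pump_ml_h = 210, t = seq(0, 180, 5)) {
  data.frame(time_min = t, pump_ml_h = pump_ml_h, glucose_mmol_l = 5)
}
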