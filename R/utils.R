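#' @keywords internal
"_PACKAGE"

# Molar mass of anhydrous glucose (mg/mmol); used to convert mg-based
# infusion rates into mmol/L pool dynamics.
GLUCOSE_MG_PER_MMOL <- 180.156

#' Split a master seed into named sub-seeds
#'
#' All stochastic generators in the package draw their randomness from a
#' single integer seed. Sub-streams (one per simulated channel or stage) are
#' derived deterministically so that adding a new channel never perturbs the
#' draws of existing ones. Derived seeds stay within the 32-bit integer
#' range.
#'
#' @param seed master integer seed.
#' @param labels character vector of stream labels.
#' @return named integer vector of sub-seeds.
#' @export
split_seed <- function(seed, labels) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(labels))
  out <- vapply(labels, function(lab) {
    h <- fnv1a32(paste0(lab, ":", format(seed, scientific = FALSE)))
    as.integer(h %% 2147483647)
  }, integer(1))
  stats::setNames(out, labels)
}

# 32-bit FNV-1a hash of a character scalar, returned as a double in
# [0, 2^32). Used for seed splitting and for config fingerprints in run
# logs; dependency-free and platform-stable. Arithmetic is done on doubles
# with an explicit 16/16-bit split so every intermediate stays below 2^53.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    h_lo <- h %% 65536
    h_hi <- (h - h_lo) / 65536
    h <- (h_lo * 16777619 + ((h_hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

#' Fingerprint an R object for run logs
#'
#' Canonicalizes the object through YAML serialization and hashes it with
#' 32-bit FNV-1a. Stable across sessions for the plain lists used as
#' pipeline configs.
#'
#' @param x an R object (typically a config list).
#' @return character scalar, 8 hex digits.
#' @export
config_hash <- function(x) {
  h <- fnv1a32(yaml::as.yaml(x))
  hi <- (h - h %% 65536) / 65536
  sprintf("%04x%04x", as.integer(hi), as.integer(h %% 65536))
}

# Multiplicative mean-one log-normal noise: exp(sigma * z - sigma^2 / 2)
# has expectation exactly 1, so noisy channels stay unbiased around their
# configured means. `cv` is interpreted as sigma on the log scale (for the
# small CVs used here the two agree to second order).
lognorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  exp(stats::rnorm(n, mean = -cv^2 / 2, sd = cv))
}

# Standard error of the mean; NA for n < 2.
se_mean <- function(x) {
  n <- sum(!is.na(x))
  if (n < 2) return(NA_real_)
  stats::sd(x, na.rm = TRUE) / sqrt(n)
}
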