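#' Cumulative fractional synthesis rate from deuterated-water labelling
#'
#' Precursor-product calculation for D2O labelling: body water deuterium
#' equilibrates with free alanine, which carries the label into newly
#' synthesized protein. The cumulative fraction of the protein pool renewed
#' over the labelling period is
#' \deqn{FSR_{cum} = \frac{e_{product}}{e_{bodywater} \times F} \times 100}
#' where `F` is the alanine hydrogen exchange factor (default 3.7, the
#' standard value for this method; configurable because laboratories differ
#' in their precursor correction). Both enrichments must share units
#' (typically mole percent excess); the result is unit-invariant to that
#' common scale.
#'
#' @param e_product protein-bound alanine deuterium enrichment (MPE %).
#' @param e_body_water plasma-water deuterium enrichment (MPE %); must
#'   be > 0.
#' @param exchange_factor alanine hydrogen exchange factor (default 3.7).
#' @param label_days labelling duration; when given, a per-day rate
#'   (`fsr_per_day`) is reported alongside the cumulative percentage.
#' @return data.frame with `fsr_cum_pct`, `fsr_per_day` (NA when
#'   `label_days` is missing) and a `flag` column: samples whose product
#'   enrichment exceeds the precursor-equivalent
#'   (`e_body_water * exchange_factor`) are flagged `"super_precursor"`
#'   with a warning but still reported.
#' @examples
#' cumulative_fsr(0.30, 3.0)  # 2.7027 %
#' @export
cumulative_fsr <- function(e_product, e_body_water, exchange_factor = 3.7,
                           label_days = NULL) {
  stopifnot(all(e_product >= 0), all(exchange_factor > 0))
  if (any(e_body_water <= 0)) {
    stop("body-water enrichment must be > 0")
  }
  precursor <- e_body_water * exchange_factor
  fsr <- e_product / precursor * 100
  flag <- ifelse(e_product > precursor, "super_precursor", "ok")
  if (any(flag == "super_precursor")) {
    warning(sum(flag == "super_precursor"),
            " sample(s) exceed the precursor-equivalent enrichment",
            " (flagged 'super_precursor')")
  }
  per_day <- if (is.null(label_days)) NA_real_ else fsr / label_days
  data.frame(fsr_cum_pct = fsr, fsr_per_day = per_day, flag = flag,
             stringsAsFactors = FALSE)
}

#' Total carbon-14 content from an AMS readout
#'
#' Accelerator mass spectrometry reports a 14C/12C isotope ratio; combined
#' with the sample's carbon mass fraction and dry mass this gives absolute
#' 14C: `mol 12C = dry_mass * carbon_fraction / 12 g/mol` and
#' `total 14C = ratio * mol 12C`. An intensive value per mg dry tissue is
#' reported alongside. Dry masses outside the 3-8 mg protocol range are
#' flagged (`"mass_out_of_protocol"`) but not rejected.
#'
#' @param ratio_14c_12c 14C/12C isotope ratio (dimensionless, >= 0).
#' @param carbon_fraction carbon mass fraction of dry tissue (g C per g).
#' @param dry_mass_mg freeze-dried sample mass (mg); protocol range 3-8 mg.
#' @return data.frame with `total_14c_mol`, `c14_mol_per_mg` and `flag`.
#' @examples
#' total_14c(2e-12, 0.45, 5)  # 3.75e-16 mol
#' @export
total_14c <- function(ratio_14c_12c, carbon_fraction, dry_mass_mg) {
  stopifnot(all(ratio_14c_12c >= 0), all(carbon_fraction > 0),
            all(dry_mass_mg > 0))
  mol_12c <- dry_mass_mg / 1000 * carbon_fraction / 12
  tot <- ratio_14c_12c * mol_12c
  data.frame(total_14c_mol = tot,
             c14_mol_per_mg = tot / dry_mass_mg,
             flag = ifelse(dry_mass_mg < 3 | dry_mass_mg > 8,
                           "mass_out_of_protocol", "ok"),
             stringsAsFactors = FALSE)
}

#' Normalize a urinary activity time series to its Day-0 value
#'
#' Each animal's series is rescaled so that Day 0 equals 100% exactly;
#' later days are expressed relative to it. Animals with a missing or
#' non-positive Day-0 reading are excluded with a reason. The operation is
#' idempotent: normalizing an already-normalized series is a no-op.
#'
#' @param urine data.frame (or CSV path) with columns `animal_id`, `day`,
#'   `activity`.
#' @return list: `normalized` (data.frame `animal_id`, `day`,
#'   `pct_of_day0`) and `excluded` (data.frame `animal_id`, `reason`).
#' @examples
#' u <- data.frame(animal_id = 1, day = c(0, 3, 7),
#'                 activity = c(200, 180, 150))
#' normalize_urine(u)$normalized$pct_of_day0  # 100 90 75
#' @export
normalize_urine <- function(urine) {
  if (is.character(urine)) urine <- utils::read.csv(urine)
  stopifnot(all(c("animal_id", "day", "activity") %in% names(urine)))
  out <- list()
  excl <- list()
  for (id in unique(urine$animal_id)) {
    s <- urine[urine$animal_id == id, ]
    d0 <- s$activity[s$day == 0]
    if (length(d0) != 1L || is.na(d0) || d0 <= 0) {
      excl[[length(excl) + 1L]] <- data.frame(
        animal_id = id,
        reason = if (length(d0) == 0L) "missing_day0" else "nonpositive_day0",
        stringsAsFactors = FALSE)
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      animal_id = id, day = s$day, pct_of_day0 = s$activity * 100 / d0)
  }
  list(normalized = if (length(out)) do.call(rbind, out) else
         data.frame(animal_id = character(), day = numeric(),
                    pct_of_day0 = numeric()),
       excluded = if (length(excl)) do.call(rbind, excl) else
         data.frame(animal_id = character(), reason = character()))
}

#' Rank correlation between protein FSR and muscle 14C/12C ratio
#'
#' Across animal x limb pairs, higher protein turnover should both raise
#' the D2O-derived fractional synthesis rate and wash out pre-loaded 14C
#' label (lowering the 14C/12C ratio), so the two endpoints are expected to
#' correlate negatively. Spearman rank correlation is used; the signed
#' coefficient is reported (reporting conventions that quote magnitudes
#' only are a presentation choice, not a computation rule).
#'
#' @param fsr numeric vector of FSR values (one per animal x limb).
#' @param ratio numeric vector of matched 14C/12C ratios.
#' @return list: `rho` (signed Spearman coefficient), `p_value` (two-sided),
#'   `n`, `sign` ("negative"/"positive"/"zero"). Constant input vectors give
#'   `rho = NA` with `sign = "undefined"`.
#' @export
fsr_turnover_correlation <- function(fsr, ratio) {
  ok <- is.finite(fsr) & is.finite(ratio)
  fsr <- fsr[ok]
  ratio <- ratio[ok]
  if (length(fsr) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(fsr) == 0 || stats::sd(ratio) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = length(fsr),
                sign = "undefined"))
  }
  ct <- suppressWarnings(
    stats::cor.test(fsr, ratio, method = "spearman", exact = FALSE))
  rho <- unname(ct$estimate)
  list(rho = rho, p_value = ct$p.value, n = length(fsr),
       sign = if (rho < 0) "negative" else if (rho > 0) "positive" else
         "zero")
}
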