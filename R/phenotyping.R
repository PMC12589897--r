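#' Grip-strength score from five trials
#'
#' Protocol reducer: of exactly five trials, the single highest and single
#' lowest forces are excluded (one instance each when tied) and the
#' arithmetic mean of the remaining three is returned. The score is
#' invariant to trial order and always lies between the 2nd-smallest and
#' 2nd-largest trial values.
#'
#' @param forces numeric vector of exactly 5 non-negative forces (N).
#' @return scalar grip score (N).
#' @examples
#' grip_score(c(10, 12, 11, 9, 13))  # mean(10, 11, 12) = 11
#' @export
grip_score <- function(forces) {
  if (length(forces) != 5L) {
    stop("grip score requires exactly 5 trials, got ", length(forces))
  }
  stopifnot(all(is.finite(forces)), all(forces >= 0))
  s <- sort(forces)
  mean(s[2:4])
}

#' Grip scores for a cohort table
#'
#' @param grip data.frame (or CSV path) with columns `animal_id`,
#'   `f1`..`f5`.
#' @return data.frame: `animal_id`, `grip_n`.
#' @export
grip_table <- function(grip) {
  if (is.character(grip)) grip <- utils::read.csv(grip)
  need <- c("animal_id", paste0("f", 1:5))
  stopifnot(all(need %in% names(grip)))
  data.frame(
    animal_id = grip$animal_id,
    grip_n = apply(as.matrix(grip[, paste0("f", 1:5)]), 1, grip_score))
}

#' Myofibre cross-sectional area distribution
#'
#' Bins per-fibre CSA values into half-open, lower-inclusive bins
#' ([0, 500), [500, 1000), ...) so that printed labels like "500-999"
#' map to [500, 1000) for fractional areas too. Proportions are computed
#' per fibre type and sum to 1 within type; overall type proportions are
#' reported as well. Types represented by fewer than `min_fibres` fibres
#' (protocol: at least 35 per type) are flagged and excluded from the
#' distributional output unless `override = TRUE`.
#'
#' @param fibres data.frame (or CSV path) with columns `fibre_type`
#'   (`"I"`/`"II"`) and `csa_um2` (> 0).
#' @param bin_width bin width in um^2 (default 500).
#' @param min_fibres minimum fibre count per type (default 35).
#' @param override include under-sampled types anyway.
#' @return list: `bins` (data.frame `fibre_type`, `bin_lo`, `bin_hi`,
#'   `label`, `n`, `proportion`), `type_proportions` (data.frame
#'   `fibre_type`, `n`, `proportion` over all fibres), `excluded_types`
#'   (character).
#' @examples
#' f <- data.frame(fibre_type = rep("I", 36),
#'                 csa_um2 = c(rep(600, 24), rep(1600, 12)))
#' csa_distribution(f)$bins
#' @export
csa_distribution <- function(fibres, bin_width = 500, min_fibres = 35,
                             override = FALSE) {
  if (is.character(fibres)) fibres <- utils::read.csv(fibres)
  stopifnot(all(c("fibre_type", "csa_um2") %in% names(fibres)))
  if (nrow(fibres) == 0L) stop("fibre table is empty")
  stopifnot(all(fibres$csa_um2 > 0), bin_width > 0)

  counts <- table(fibres$fibre_type)
  type_prop <- data.frame(fibre_type = names(counts),
                          n = as.integer(counts),
                          proportion = as.numeric(counts) / nrow(fibres),
                          stringsAsFactors = FALSE)
  small <- names(counts)[counts < min_fibres]
  keep <- if (override) names(counts) else setdiff(names(counts), small)

  n_bins <- ceiling(max(fibres$csa_um2) / bin_width + 1e-12)
  lo <- (seq_len(n_bins) - 1L) * bin_width
  rows <- lapply(keep, function(ty) {
    csa <- fibres$csa_um2[fibres$fibre_type == ty]
    idx <- floor(csa / bin_width) + 1L  # half-open lower-inclusive bins
    n <- tabulate(idx, nbins = n_bins)
    data.frame(fibre_type = ty, bin_lo = lo, bin_hi = lo + bin_width,
               label = sprintf("%d-%d", as.integer(lo),
                               as.integer(lo + bin_width - 1)),
               n = n, proportion = n / length(csa),
               stringsAsFactors = FALSE)
  })
  list(bins = if (length(rows)) do.call(rbind, rows) else
         data.frame(fibre_type = character(), bin_lo = numeric(),
                    bin_hi = numeric(), label = character(), n = integer(),
                    proportion = numeric()),
       type_proportions = type_prop,
       excluded_types = if (override) character(0) else small)
}
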