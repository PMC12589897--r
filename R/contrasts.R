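#' Percent change between two occasions
#'
#' Absolute-denominator convention: `(post - pre) / |pre| * 100`, so the
#' sign of the change is preserved even when the baseline is negative (as
#' for net-release balances). Zero baselines give NA (undefined).
#'
#' @param pre,post numeric vectors (recycled).
#' @return percent change; NA where `pre == 0`.
#' @examples
#' percent_change(8.4, 10.3)   # +22.6
#' percent_change(-6.8, -17)   # -150
#' @export
percent_change <- function(pre, post) {
  ifelse(pre == 0, NA_real_, (post - pre) / abs(pre) * 100)
}

#' Descriptive contrast between two cohort cells
#'
#' Compares the mean of an endpoint between two group (x limb) cells of a
#' long-format cohort table: difference of means, ratio of means, and
#' descriptive dispersion. Purely descriptive -- no inferential statistics
#' are attached; the tidy output is meant to be consumed by any stats
#' package downstream.
#'
#' @param table long-format data.frame with columns `unit_id`, `group`,
#'   `limb`, `endpoint`, `value`.
#' @param endpoint endpoint name to contrast.
#' @param group_a,group_b groups of the numerator / denominator cell.
#' @param limb_a,limb_b limb of each cell (`NULL` to pool limbs).
#' @return one-row data.frame: `endpoint`, cell labels, `mean_a`, `mean_b`,
#'   `se_a`, `se_b`, `n_a`, `n_b`, `difference` (a - b), `ratio` (a / b).
#'   Cells with fewer than 2 units give NA contrast values.
#' @export
group_contrast <- function(table, endpoint, group_a, group_b,
                           limb_a = NULL, limb_b = NULL) {
  cell <- function(grp, limb) {
    sel <- table$endpoint == endpoint & table$group == grp
    if (!is.null(limb)) sel <- sel & table$limb == limb
    table$value[sel & is.finite(table$value)]
  }
  a <- cell(group_a, limb_a)
  b <- cell(group_b, limb_b)
  ok <- length(a) >= 2 && length(b) >= 2
  data.frame(
    endpoint = endpoint,
    cell_a = paste0(group_a, if (!is.null(limb_a)) paste0(":", limb_a)),
    cell_b = paste0(group_b, if (!is.null(limb_b)) paste0(":", limb_b)),
    mean_a = if (length(a)) mean(a) else NA_real_,
    mean_b = if (length(b)) mean(b) else NA_real_,
    se_a = se_mean(a), se_b = se_mean(b),
    n_a = length(a), n_b = length(b),
    difference = if (ok) mean(a) - mean(b) else NA_real_,
    ratio = if (ok && mean(b) != 0) mean(a) / mean(b) else NA_real_,
    stringsAsFactors = FALSE)
}

#' The study's standard contrast set for a simulated cohort
#'
#' Four contrasts per limb-resolved endpoint -- caloric-restriction atrophy
#' (control vs healthy, mobile limb), the additional immobilization effect
#' (immobilized vs mobile limb within control), and the treatment effect in
#' each limb (salbutamol vs control) -- plus the control-vs-healthy
#' contrast for animal-level endpoints. Each row carries the generator's
#' configured true ratio, so estimated ratios can be compared against truth
#' directly.
#'
#' @param table long-format cohort table (see [group_contrast()]).
#' @param config the generator config the table was produced under
#'   (default [cohort_defaults()]).
#' @return data.frame of [group_contrast()] rows with extra columns
#'   `contrast` and `true_ratio`.
#' @export
standard_contrasts <- function(table, config = cohort_defaults()) {
  cm <- config$cell_multipliers
  rows <- list()
  for (ep in unique(cm$endpoint)) {
    sub <- cm[cm$endpoint == ep, ]
    m <- function(grp, limb) sub$mult[sub$group == grp & sub$limb == limb]
    if (all(c("mobile", "immobilized") %in% sub$limb)) {
      defs <- list(
        cr_atrophy = list("control", "healthy", "mobile", "mobile",
                          m("control", "mobile") / m("healthy", "mobile")),
        immobilization = list("control", "control", "immobilized", "mobile",
                              m("control", "immobilized") /
                                m("control", "mobile")),
        salbutamol_mobile = list("salbutamol", "control", "mobile", "mobile",
                                 m("salbutamol", "mobile") /
                                   m("control", "mobile")),
        salbutamol_immobilized = list("salbutamol", "control", "immobilized",
                                      "immobilized",
                                      m("salbutamol", "immobilized") /
                                        m("control", "immobilized")))
      for (nm in names(defs)) {
        d <- defs[[nm]]
        r <- group_contrast(table, ep, d[[1]], d[[2]], d[[3]], d[[4]])
        r$contrast <- nm
        r$true_ratio <- d[[5]]
        rows[[length(rows) + 1L]] <- r
      }
    } else {
      for (nm in c("cr_atrophy", "salbutamol")) {
        grp <- if (nm == "cr_atrophy") c("control", "healthy") else
          c("salbutamol", "control")
        r <- group_contrast(table, ep, grp[1], grp[2])
        r$contrast <- nm
        r$true_ratio <- m(grp[1], "n/a") / m(grp[2], "n/a")
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  do.call(rbind, rows)
}
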