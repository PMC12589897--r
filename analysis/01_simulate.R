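#!/usr/bin/env Rscript
# Generate the synthetic study: two virtual clamp subjects with paired
# arteriovenous sampling and Doppler scans, plus a calibrated three-group
# mouse cohort. Everything downstream (02-04) consumes this bundle.

library(limbflux)

seed <- 1L
fixture_dir <- "results/fixture"

unlink(fixture_dir, recursive = TRUE)
truth <- make_fixture_bundle(fixture_dir, seed = seed)

cat("Fixture bundle written to", fixture_dir, "\n")
cat("Subjects:", length(truth$subjects),
    "| forearm truth sets:", length(truth$forearm),
    "| mice:", 3 * truth$cohort_n_per_group, "\n")
cat("Forearm truths (rd/ra/nb, nmol/min/100 mL):\n")
for (key in names(truth$forearm)) {
  tr <- truth$forearm[[key]]
  cat(sprintf("  %-22s rd=%5.1f ra=%5.1f nb=%6.1f flow=%.1f\n",
              key, tr$rd, tr$ra, tr$nb, tr$f))
}
cat("Clamp disposal truths (mg/kg/min):",
    paste(vapply(truth$subjects, function(s)
      sprintf("%s=%.1f", s$subject_id, s$disposal_truth), ""),
      collapse = ", "), "\n")
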