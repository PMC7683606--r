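#!/usr/bin/env Rscript
# Step 2 — ultradian band power and surge-anticipation features.
#
# Reads the simulated datasets, applies the cleaning and inclusion rules,
# computes 2-5 h Morse wavelet band power of waking DBT and sleeping HRV
# (RMSSD), detects the first inflection / subsequent peak / post-surge
# trough of each cycle, and writes the aligned cohort curves, per-cycle
# features and the cumulative anticipation summary to results/.

library(surgewave)

for (grp in c("premenopausal", "perimenopausal")) {
  ds_path <- file.path("scratch/datasets", grp)
  if (!dir.exists(ds_path)) stop("run analysis/01_simulate_cohort.R first")
  res <- run_analyze(ds_path, file.path("results", grp),
                     channels = c("dbt", "rmssd"))
  f <- res$features
  cat(sprintf("\n%s (%d cycles analyzed):\n", grp, res$summary$n_cycles))
  for (ch in unique(f$channel)) {
    fc <- f[f$channel == ch, ]
    cat(sprintf("  %-5s inflection %6.2f (%.2f) | peak %6.2f (%.2f) | trough %5.2f (%.2f)\n",
                ch, mean(fc$inflection, na.rm = TRUE), sd(fc$inflection, na.rm = TRUE),
                mean(fc$peak, na.rm = TRUE), sd(fc$peak, na.rm = TRUE),
                mean(fc$trough, na.rm = TRUE), sd(fc$trough, na.rm = TRUE)))
  }
  if (grp == "premenopausal") {
    s <- res$summary
    cat(sprintf("  co-detected inflection by day -4: %.0f%%, by -2: %.0f%%; peak by -1: %.0f%%\n",
                100 * s$cumulative$both_inflection[s$days == -4],
                100 * s$cumulative$both_inflection[s$days == -2],
                100 * s$cumulative$both_peak[s$days == -1]))
    cat(sprintf("  intra/inter-individual range ratio (inflection): dbt %.2f, rmssd %.2f\n",
                s$range_ratio[["dbt_inflection"]], s$range_ratio[["rmssd_inflection"]]))
  }
}
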