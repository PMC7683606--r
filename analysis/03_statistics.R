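#!/usr/bin/env Rscript
# Step 3 — cohort statistics.
#
# Kruskal-Wallis comparisons of pre- vs post-surge slopes of ultradian
# power and of peak vs trough raw power (one value per cycle), for the
# premenopausal and the perimenopausal (negative control) cohorts; and
# repeated-measures ANOVA of the urinary hormone panel with per-day
# contrasts against baseline. Results go to results/statistics.csv.

library(surgewave)

rows <- list()
for (grp in c("premenopausal", "perimenopausal")) {
  stats <- jsonlite::read_json(file.path("results", grp, "stats.json"),
                               simplifyVector = TRUE)
  for (ch in names(stats)) for (nm in names(stats[[ch]])) {
    s <- stats[[ch]][[nm]]
    if (is.null(s$H)) next
    rows[[length(rows) + 1]] <- data.frame(
      group = grp, channel = ch, test = nm,
      chi2 = round(s$H, 3), df = s$df, p = signif(s$p, 4))
  }
}

# hormone rmANOVA on the premenopausal panel
recs <- read_dataset("scratch/datasets/premenopausal")
for (an in c("e2", "apg", "bpg")) {
  m <- hormone_day_matrix(recs, an)
  rma <- rm_anova_with_contrasts(m, reference_day = -7)
  rows[[length(rows) + 1]] <- data.frame(
    group = "premenopausal", channel = an, test = "rmanova_day_effect",
    chi2 = round(rma$F, 3), df = rma$df1, p = signif(rma$p, 4))
  sig <- rma$contrasts$day[rma$contrasts$p_adj < 0.05]
  cat(sprintf("%s: F(%d,%d) = %.1f, p = %.3g; days above baseline (Holm p<0.05): %s\n",
              an, rma$df1, rma$df2, rma$F, rma$p, paste(sig, collapse = " ")))
}

tab <- do.call(rbind, rows)
write.csv(tab, "results/statistics.csv", row.names = FALSE)
print(tab, row.names = FALSE)
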