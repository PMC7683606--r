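#!/usr/bin/env Rscript
# Step 4 — human-readable report.
#
# Aggregates the artifacts written by steps 2-3 (no recomputation) into
# markdown reports under results/.

library(surgewave)

for (grp in c("premenopausal", "perimenopausal")) {
  out <- run_report(file.path("results", grp))
  cat("wrote", out, "\n")
}
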