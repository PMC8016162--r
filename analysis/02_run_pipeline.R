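#!/usr/bin/env Rscript
# Step 2: run the full pipeline over the synthetic study written by
# 01_build_synthetic_study.R and print the headline results.

suppressPackageStartupMessages(library(poreflow))

agg <- run_pipeline(file.path("analysis", "results", "config.yaml"))

cat("\nstate populations (%):\n")
print(round(as.matrix(agg$populations), 1))
cat("\nconductance by condition@voltage:\n")
for (key in names(agg$conductance)) {
  cc <- agg$conductance[[key]]
  cat(sprintf("  %-16s events %s  mean %.2f pS  sd %.2f pS\n", key,
              paste(cc$events, collapse = "/"), cc$mean_pS, cc$sd_pS))
}
cat("\nper-replica summary:\n")
for (r in agg$replicas) {
  cat(sprintf("  %s +%d mV replica %d: %d events, gating %s, lipid %s\n",
              r$condition, r$voltage_mV, r$replica, r$n_events,
              r$prevalent_state,
              if (r$lipid_in_cavity) "in cavity" else "out"))
}
cat("\nreports written under analysis/results/reports/\n")
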