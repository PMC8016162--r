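#!/usr/bin/env Rscript
# Step 3: recompute the study bookkeeping from the shipped per-run
# summary tables: the four conductance lines, the total event count of
# the conducting condition, the total simulated time and the II + II'
# population sums. Writes analysis/results/study_tables.csv.

suppressPackageStartupMessages(library(poreflow))

reg <- study_registry()
cat(sprintf("%d replicas, %.0f us total\n", nrow(reg),
            registry_total_time(reg)))

conds <- list(c("AMBER", "KK", 100), c("AMBER", "KK", 200),
              c("AMBER", "KWK", 100), c("CHARMM", "KK", 200))
rows <- list()
for (cond in conds) {
  g <- condition_conductance(reg, cond[[1]], cond[[2]],
                             as.numeric(cond[[3]]))
  cat(sprintf("%s-%s +%s mV: ", cond[[1]], cond[[2]], cond[[3]]))
  print(g)
  rows[[length(rows) + 1]] <- data.frame(
    force_field = cond[[1]], init_config = cond[[2]],
    voltage_mV = as.numeric(cond[[3]]),
    mean_pS = g$mean, sd_pS = g$sd, n = g$n_replicas)
}

tab <- t(study_populations())
cat(sprintf("II + II' sums: CHARMM-KWK %.1f%%, AMBER-KWK %.1f%%\n",
            sum_states(tab, c("II", "II'"), "CHARMM-KWK"),
            sum_states(tab, c("II", "II'"), "AMBER-KWK")))

dir.create(file.path("analysis", "results"), recursive = TRUE,
           showWarnings = FALSE)
utils::write.csv(do.call(rbind, rows),
                 file.path("analysis", "results", "study_tables.csv"),
                 row.names = FALSE)
cat("wrote analysis/results/study_tables.csv\n")
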