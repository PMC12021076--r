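#!/usr/bin/env Rscript
# Long-distance regeneration at the optic chiasm: axons reaching the distal
# nerve are classified by the landmark region containing their terminal —
# pre-chiasmic (stopped or turned back before the transition zone), ipsi-
# or contralateral optic tract, or contralateral optic nerve. The fate mix
# emulates the published pattern for strongly regenerating nerves: most
# axons stall at the chiasm entrance and most that enter project
# ipsilaterally.

suppressPackageStartupMessages(library(axonreg))

out_dir <- "results/chiasm"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
lm <- chiasm_landmarks(octz_x = 500, tract_x = 900, midline_y = 100)
fate_probs <- c(pre_chiasmic = 0.62, ipsi_tract = 0.27, contra_tract = 0.06,
                contra_nerve = 0.05)

rows <- list()
for (nerve in 1:5) {
  cfg <- nerve_sim_config(n_axons = 40, nerve_length = 1200,
                          nerve_radius = 150, seed = 4000 + nerve)
  gt <- simulate_chiasm(cfg, lm, fate_probs)
  ft <- classify_chiasm_fates(gt$axons, gt$geometry)
  stopifnot(identical(unname(attr(ft, "per_axon")), gt$labels$fate))
  tm <- trajectory_metrics(gt$axons, selection = "all_in_region",
                           selection_site = 0)
  rows[[nerve]] <- data.frame(nerve = nerve, t(ft$fraction),
                              uturn_rate = tm$uturn_rate)
  names(rows[[nerve]])[2:6] <- ft$fate
}
tab <- do.call(rbind, rows)
utils::write.csv(tab, file.path(out_dir, "fate_fractions.csv"),
                 row.names = FALSE)

message("Per-nerve fate fractions (classification matched ground truth ",
        "exactly on all nerves):")
print(tab, digits = 2)
message("Mean pre-chiasmic fraction: ",
        round(mean(tab$pre_chiasmic), 3))
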