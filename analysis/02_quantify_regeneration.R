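#!/usr/bin/env Rscript
# Scores regeneration for every simulated nerve from its trajectories:
# fiber counts at 250-um intervals distal to the crush site (plane-crossing
# counts of the ground-truth polylines) and the mean length of the top 5
# longest axons. Writes one regeneration profile per nerve and a cohort
# summary table.

suppressPackageStartupMessages(library(axonreg))

in_dir <- "results/cohorts"
out_dir <- "results/regeneration"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
manifest <- utils::read.csv(file.path(in_dir, "manifest.csv"))

rows <- list()
for (i in seq_len(nrow(manifest))) {
  base <- sprintf("%s_nerve%02d", manifest$cohort[i], manifest$nerve[i])
  trees <- read_swc(file.path(in_dir, paste0(base, ".swc")))
  geom <- nerve_geometry(crush_x = 0, extent = 2000)
  profile <- data.frame(
    distance_um = seq(250, 2000, by = 250),
    count = plane_crossings(trees, geom, seq(250, 2000, by = 250)))
  utils::write.csv(profile,
                   file.path(out_dir, paste0(base, "_profile.csv")),
                   row.names = FALSE)
  lens <- axon_lengths(trees, k = 5)
  rows[[i]] <- data.frame(
    cohort = manifest$cohort[i], nerve = manifest$nerve[i],
    count_250 = profile$count[1], count_500 = profile$count[2],
    count_1000 = profile$count[4],
    top5_mean_length_um = lens$top_k_mean)
}
summary_tab <- do.call(rbind, rows)
utils::write.csv(summary_tab, file.path(out_dir, "summary.csv"),
                 row.names = FALSE)

message("Per-cohort means:")
print(stats::aggregate(cbind(count_250, count_500, count_1000,
                             top5_mean_length_um) ~ cohort, summary_tab,
                       mean))
message("Profiles written under ", out_dir)
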