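#!/usr/bin/env Rscript
# Trajectory and tip morphology per nerve: the U-turn rate and branching
# index of the top 20 longest axons (per-axon terminal angle against the
# nerve axis, one U-turn counted per axon; branching index = terminal tips
# over analyzed axons), plus the ground-truth retraction-bulb fraction.
# One imaged nerve per cohort is additionally pushed through the full
# rasterize -> binarize -> trace pipeline to confirm the image-based route
# agrees with the trajectory-based one.

suppressPackageStartupMessages(library(axonreg))

in_dir <- "results/cohorts"
out_dir <- "results/trajectory"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
manifest <- utils::read.csv(file.path(in_dir, "manifest.csv"))

rows <- list()
for (i in seq_len(nrow(manifest))) {
  base <- sprintf("%s_nerve%02d", manifest$cohort[i], manifest$nerve[i])
  trees <- read_swc(file.path(in_dir, paste0(base, ".swc")))
  labels <- utils::read.csv(file.path(in_dir, paste0(base, "_labels.csv")))
  tm <- suppressWarnings(
    trajectory_metrics(trees, selection = "top_20_longest"))
  utils::write.csv(tm$per_axon,
                   file.path(out_dir, paste0(base, "_axons.csv")),
                   row.names = FALSE)
  rows[[i]] <- data.frame(
    cohort = manifest$cohort[i], nerve = manifest$nerve[i],
    uturn_rate = tm$uturn_rate, branching_index = tm$branching_index,
    bulb_fraction = mean(labels$tip_class == "retraction_bulb"))
}
summary_tab <- do.call(rbind, rows)
utils::write.csv(summary_tab, file.path(out_dir, "summary.csv"),
                 row.names = FALSE)
message("Per-cohort trajectory metrics:")
print(stats::aggregate(cbind(uturn_rate, branching_index, bulb_fraction) ~
                         cohort, summary_tab, mean))

# image-based cross-check on one small nerve per cohort
message("\nImage-pipeline cross-check (noise-free rasterization):")
for (cohort in unique(manifest$cohort)) {
  seed <- manifest$seed[manifest$cohort == cohort][1]
  cfg <- nerve_sim_config(n_axons = 8, flat = TRUE, lane_spacing = 45,
                          nerve_radius = 400,
                          p_uturn = ifelse(cohort == "control", 0.45, 0.15),
                          branch_rate = 0.4, branch_max_len = 60, p_bulb = 0,
                          length_scale = 250, min_length = 120, seed = seed)
  gt <- simulate_nerve(cfg)
  st <- rasterize_stack(gt, imaging_config(psf_sigma = 0,
                                           shot_noise = FALSE,
                                           background = 0))
  tr <- trace_axons(binarize(st, "fixed", threshold = 1), gt$geometry)
  tm_img <- suppressWarnings(
    trajectory_metrics(tr$trees, selection = "all_in_region"))
  tm_gt <- trajectory_metrics(gt$axons, selection = "all_in_region")
  message(sprintf(
    "  %s: traced U-turn rate %.2f (truth %.2f), branching %.2f (truth %.2f)",
    cohort, tm_img$uturn_rate, tm_gt$uturn_rate, tm_img$branching_index,
    tm_gt$branching_index))
}
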