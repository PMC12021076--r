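#' Reproducible run configuration
#'
#' Collects the parameters of a quantification run — every default of the
#' scheme (counting interval, slice grouping, tip-ratio threshold, U-turn
#' angle, top-n selections, minimum-axon QC) plus a mandatory root seed —
#' into a serializable record whose hash stamps every output table, so
#' identical config + seed reproduce identical outputs.
#'
#' @param seed integer root seed (mandatory).
#' @param interval_um fiber-counting interval (um).
#' @param group_slices slices per optical section.
#' @param tip_ratio_threshold retraction-bulb threshold on tip/shaft ratio.
#' @param uturn_angle_deg U-turn angle threshold (degrees).
#' @param top_n_lengths axons in the top-length mean.
#' @param top_n_trajectories axons selected for trajectory metrics.
#' @param min_axons sciatic QC minimum.
#' @param direction_window_um tip-direction window (um).
#' @param tip_window_um,shaft_window_um,shaft_gap_um tip morphometry windows
#'   (um).
#' @param ... further named parameters stored verbatim.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed, interval_um = 250, group_slices = 4L,
                       tip_ratio_threshold = 4, uturn_angle_deg = 90,
                       top_n_lengths = 5L, top_n_trajectories = 20L,
                       min_axons = 15L, direction_window_um = 20,
                       tip_window_um = 10, shaft_window_um = 20,
                       shaft_gap_um = 10, ...) {
  if (missing(seed) || !is.finite(seed)) stop("run_config requires a seed")
  cfg <- list(seed = as.integer(seed), interval_um = interval_um,
              group_slices = as.integer(group_slices),
              tip_ratio_threshold = tip_ratio_threshold,
              uturn_angle_deg = uturn_angle_deg,
              top_n_lengths = as.integer(top_n_lengths),
              top_n_trajectories = as.integer(top_n_trajectories),
              min_axons = as.integer(min_axons),
              direction_window_um = direction_window_um,
              tip_window_um = tip_window_um,
              shaft_window_um = shaft_window_um,
              shaft_gap_um = shaft_gap_um, ...)
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "run_config")
}

#' Stable content hash of a configuration
#'
#' Polynomial rolling hash over the canonical JSON serialization; used to
#' stamp outputs.
#'
#' @param cfg a list or `run_config` (any `hash` field is excluded).
#' @return Hex string.
#' @export
config_hash <- function(cfg) {
  cfg$hash <- NULL
  s <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                        digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Quantify a nerve end-to-end
#'
#' Runs the full optic-nerve quantification scheme on either an image stack
#' (projection, fiber counting, tracing, per-axon metrics) or directly on
#' traced/simulated trees (image-free mode): regeneration profile at the
#' counting interval, per-axon lengths and top-n mean, tip-direction angles
#' and U-turn rate, branching index, and (when chiasm landmarks are present)
#' the fate table.
#'
#' @param stack an [image_stack()], or `NULL` in image-free mode.
#' @param trees list of [axon_tree()] for image-free mode (ignored when a
#'   stack is supplied).
#' @param geometry a [nerve_geometry()].
#' @param config a [run_config()].
#' @param mask_threshold threshold passed to [binarize()] (`NULL` for Otsu).
#' @param min_length minimum traced tree length (um).
#' @return Object of class `nerve_quantification`: list with `profile`
#'   (data frame `distance_um`, `count`; `NULL` in image-free mode),
#'   `lengths`, `trajectory`, `fates` (or `NULL`), `trees`, `config`.
#' @export
quantify_nerve <- function(stack = NULL, trees = NULL, geometry, config,
                           mask_threshold = NULL, min_length = 50) {
  stopifnot(inherits(config, "run_config"))
  profile <- NULL
  if (!is.null(stack)) {
    projections <- project_z(stack, group = config$group_slices)
    profile <- count_fibers(projections, geometry,
                            interval = config$interval_um,
                            threshold = mask_threshold)
    mask <- if (is.null(mask_threshold)) {
      binarize(stack, "background")
    } else {
      binarize(stack, "fixed", threshold = mask_threshold)
    }
    traced <- trace_axons(mask, geometry, min_length = min_length)
    trees <- traced$trees
  }
  if (is.null(trees) || length(trees) == 0L) {
    stop("no axons available: supply a stack or a non-empty tree list")
  }
  lens <- axon_lengths(trees, k = config$top_n_lengths)
  traj <- trajectory_metrics(
    trees, axis = geometry$axis,
    selection = if (is.null(geometry$chiasm)) "top_20_longest" else
      "all_in_region",
    n_top = config$top_n_trajectories,
    selection_site = if (is.null(geometry$chiasm)) 0 else
      geometry$chiasm$octz_x,
    direction_window = config$direction_window_um)
  fates <- if (!is.null(geometry$chiasm)) {
    classify_chiasm_fates(trees, geometry)
  } else NULL
  structure(list(profile = profile, lengths = lens, trajectory = traj,
                 fates = fates, trees = trees, config = config),
            class = "nerve_quantification")
}

#' Quantify a control / injured retina pair
#'
#' Detects Tuj1+ cells in every field of both arms, matches the Cre and p-S6
#' channels against them, and reports the survival rate, transduction rate
#' and p-S6+ fraction with per-field counts.
#'
#' @param pair a [simulate_retina_pair()] result (or any object with the
#'   same field structure).
#' @param config a [run_config()].
#' @param cell_radius expected cell radius (um) for detection.
#' @param k detection threshold in robust SDs.
#' @return Object of class `retina_quantification`: list with
#'   `survival_rate`, `transduction_rate`, `ps6_fraction` (percent),
#'   `per_field` (data frame `arm`, `field`, `n_tuj1`, `n_cre_double`,
#'   `n_ps6_double`), `config`.
#' @export
quantify_retina <- function(pair, config, cell_radius = NULL, k = 3) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(cell_radius)) cell_radius <- pair$config$cell_radius
  per_field <- list()
  for (arm in c("control", "injured")) {
    for (f in seq_along(pair[[arm]])) {
      fld <- pair[[arm]][[f]]
      tuj1 <- detect_cells(fld$channels$tuj1, fld$pixel_size, cell_radius,
                           k = k)
      cre <- detect_cells(fld$channels$cre, fld$pixel_size, cell_radius,
                          k = k)
      ps6 <- detect_cells(fld$channels$ps6, fld$pixel_size, cell_radius,
                          k = k)
      per_field[[length(per_field) + 1L]] <- data.frame(
        arm = arm, field = f, n_tuj1 = nrow(tuj1),
        n_cre_double = match_channels(tuj1, cre,
                                      radius = cell_radius)$n_matched,
        n_ps6_double = match_channels(tuj1, ps6,
                                      radius = cell_radius)$n_matched)
    }
  }
  per_field <- do.call(rbind, per_field)
  ctrl <- per_field[per_field$arm == "control", ]
  inj <- per_field[per_field$arm == "injured", ]
  all_tuj1 <- sum(per_field$n_tuj1)
  structure(list(
    survival_rate = survival_rate(inj$n_tuj1, ctrl$n_tuj1),
    transduction_rate = marker_fraction(sum(per_field$n_cre_double),
                                        all_tuj1),
    ps6_fraction = marker_fraction(sum(per_field$n_ps6_double), all_tuj1),
    per_field = per_field, config = config),
    class = "retina_quantification")
}

#' Write quantification outputs with their config stamp
#'
#' Writes the regeneration profile and per-axon metrics as CSV and a JSON
#' summary, each carrying the config hash and seed, into `dir`. A snapshot
#' of the run configuration is written beside the outputs.
#'
#' @param quant a [quantify_nerve()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_nerve_outputs <- function(quant, dir, prefix = "nerve") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- quant$config
  paths <- character(0)
  stamp <- sprintf("# config_hash=%s seed=%d", cfg$hash, cfg$seed)
  if (!is.null(quant$profile)) {
    p <- file.path(dir, paste0(prefix, "_profile.csv"))
    writeLines(c(stamp, "distance_um,count",
                 sprintf("%g,%d", quant$profile$distance_um,
                         quant$profile$count)), p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, paste0(prefix, "_axons.csv"))
  per <- quant$trajectory$per_axon
  writeLines(c(stamp, "axon,length_um,angle_deg,is_uturn,n_tips",
               sprintf("%d,%.6g,%.6g,%s,%d", per$axon, per$length_um,
                       per$angle_deg, per$is_uturn, per$n_tips)), p)
  paths <- c(paths, p)
  summary <- list(
    config_hash = cfg$hash, seed = cfg$seed,
    top_n_mean_length_um = quant$lengths$top_k_mean,
    n_axons_analyzed = quant$trajectory$n_axons_analyzed,
    uturn_rate = quant$trajectory$uturn_rate,
    branching_index = quant$trajectory$branching_index)
  if (!is.null(quant$fates)) {
    summary$fates <- as.list(stats::setNames(quant$fates$fraction,
                                             quant$fates$fate))
  }
  p <- file.path(dir, paste0(prefix, "_summary.json"))
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  p <- file.path(dir, paste0(prefix, "_config.json"))
  jsonlite::write_json(unclass(cfg), p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}

#' Read/write a run configuration as YAML
#'
#' @param cfg a [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` invisibly returns `path`; `read_run_config`
#'   returns a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals$hash <- NULL
  do.call(run_config, vals)
}
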