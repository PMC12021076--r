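#' Per-axon lengths and top-k mean length
#'
#' Length of an axon is the arc length of the longest root-to-tip path,
#' measured from the terminal end back to the crush-site root. The summary
#' statistic is the mean over the `k` longest axons (the conventional top-5);
#' with fewer than `k` axons the mean is over all present, with a warning.
#' Ties are broken by tree order so results are deterministic.
#'
#' @param trees list of [axon_tree()] (or a [trace_axons()] result).
#' @param k number of longest axons averaged (default 5).
#' @return List with `per_axon_lengths` (um, in tree order), `top_k_mean`
#'   (um) and `k_used`.
#' @export
axon_lengths <- function(trees, k = 5L) {
  trees <- as_tree_list(trees)
  if (length(trees) == 0L) stop("no axons supplied (empty tree list)")
  lens <- vapply(trees, tree_length, numeric(1))
  k_used <- min(as.integer(k), length(lens))
  if (k_used < k) {
    warning("only ", length(lens), " axon(s) present; top-", k,
            " mean computed over all of them")
  }
  ord <- order(-lens, seq_along(lens))
  list(per_axon_lengths = lens,
       top_k_mean = mean(lens[ord[seq_len(k_used)]]),
       k_used = k_used)
}

#' Classify an axonal tip by its tip/shaft width ratio
#'
#' Tips with ratio strictly greater than `threshold` (default 4) are
#' retraction bulbs; all others, including a tip measuring exactly the
#' threshold, are growth cones.
#'
#' @param ratio tip/shaft width ratio(s).
#' @param threshold classification threshold (default 4).
#' @return Character vector, `"retraction_bulb"` or `"growth_cone"`.
#' @export
classify_tip <- function(ratio, threshold = 4) {
  ifelse(ratio > threshold, "retraction_bulb", "growth_cone")
}

#' Measure terminal tip morphology of a traced axon
#'
#' The local width at a centreline point is twice the Euclidean distance
#' transform of the binary mask. The tip width is the maximal width over the
#' terminal `tip_window` of arc length of the main root-to-tip path; the
#' shaft diameter is the median width over a `shaft_window` starting
#' `shaft_gap` proximal to the tip window. The tip/shaft ratio classifies the
#' tip as retraction bulb (> `threshold`) or growth cone.
#'
#' @param tree an [axon_tree()] whose terminal lies inside the mask.
#' @param mask a [binarize()] result (or any list with logical `data`,
#'   `voxel`, `origin`).
#' @param tip_window terminal window for the maximal tip width (um).
#' @param shaft_window window for the representative shaft width (um).
#' @param shaft_gap gap between tip window and shaft window (um).
#' @param threshold classification threshold on the ratio.
#' @return Object of class `tip_measurement`: list with `tip_width`,
#'   `shaft_diameter`, `ratio`, `klass`.
#' @export
measure_tip <- function(tree, mask, tip_window = 10, shaft_window = 20,
                        shaft_gap = 10, threshold = 4) {
  path <- tree_main_path(tree)
  xyz <- node_xyz(tree, path)
  n <- nrow(xyz)
  seg <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-n, , drop = FALSE])^2))
  arc_from_tip <- rev(c(0, cumsum(rev(seg))))
  need <- tip_window + shaft_gap + shaft_window
  if (arc_from_tip[1] < need) {
    stop("axon too short for tip morphometry: main path ",
         round(arc_from_tip[1], 1), " um < ", need, " um")
  }
  dt <- edt3d(as.logical(mask$data), dim(mask$data), mask$voxel)
  dim(dt) <- dim(mask$data)
  width_at <- function(rows) {
    idx <- sweep(xyz[rows, , drop = FALSE], 2, mask$origin)
    idx <- round(sweep(idx, 2, mask$voxel, "/")) + 1
    idx[, 1] <- pmin(pmax(idx[, 1], 1), dim(dt)[1])
    idx[, 2] <- pmin(pmax(idx[, 2], 1), dim(dt)[2])
    idx[, 3] <- pmin(pmax(idx[, 3], 1), dim(dt)[3])
    2 * dt[cbind(idx[, 1], idx[, 2], idx[, 3])]
  }
  tip_rows <- which(arc_from_tip <= tip_window)
  shaft_rows <- which(arc_from_tip > tip_window + shaft_gap &
                      arc_from_tip <= tip_window + shaft_gap + shaft_window)
  tip_width <- max(width_at(tip_rows))
  shaft_diameter <- stats::median(width_at(shaft_rows))
  if (shaft_diameter <= 0) stop("shaft width measured as zero; terminal not inside mask?")
  ratio <- tip_width / shaft_diameter
  structure(list(tip_width = tip_width, shaft_diameter = shaft_diameter,
                 ratio = ratio, klass = classify_tip(ratio, threshold)),
            class = "tip_measurement")
}

#' @export
print.tip_measurement <- function(x, ...) {
  cat(sprintf("<tip: width %.2f um / shaft %.2f um = ratio %.2f -> %s>\n",
              x$tip_width, x$shaft_diameter, x$ratio, x$klass))
  invisible(x)
}

#' Detect a U-turn from the terminal trajectory direction
#'
#' The direction of the axonal tip is taken over the terminal
#' `direction_window` of arc length of the main root-to-tip path; a turning
#' angle between this direction and the nerve's longitudinal axis greater
#' than 90 degrees defines a U-turn.
#'
#' @param tree an [axon_tree()].
#' @param axis longitudinal unit axis of the nerve.
#' @param direction_window arc-length window near the axonal end (um).
#' @return List with `angle_deg` and `is_uturn`.
#' @export
detect_uturn <- function(tree, axis = c(1, 0, 0), direction_window = 20) {
  if (tree_length(tree) < direction_window) {
    stop("main path shorter than the direction window")
  }
  axis <- axis / sqrt(sum(axis^2))
  v <- tip_direction(tree, window = direction_window)
  angle <- acos(pmin(pmax(sum(v * axis), -1), 1)) * 180 / pi
  list(angle_deg = angle, is_uturn = angle > 90)
}

#' Count direction-reversal events along the main path
#'
#' Alternative U-turn accounting: counts distinct excursions of the running
#' trajectory direction (over a sliding `direction_window`) above 90 degrees
#' to the axis, with re-arming below 80 degrees. The headline U-turn rate
#' uses per-axon accounting (at most one U-turn per axon); this event count
#' is exposed for sensitivity analyses.
#'
#' @inheritParams detect_uturn
#' @return Integer number of reversal events.
#' @export
count_reversal_events <- function(tree, axis = c(1, 0, 0),
                                  direction_window = 20) {
  axis <- axis / sqrt(sum(axis^2))
  path <- tree_main_path(tree)
  xyz <- node_xyz(tree, path)
  n <- nrow(xyz)
  if (n < 2L) return(0L)
  seg <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-n, , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))
  events <- 0L
  armed <- TRUE
  for (i in 2:n) {
    j <- which(arc >= arc[i] - direction_window)[1]
    if (j >= i) j <- i - 1L
    v <- xyz[i, ] - xyz[j, ]
    nv <- sqrt(sum(v^2))
    if (nv == 0) next
    ang <- acos(pmin(pmax(sum(v / nv * axis), -1), 1)) * 180 / pi
    if (armed && ang > 90) {
      events <- events + 1L
      armed <- FALSE
    } else if (!armed && ang < 80) {
      armed <- TRUE
    }
  }
  events
}

#' Trajectory metrics: U-turn rate and branching index
#'
#' Axons are selected as the top `n_top` longest in the nerve (the
#' conventional top-20) or all axons in the analyzed region (the chiasm
#' convention); the U-turn rate is the fraction of selected axons whose
#' terminal direction exceeds 90 degrees to the axis (one U-turn counted per
#' axon), and the branching index is the number of terminal tips distal to
#' the selection site divided by the number of selected axons.
#'
#' @param trees list of [axon_tree()] (or a [trace_axons()] result).
#' @param axis longitudinal unit axis.
#' @param selection `"top_20_longest"` or `"all_in_region"`.
#' @param n_top number of longest axons selected under `"top_20_longest"`.
#' @param selection_site axial distance (um) from which tips are counted
#'   (default the crush plane, 0; use the OCTZ position for chiasm analyses).
#' @param direction_window tip-direction window (um).
#' @return Object of class `trajectory_metrics`: list with
#'   `n_axons_analyzed`, `uturn_count`, `uturn_rate`, `tip_count`,
#'   `branching_index`, `selection_site`, and `per_axon` (data frame with
#'   `axon`, `length_um`, `angle_deg`, `is_uturn`, `n_tips`).
#' @export
trajectory_metrics <- function(trees, axis = c(1, 0, 0),
                               selection = c("top_20_longest",
                                             "all_in_region"),
                               n_top = 20L, selection_site = 0,
                               direction_window = 20) {
  trees <- as_tree_list(trees)
  selection <- match.arg(selection)
  if (length(trees) == 0L) stop("no axons to analyze")
  lens <- vapply(trees, tree_length, numeric(1))
  if (selection == "top_20_longest") {
    if (length(trees) < n_top) {
      warning("fewer than ", n_top, " axons present (", length(trees),
              "); analyzing all of them")
    }
    sel <- order(-lens, seq_along(lens))[seq_len(min(n_top, length(trees)))]
  } else {
    sel <- seq_along(trees)
  }
  axis <- axis / sqrt(sum(axis^2))
  per <- lapply(sel, function(i) {
    ut <- detect_uturn(trees[[i]], axis, direction_window)
    tips <- tree_tips(trees[[i]])
    tip_pos <- node_xyz(trees[[i]], tips)
    n_tips <- sum(as.numeric(tip_pos %*% axis) >= selection_site)
    data.frame(axon = i, length_um = lens[i], angle_deg = ut$angle_deg,
               is_uturn = ut$is_uturn, n_tips = n_tips)
  })
  per <- do.call(rbind, per)
  structure(list(n_axons_analyzed = nrow(per),
                 uturn_count = sum(per$is_uturn),
                 uturn_rate = mean(per$is_uturn),
                 tip_count = sum(per$n_tips),
                 branching_index = sum(per$n_tips) / nrow(per),
                 selection_site = selection_site, per_axon = per),
            class = "trajectory_metrics")
}

#' @export
print.trajectory_metrics <- function(x, ...) {
  cat(sprintf(
    "<trajectory_metrics: %d axons, U-turn rate %.3f, branching index %.2f>\n",
    x$n_axons_analyzed, x$uturn_rate, x$branching_index))
  invisible(x)
}

#' Sciatic-nerve regeneration lengths with the minimum-axon QC rule
#'
#' Whole-mount sciatic traces are measured from the crush site to the distal
#' tip; nerves with fewer than `min_axons` identifiable axons fail QC and are
#' excluded from summary statistics (no summary is emitted for them).
#'
#' @param trees list of [axon_tree()] 2D whole-mount traces.
#' @param min_axons minimum identifiable axons required (default 15).
#' @return List with `n_axons`, `qc_pass`, `per_axon_lengths` and, for
#'   passing nerves only, `mean_length`.
#' @export
sciatic_regeneration <- function(trees, min_axons = 15L) {
  trees <- as_tree_list(trees)
  lens <- vapply(trees, tree_length, numeric(1))
  qc <- length(trees) >= min_axons
  out <- list(n_axons = length(trees), qc_pass = qc,
              per_axon_lengths = lens)
  if (qc) {
    out$mean_length <- mean(lens)
  } else {
    warning("nerve fails QC: ", length(trees), " identifiable axon(s) < ",
            min_axons, "; no summary emitted")
  }
  out
}

as_tree_list <- function(trees) {
  if (inherits(trees, "trace_result")) return(trees$trees)
  if (inherits(trees, "axon_tree")) return(list(trees))
  trees
}
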