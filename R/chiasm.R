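#' Simulate regenerating axons approaching the optic chiasm
#'
#' Each axon is assigned a ground-truth fate — stopping before the optic
#' nerve-chiasm transition zone (`pre_chiasmic`), projecting into the
#' ipsilateral or contralateral optic tract, or extending into the
#' contralateral optic nerve — with the supplied probabilities, and its
#' trajectory is laid through the corresponding landmark regions (see
#' [chiasm_landmarks()]): contra-fated axons cross the midline inside the
#' chiasm; pre-chiasmic terminals stay proximal to the OCTZ.
#'
#' @param config a [nerve_sim_config()]; `nerve_length` must reach past the
#'   tract plane.
#' @param landmarks a [chiasm_landmarks()].
#' @param fate_probs named or positional probabilities for
#'   `pre_chiasmic`, `ipsi_tract`, `contra_tract`, `contra_nerve`; must sum
#'   to 1.
#' @return A `ground_truth` whose `labels` carry a `fate` column and whose
#'   `geometry` carries the chiasm landmarks.
#' @export
simulate_chiasm <- function(config, landmarks,
                            fate_probs = c(pre_chiasmic = 0.6,
                                           ipsi_tract = 0.3,
                                           contra_tract = 0.05,
                                           contra_nerve = 0.05)) {
  stopifnot(inherits(config, "nerve_sim_config"),
            inherits(landmarks, "chiasm_landmarks"))
  fates <- c("pre_chiasmic", "ipsi_tract", "contra_tract", "contra_nerve")
  if (!is.null(names(fate_probs))) fate_probs <- fate_probs[fates]
  fate_probs <- as.numeric(fate_probs)
  if (length(fate_probs) != 4L || anyNA(fate_probs) ||
      abs(sum(fate_probs) - 1) > 1e-8 || any(fate_probs < 0)) {
    stop("fate_probs must be four non-negative probabilities summing to 1")
  }
  geometry <- nerve_geometry(crush_x = config$crush_x, axis = c(1, 0, 0),
                             extent = config$nerve_length,
                             radius = config$nerve_radius, chiasm = landmarks)

  n <- config$n_axons
  fate_draw <- with_seed(derive_seed(config$seed, 0L),
                         sample(fates, n, replace = TRUE, prob = fate_probs))
  axons <- vector("list", n)
  labels <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- with_seed(derive_seed(config$seed, i),
                    chiasm_axon(config, landmarks, fate_draw[i], i))
    axons[[i]] <- tr
    labels[[i]] <- data.frame(axon = i, length_um = tree_length(tr),
                              n_tips = length(tree_tips(tr)),
                              uturn = FALSE, tip_class = "growth_cone",
                              true_tip_ratio = mean(config$gc_ratio_range),
                              fate = fate_draw[i])
  }
  labels <- do.call(rbind, labels)
  interval <- 250
  distances <- seq(interval, config$nerve_length, by = interval)
  structure(list(geometry = geometry, axons = axons, labels = labels,
                 crossing_table = data.frame(
                   distance_um = distances,
                   count = plane_crossings(axons, geometry, distances)),
                 config = config),
            class = "ground_truth")
}

# one chiasm-bound axon laid through waypoints for its fate
chiasm_axon <- function(config, lm, fate, i) {
  ipsi_y <- -config$nerve_radius / 2
  y0 <- ipsi_y + stats::runif(1, -config$nerve_radius / 4,
                              config$nerve_radius / 4)
  z0 <- stats::runif(1, -5, 5)
  margin <- 25
  wp <- switch(fate,
    pre_chiasmic = rbind(
      c(config$crush_x, y0, z0),
      c(config$crush_x + stats::runif(1, 0.3, 0.9) *
          (lm$octz_x - config$crush_x), y0, z0)),
    ipsi_tract = rbind(
      c(config$crush_x, y0, z0),
      c(lm$octz_x, y0, z0),
      c(lm$tract_x + stats::runif(1, 30, 120),
        stats::runif(1, y0, lm$midline_y - margin), z0)),
    contra_tract = rbind(
      c(config$crush_x, y0, z0),
      c(lm$octz_x, y0, z0),
      c((lm$octz_x + lm$tract_x) / 2, lm$midline_y +
          stats::runif(1, margin / 2, margin), z0),
      c(lm$tract_x + stats::runif(1, 30, 120),
        lm$midline_y + stats::runif(1, margin, 3 * margin), z0)),
    contra_nerve = rbind(
      c(config$crush_x, y0, z0),
      c(lm$octz_x, y0, z0),
      c((lm$octz_x + lm$tract_x) / 2,
        lm$midline_y + stats::runif(1, margin, 2 * margin), z0),
      c(lm$octz_x - stats::runif(1, 0.2, 0.6) * (lm$octz_x - config$crush_x),
        lm$midline_y + stats::runif(1, margin, 2 * margin), z0)))
  pts <- interp_waypoints(wp, config$step)
  jit <- config$tortuosity_sd / 10
  if (nrow(pts) > 2) {
    mid <- 2:(nrow(pts) - 1)
    pts[mid, 2] <- pts[mid, 2] + stats::rnorm(length(mid), 0, jit)
    if (!config$flat) {
      pts[mid, 3] <- pts[mid, 3] + stats::rnorm(length(mid), 0, jit)
    }
  }
  axon_tree(data.frame(id = seq_len(nrow(pts)),
                       parent = c(-1L, seq_len(nrow(pts) - 1L)),
                       x = pts[, 1], y = pts[, 2], z = pts[, 3],
                       radius = config$shaft_diameter / 2))
}

interp_waypoints <- function(wp, step) {
  pts <- wp[1, , drop = FALSE]
  for (s in seq_len(nrow(wp) - 1L)) {
    a <- wp[s, ]; b <- wp[s + 1L, ]
    len <- sqrt(sum((b - a)^2))
    nseg <- max(1L, ceiling(len / step))
    tt <- seq_len(nseg) / nseg
    pts <- rbind(pts, outer(tt, b - a) + matrix(a, nseg, 3, byrow = TRUE))
  }
  pts
}

#' Classify chiasm fates of traced axons
#'
#' The fate is determined by the landmark region containing the terminal
#' point of each axon's main path: proximal to the OCTZ on the ipsilateral
#' side of the midline (including axons that turned back) is `pre_chiasmic`;
#' at or beyond the tract plane, `ipsi_tract` or `contra_tract` by side of
#' the midline; proximal to the OCTZ beyond the midline is `contra_nerve`.
#' Terminals inside the chiasm region itself fall into an explicit
#' `unassigned` bucket, never silently dropped.
#'
#' @param trees list of [axon_tree()] (or a [trace_axons()] result).
#' @param geometry a [nerve_geometry()] whose `chiasm` landmarks are set.
#' @return Object of class `chiasm_fate_table`: data frame with `fate`,
#'   `count`, `fraction` (fractions over all analyzed axons, summing to 1).
#' @export
classify_chiasm_fates <- function(trees, geometry) {
  trees <- as_tree_list(trees)
  lm <- geometry$chiasm
  if (is.null(lm)) stop("geometry carries no chiasm landmarks")
  fates <- c("pre_chiasmic", "ipsi_tract", "contra_tract", "contra_nerve",
             "unassigned")
  assign_one <- function(tree) {
    path <- tree_main_path(tree)
    tip <- node_xyz(tree, path[length(path)])
    x <- tip[1]; y <- tip[2]
    if (x < lm$octz_x) {
      if (y <= lm$midline_y) "pre_chiasmic" else "contra_nerve"
    } else if (x >= lm$tract_x) {
      if (y <= lm$midline_y) "ipsi_tract" else "contra_tract"
    } else {
      "unassigned"
    }
  }
  got <- vapply(trees, assign_one, character(1))
  counts <- vapply(fates, function(f) sum(got == f), integer(1))
  out <- data.frame(fate = fates, count = counts,
                    fraction = if (length(trees) > 0) {
                      counts / length(trees)
                    } else rep(NA_real_, length(fates)))
  structure(out, class = c("chiasm_fate_table", "data.frame"),
            per_axon = got)
}
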