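#' Simulate ground-truth regenerating axons in a crushed nerve
#'
#' Generates a population of regenerating axons emanating from the crush
#' plane as correlated random walks with mean extension `length_scale`
#' (truncated-exponential law), optional terminal U-turn reversals, Poisson
#' branch events along arc length, and terminal morphology labels drawn from
#' the configured retraction-bulb / growth-cone mixture. The exact
#' axon-plane crossing counts at each `interval` distal to the crush site are
#' computed from the polylines and stored in the ground truth.
#'
#' Non-U-turn trajectories are mean-reverting toward the nerve axis with the
#' heading clipped below the 90 degree threshold, so the drawn U-turn label is
#' always consistent with the realized terminal geometry. U-turn axons end in
#' a smooth reversal arc (radius `turn_radius`) followed by a reversed tail,
#' so a direction window near the tip reads an angle above 90 degrees.
#'
#' @param config a [nerve_sim_config()].
#' @param lengths optional fixed vector of axon extension lengths (um),
#'   replacing the random length law (recycled to `n_axons`).
#' @param interval crossing-table interval (um, default 250).
#' @return Object of class `ground_truth`: list with `geometry`
#'   ([nerve_geometry()]), `axons` (list of [axon_tree()]), `labels` (per-axon
#'   data frame: `axon`, `length_um`, `n_tips`, `uturn`, `tip_class`,
#'   `true_tip_ratio`), `crossing_table` (`distance_um`, `count`) and
#'   `config`.
#' @export
simulate_nerve <- function(config, lengths = NULL, interval = 250) {
  stopifnot(inherits(config, "nerve_sim_config"))
  geometry <- nerve_geometry(crush_x = config$crush_x, axis = c(1, 0, 0),
                             extent = config$nerve_length,
                             radius = config$nerve_radius)
  n <- config$n_axons
  starts <- with_seed(derive_seed(config$seed, 0L),
                      start_points(n, config))
  if (!is.null(lengths)) lengths <- rep_len(as.numeric(lengths), n)

  axons <- vector("list", n)
  labels <- vector("list", n)
  for (i in seq_len(n)) {
    res <- with_seed(derive_seed(config$seed, i),
                     simulate_axon(config, starts[i, ], lengths[i]))
    axons[[i]] <- res$tree
    labels[[i]] <- data.frame(axon = i, length_um = tree_length(res$tree),
                              n_tips = length(tree_tips(res$tree)),
                              uturn = res$uturn, tip_class = res$tip_class,
                              true_tip_ratio = res$tip_ratio)
  }
  labels <- if (n > 0) do.call(rbind, labels) else
    data.frame(axon = integer(0), length_um = numeric(0),
               n_tips = integer(0), uturn = logical(0),
               tip_class = character(0), true_tip_ratio = numeric(0))

  distances <- seq(interval, config$nerve_length, by = interval)
  crossing_table <- data.frame(
    distance_um = distances,
    count = plane_crossings(axons, geometry, distances))

  structure(list(geometry = geometry, axons = axons, labels = labels,
                 crossing_table = crossing_table, config = config),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth: %d axons, %d tips, %d U-turn(s)>\n",
              length(x$axons), sum(x$labels$n_tips), sum(x$labels$uturn)))
  invisible(x)
}

#' Exact axon-plane crossing counts
#'
#' Counts, for each distance, how many polyline edges (over all trees,
#' branches included) cross the plane perpendicular to the nerve axis at that
#' distance distal to the crush site. Crossings are counted on half-open
#' intervals so an edge endpoint sitting exactly on a plane is counted once.
#'
#' @param trees list of `axon_tree` objects.
#' @param geometry a [nerve_geometry()].
#' @param distances plane distances distal to the crush site (um).
#' @return Integer vector of counts, one per distance.
#' @export
plane_crossings <- function(trees, geometry, distances) {
  if (inherits(trees, "axon_tree")) trees <- list(trees)
  counts <- integer(length(distances))
  for (tree in trees) {
    ax <- as.numeric(axial_distance(geometry, cbind(tree$x, tree$y, tree$z)))
    pidx <- parent_index(tree)
    ok <- !is.na(pidx)
    a <- ax[pidx[ok]]
    b <- ax[ok]
    for (j in seq_along(distances)) {
      d <- distances[j]
      counts[j] <- counts[j] +
        sum((a < d & b >= d) | (b < d & a >= d))
    }
  }
  counts
}

# jittered grid of start points on the crush plane, ordered centre-out
start_points <- function(n, config) {
  if (n == 0) return(matrix(numeric(0), ncol = 3))
  sp <- config$lane_spacing
  if (config$flat) {
    offs <- (seq_len(n) - (n + 1) / 2) * sp
    if (max(abs(offs)) > config$nerve_radius) {
      stop("nerve_radius too small for ", n, " lanes at spacing ", sp)
    }
    y <- offs + stats::runif(n, -sp / 10, sp / 10)
    return(cbind(x = rep(config$crush_x, n), y = y, z = rep(0, n)))
  }
  k <- ceiling(config$nerve_radius / sp)
  g <- expand.grid(iy = -k:k, iz = -k:k)
  gy <- g$iy * sp
  gz <- g$iz * sp
  keep <- sqrt(gy^2 + gz^2) <= config$nerve_radius
  gy <- gy[keep]; gz <- gz[keep]
  ord <- order(gy^2 + gz^2, gy, gz)
  if (length(ord) < n) {
    stop("nerve_radius too small for ", n, " lanes at spacing ", sp)
  }
  gy <- gy[ord][seq_len(n)]
  gz <- gz[ord][seq_len(n)]
  # jitter drawn per axon (y, z consecutive) so that the draw sequence for
  # the first k axons does not depend on n
  jit <- matrix(stats::runif(2 * n, -sp / 10, sp / 10), ncol = 2,
                byrow = TRUE)
  cbind(x = rep(config$crush_x, n), y = gy + jit[, 1], z = gz + jit[, 2])
}

# one axon: correlated random walk + optional terminal reversal + branches
simulate_axon <- function(config, start, length_fixed = NULL) {
  step <- config$step
  sdrad <- config$tortuosity_sd * pi / 180
  L <- if (!is.null(length_fixed) && !is.na(length_fixed)) {
    length_fixed
  } else {
    # truncated exponential extension, mean length_scale before truncation
    l <- stats::rexp(1, 1 / config$length_scale)
    min(max(l, config$min_length), config$nerve_length * 0.95)
  }
  uturn <- stats::runif(1) < config$p_uturn
  is_bulb <- stats::runif(1) < config$p_bulb
  tip_ratio <- if (is_bulb) {
    stats::runif(1, config$bulb_ratio_range[1], config$bulb_ratio_range[2])
  } else {
    stats::runif(1, config$gc_ratio_range[1], config$gc_ratio_range[2])
  }

  n_steps <- max(2L, ceiling(L / step))
  pos <- matrix(0, n_steps + 1, 3)
  pos[1, ] <- start
  h <- c(1, 0, 0)
  centre <- start[2:3]
  max_ang <- 70 * pi / 180
  for (s in seq_len(n_steps)) {
    noise <- c(0, stats::rnorm(1, 0, sin(sdrad)),
               if (config$flat) 0 else stats::rnorm(1, 0, sin(sdrad)))
    h <- h + 0.08 * (c(1, 0, 0) - h) + noise
    h <- h / sqrt(sum(h^2))
    # clip heading below the U-turn threshold (with margin)
    cosang <- h[1]
    if (cosang < cos(max_ang)) {
      lat <- h[2:3]
      lnorm <- sqrt(sum(lat^2))
      if (lnorm > 0) h <- c(cos(max_ang), sin(max_ang) * lat / lnorm)
      else h <- c(1, 0, 0)
    }
    nxt <- pos[s, ] + step * h
    # corridor reflection keeps lanes disjoint
    off <- nxt[2:3] - centre
    if (sqrt(sum(off^2)) > config$corridor_radius) {
      u <- off / sqrt(sum(off^2))
      lat <- h[2:3]
      h[2:3] <- lat - 2 * sum(lat * u) * u
      h <- h / sqrt(sum(h^2))
      if (h[1] < cos(max_ang)) {
        lat <- h[2:3]; lnorm <- sqrt(sum(lat^2))
        h <- if (lnorm > 0) c(cos(max_ang), sin(max_ang) * lat / lnorm)
             else c(1, 0, 0)
      }
      nxt <- pos[s, ] + step * h
    }
    pos[s + 1, ] <- nxt
  }

  if (uturn) {
    # straighten toward the axis over a few steps, then a smooth in-plane
    # reversal arc, then a reversed tail: keeps the turn from looping back
    # over the axon's own shaft
    extra <- list()
    p <- pos[nrow(pos), ]
    for (s in 1:6) {
      h <- h + 0.5 * (c(1, 0, 0) - h)
      h <- h / sqrt(sum(h^2))
      p <- p + step * h
      extra[[length(extra) + 1L]] <- p
    }
    dphi <- step / config$turn_radius
    turn_sign <- if (start[2] > 0) -1 else 1
    ang <- atan2(h[2], h[1])
    while (cos(ang) > cos(160 * pi / 180)) {
      ang <- ang + turn_sign * dphi
      hxy <- c(cos(ang), sin(ang))
      p <- p + step * c(hxy[1], hxy[2], 0)
      extra[[length(extra) + 1L]] <- p
    }
    tail_steps <- ceiling(config$uturn_tail / step)
    hdir <- c(cos(ang), sin(ang), 0)
    for (s in seq_len(tail_steps)) {
      cand <- p + step * hdir
      if (cand[1] <= config$crush_x + 5) break
      p <- cand
      extra[[length(extra) + 1L]] <- p
    }
    pos <- rbind(pos, do.call(rbind, extra))
  }

  nodes <- data.frame(id = seq_len(nrow(pos)),
                      parent = c(-1L, seq_len(nrow(pos) - 1L)),
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      radius = config$shaft_diameter / 2)
  main_n <- nrow(nodes)

  # Poisson branch events along the main extension
  n_br <- if (config$branch_rate > 0) {
    stats::rpois(1, config$branch_rate * (L / 1000))
  } else 0L
  if (n_br > 0) {
    for (b in seq_len(n_br)) {
      at <- 1L + floor(stats::runif(1, 0.1, 0.85) * (main_n - 1L))
      base_dir <- pos[min(at + 1L, main_n), ] - pos[at, ]
      base_ang <- atan2(base_dir[2], base_dir[1])
      dev <- (30 + stats::rexp(1, 1 / 10)) * pi / 180 * sample(c(-1, 1), 1)
      bang <- base_ang + dev
      # keep side branches shorter than the remaining main path so the main
      # (longest) root-to-tip path, whose tip carries the morphology and
      # U-turn labels, is never displaced by a branch
      remaining <- L - (at - 1L) * step
      blen <- min(config$branch_max_len,
                  config$min_length / 2 + stats::rexp(1, 1 / 40),
                  0.6 * remaining)
      if (blen < 10) next
      bsteps <- max(2L, ceiling(blen / step))
      bh <- c(cos(bang), sin(bang), 0)
      p <- pos[at, ]
      prev_id <- nodes$id[at]
      for (s in seq_len(bsteps)) {
        jit <- c(0, stats::rnorm(1, 0, sin(sdrad) / 2),
                 if (config$flat) 0 else stats::rnorm(1, 0, sin(sdrad) / 2))
        bh <- (bh + jit); bh <- bh / sqrt(sum(bh^2))
        p <- p + step * bh
        new_id <- nrow(nodes) + 1L
        nodes <- rbind(nodes, data.frame(id = new_id, parent = prev_id,
                                         x = p[1], y = p[2], z = p[3],
                                         radius = config$shaft_diameter / 2))
        prev_id <- new_id
      }
    }
  }

  list(tree = axon_tree(nodes), uturn = uturn,
       tip_class = if (is_bulb) "retraction_bulb" else "growth_cone",
       tip_ratio = tip_ratio)
}
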