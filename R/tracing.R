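#' Threshold a fluorescence stack into a binary mask
#'
#' Supported methods: `"otsu"` (histogram threshold maximizing between-class
#' variance), `"fixed"` (explicit threshold in intensity units),
#' `"percentile"` (quantile of the intensity distribution) and
#' `"background"` (background median plus `threshold` robust SDs, the MAD
#' estimate; robust when rare very bright structures such as retraction
#' bulbs make the histogram strongly multi-modal, where Otsu splits the
#' bright mode instead of separating signal from background). The
#' thresholding provenance (method and realized threshold) is recorded on
#' the mask. The mask is monotone in the threshold: a lower threshold yields
#' a superset.
#'
#' @param stack an [image_stack()].
#' @param method one of `"otsu"`, `"fixed"`, `"percentile"`, `"background"`.
#' @param threshold threshold value (`"fixed"`), probability
#'   (`"percentile"`), or number of robust SDs above the background median
#'   (`"background"`, default 4).
#' @return Object of class `binary_mask`: list with logical array `data`,
#'   `voxel`, `origin`, `method`, `threshold`.
#' @export
binarize <- function(stack, method = c("otsu", "fixed", "percentile",
                                       "background"),
                     threshold = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  method <- match.arg(method)
  v <- as.numeric(stack$data)
  thr <- switch(method,
    fixed = {
      if (is.null(threshold)) stop("method 'fixed' requires a threshold")
      threshold
    },
    percentile = {
      if (is.null(threshold)) threshold <- 0.99
      as.numeric(stats::quantile(v, threshold))
    },
    otsu = {
      if (max(v) - min(v) < .Machine$double.eps) {
        stop("otsu thresholding is degenerate on a constant-intensity stack")
      }
      otsu_threshold(v)
    },
    background = {
      if (is.null(threshold)) threshold <- 4
      spread <- stats::mad(v)
      if (spread == 0) spread <- stats::sd(v)
      stats::median(v) + threshold * spread
    })
  structure(list(data = array(stack$data > thr, dim(stack$data)),
                 voxel = stack$voxel, origin = stack$origin,
                 method = method, threshold = thr),
            class = "binary_mask")
}

# Otsu's method on a 256-bin histogram
otsu_threshold <- function(v, n_bins = 256L) {
  r <- range(v)
  breaks <- seq(r[1], r[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask: %s voxels foreground (%s, threshold %.4g)>\n",
              format(sum(x$data)), x$method, x$threshold))
  invisible(x)
}

#' Trace axons from a binary mask
#'
#' The automated substitute for manual axon tracing. Foreground voxels form a
#' 26-connected graph with edge costs equal to the physical step length
#' down-weighted by the Euclidean distance transform, so that shortest paths
#' run along tube centrelines. Each connected component touching the crush
#' plane (within `root_tol`) is converted to a rooted tree by iterative
#' farthest-point geodesic extraction: repeatedly take the uncovered voxel
#' with the largest geodesic distance from the root, extract its path, attach
#' the novel suffix to the existing tree, and mark all voxels within the
#' local tube radius of the traced centreline as covered. Short terminal
#' spurs (< `prune_len`) are pruned and trees shorter than `min_length` are
#' dropped (their count is reported).
#'
#' Components with more than two crush-plane contact voxels well separated in
#' space may be merged axon bundles; they are traced as one tree and flagged.
#'
#' @param mask a [binarize()] result.
#' @param geometry a [nerve_geometry()] locating the crush plane.
#' @param min_length minimum tree length to keep (um).
#' @param prune_len spur-prune length (um).
#' @param root_tol distance tolerance from the crush plane for roots (um).
#' @param smooth_window node window for centreline smoothing (odd integer;
#'   1 disables).
#' @return Object of class `trace_result`: list with `trees` (list of
#'   [axon_tree()]), `flags` (per-tree data frame with `reached_crush`,
#'   `min_length_pass`, `multi_contact`) and `n_dropped`.
#' @export
trace_axons <- function(mask, geometry, min_length = 50, prune_len = 10,
                        root_tol = 20, smooth_window = 5) {
  stopifnot(inherits(mask, "binary_mask"))
  dims <- dim(mask$data)
  fg <- which(mask$data)
  if (length(fg) == 0L) stop("mask is empty")

  dt <- edt3d(as.logical(mask$data), dims, mask$voxel)
  coords <- arrayInd(fg, dims)
  # physical coordinates of foreground voxel centres
  phys <- sweep(sweep(coords - 1, 2, mask$voxel, "*"), 2, mask$origin, "+")
  ax <- as.numeric(axial_distance(geometry, phys))
  dt_fg <- dt[fg]

  id_grid <- array(0L, dims)
  id_grid[fg] <- seq_along(fg)

  edges <- voxel_edges(id_grid, dims, mask$voxel, dt_fg)
  g <- igraph::graph_from_edgelist(edges$pairs, directed = FALSE)
  if (igraph::vcount(g) < length(fg)) {
    g <- igraph::add_vertices(g, length(fg) - igraph::vcount(g))
  }
  igraph::E(g)$weight <- edges$w
  comp <- igraph::components(g)

  trees <- list()
  flags <- list()
  n_dropped <- 0L
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    contacts <- members[abs(ax[members]) <= root_tol]
    if (length(contacts) == 0L) next
    # root on the crush-plane-most voxel layer (else the segment between the
    # root and the plane would read as a spurious proximal branch); within
    # that layer prefer the tube centre (largest distance transform)
    near <- contacts[abs(ax[contacts]) <=
                       min(abs(ax[contacts])) + 2 * max(mask$voxel)]
    root <- near[order(-dt_fg[near], near)][1]
    # widely separated contacts indicate merged axons entering together
    multi_contact <- FALSE
    if (length(contacts) > 2L) {
      spread <- max(stats::dist(phys[contacts, , drop = FALSE]))
      multi_contact <- spread > 4 * max(dt_fg[contacts])
    }
    tr <- extract_component_tree(g, edges, root, members, phys, dt_fg,
                                 mask$voxel, prune_len)
    if (is.null(tr)) next
    tr <- smooth_tree(tr, smooth_window)
    tr <- prune_spurs(tr, prune_len)
    len <- tree_length(tr)
    if (len < min_length) {
      n_dropped <- n_dropped + 1L
      next
    }
    trees[[length(trees) + 1L]] <- tr
    flags[[length(flags) + 1L]] <- data.frame(
      tree = length(trees), reached_crush = TRUE, min_length_pass = TRUE,
      multi_contact = multi_contact, length_um = len)
  }
  if (length(trees) == 0L) {
    warning("no mask component touches the crush plane; empty trace result")
  }
  structure(list(trees = trees,
                 flags = if (length(flags) > 0) do.call(rbind, flags) else
                   data.frame(tree = integer(0), reached_crush = logical(0),
                              min_length_pass = logical(0),
                              multi_contact = logical(0),
                              length_um = numeric(0)),
                 n_dropped = n_dropped),
            class = "trace_result")
}

#' @export
print.trace_result <- function(x, ...) {
  cat(sprintf("<trace_result: %d tree(s), %d dropped below min length>\n",
              length(x$trees), x$n_dropped))
  invisible(x)
}

# 26-neighbourhood edges between foreground voxels; cost = physical step
# length / (0.5 + mean local distance-transform) so paths hug centrelines
voxel_edges <- function(id_grid, dims, voxel, dt_fg) {
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0 & offs$dk == 0), ]
  # half of the 26 offsets (the rest are mirror images)
  offs <- offs[offs$di > 0 | (offs$di == 0 & offs$dj > 0) |
               (offs$di == 0 & offs$dj == 0 & offs$dk > 0), ]
  pairs <- list()
  wts <- list()
  for (r in seq_len(nrow(offs))) {
    di <- offs$di[r]; dj <- offs$dj[r]; dk <- offs$dk[r]
    xs <- max(1, 1 - di):min(dims[1], dims[1] - di)
    ys <- max(1, 1 - dj):min(dims[2], dims[2] - dj)
    zs <- max(1, 1 - dk):min(dims[3], dims[3] - dk)
    a <- id_grid[xs, ys, zs, drop = FALSE]
    b <- id_grid[xs + di, ys + dj, zs + dk, drop = FALSE]
    sel <- a > 0L & b > 0L
    if (!any(sel)) next
    av <- a[sel]; bv <- b[sel]
    step <- sqrt(sum((c(di, dj, dk) * voxel)^2))
    pairs[[length(pairs) + 1L]] <- cbind(av, bv)
    wts[[length(wts) + 1L]] <-
      step / (0.5 + (dt_fg[av] + dt_fg[bv]) / 2)
  }
  list(pairs = do.call(rbind, pairs), w = unlist(wts))
}

# farthest-point geodesic extraction of one component into a rooted tree
extract_component_tree <- function(g, edges, root, members, phys, dt_fg,
                                   voxel, prune_len) {
  dall <- rep(Inf, igraph::vcount(g))
  dall[members] <- igraph::distances(g, v = root, to = members)[1, ]
  dists <- dall[members]
  names(dists) <- members
  # geodesic predecessors recovered from the distance field: a neighbour u
  # is v's predecessor iff d(u) + w(u,v) = d(v)
  pred <- rep(NA_integer_, igraph::vcount(g))
  a <- edges$pairs[, 1]; b <- edges$pairs[, 2]; w <- edges$w
  tol <- 1e-9
  fin <- is.finite(dall[a]) & is.finite(dall[b])
  ok <- fin & abs(dall[a] + w - dall[b]) <= tol * (1 + abs(dall[b]))
  pred[b[ok]] <- a[ok]
  ok <- fin & abs(dall[b] + w - dall[a]) <= tol * (1 + abs(dall[a]))
  pred[a[ok]] <- b[ok]
  pred[root] <- 0L
  walk_path <- function(tip) {
    path <- integer(0)
    v <- tip
    while (!is.na(v) && v != 0L) {
      path <- c(path, v)
      if (v == root) break
      v <- pred[v]
    }
    rev(path)
  }
  covered <- rep(FALSE, length(members))
  names(covered) <- members
  in_tree <- logical(length(dt_fg))  # by voxel id
  cover_r <- pmax(dt_fg, 1.2 * max(voxel))

  nodes <- data.frame(id = 1L, parent = -1L, x = phys[root, 1],
                      y = phys[root, 2], z = phys[root, 3],
                      radius = dt_fg[root])
  node_voxel <- root
  in_tree[root] <- TRUE
  covered[as.character(root)] <- TRUE
  update_cover <- function(new_voxels) {
    unc <- members[!covered]
    if (length(unc) == 0L || length(new_voxels) == 0L) return()
    pn <- phys[new_voxels, , drop = FALSE]
    nn2 <- rowSums(pn^2)
    for (start in seq(1, length(unc), by = 4000L)) {
      idx <- unc[start:min(start + 3999L, length(unc))]
      pu <- phys[idx, , drop = FALSE]
      d2 <- outer(rowSums(pu^2), nn2, "+") - 2 * pu %*% t(pn)
      mind <- sqrt(pmax(do.call(pmin, as.data.frame(d2)), 0))
      hit <- mind <= cover_r[idx]
      covered[as.character(idx[hit])] <<- TRUE
    }
  }

  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 500L) break
    unc <- members[!covered]
    unc <- unc[is.finite(dists[as.character(unc)])]
    if (length(unc) == 0L) break
    tip <- unc[which.max(dists[as.character(unc)])]
    path <- walk_path(tip)
    if (length(path) < 2L) {
      covered[as.character(tip)] <- TRUE
      next
    }
    # novel suffix: nodes after the last path voxel already covered by the
    # traced tree (coverage, not voxel identity: geodesics re-entering the
    # same tube need not revisit the exact voxels already traced)
    cov_path <- in_tree[path] | covered[as.character(path)]
    anchor_pos <- if (any(cov_path)) max(which(cov_path)) else 1L
    if (anchor_pos >= length(path)) {
      covered[as.character(tip)] <- TRUE
      next
    }
    suffix <- path[seq.int(anchor_pos + 1L, length(path))]
    seg <- sqrt(rowSums((phys[path[-1], , drop = FALSE] -
                         phys[path[-length(path)], , drop = FALSE])^2))
    new_len <- sum(seg[seq.int(anchor_pos, length(seg))])
    if (new_len < prune_len) {
      covered[as.character(c(tip, suffix))] <- TRUE
      update_cover(suffix)
      next
    }
    # attach at the nearest existing tree node to the anchor voxel
    anchor_voxel <- path[anchor_pos]
    d2a <- (nodes$x - phys[anchor_voxel, 1])^2 +
      (nodes$y - phys[anchor_voxel, 2])^2 +
      (nodes$z - phys[anchor_voxel, 3])^2
    parent_id <- nodes$id[which.min(d2a)]
    new_ids <- nrow(nodes) + seq_along(suffix)
    nodes <- rbind(nodes, data.frame(
      id = new_ids,
      parent = c(parent_id, new_ids[-length(new_ids)]),
      x = phys[suffix, 1], y = phys[suffix, 2], z = phys[suffix, 3],
      radius = dt_fg[suffix]))
    node_voxel <- c(node_voxel, suffix)
    in_tree[suffix] <- TRUE
    covered[as.character(suffix)] <- TRUE
    update_cover(suffix)
  }
  if (nrow(nodes) < 2L) return(NULL)
  axon_tree(nodes)
}

# moving-average smoothing of node positions along each unbranched run;
# endpoints, the root and branch points stay fixed
smooth_tree <- function(tree, window = 5) {
  if (window <= 1L || nrow(tree) < 3L) return(tree)
  half <- floor(window / 2)
  keep <- tree$id %in% c(tree$id[tree$parent == -1L], tree_tips(tree),
                         tree_branch_points(tree))
  pidx <- parent_index(tree)
  children <- split(seq_len(nrow(tree)), tree$parent)[-1]
  for (col in c("x", "y", "z")) {
    v <- tree[[col]]
    sm <- v
    for (i in seq_len(nrow(tree))) {
      if (keep[i]) next
      # walk half steps up and down the unbranched chain
      idxs <- i
      up <- i
      for (s in seq_len(half)) {
        p <- pidx[up]
        if (is.na(p)) break
        idxs <- c(idxs, p); up <- p
      }
      down <- i
      for (s in seq_len(half)) {
        ch <- children[[as.character(tree$id[down])]]
        if (is.null(ch) || length(ch) != 1L) break
        idxs <- c(idxs, ch); down <- ch
      }
      sm[i] <- mean(v[idxs])
    }
    tree[[col]] <- sm
  }
  tree
}
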