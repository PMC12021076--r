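#' Rooted axon tree
#'
#' An `axon_tree` is a data frame of nodes describing one reconstructed or
#' simulated axon as a rooted tree in physical coordinates (micrometres).
#' Columns are the standard SWC fields: `id` (1-based integer node id),
#' `parent` (id of the parent node, `-1` for the root), `x`, `y`, `z`
#' (position, um) and `radius` (local half-width, um). The root conventionally
#' lies on the crush plane; regeneration proceeds toward increasing distance
#' along the nerve axis.
#'
#' @param nodes data frame with columns `id`, `parent`, `x`, `y`, `z`,
#'   `radius`. Parents must precede children and exactly one node must have
#'   `parent == -1`.
#' @return An object of class `axon_tree`.
#' @export
axon_tree <- function(nodes) {
  required <- c("id", "parent", "x", "y", "z", "radius")
  missing <- setdiff(required, names(nodes))
  if (length(missing) > 0) {
    stop("axon_tree nodes lack columns: ", paste(missing, collapse = ", "))
  }
  nodes <- as.data.frame(nodes)[, required]
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids in axon_tree")
  roots <- which(nodes$parent == -1L)
  if (length(roots) != 1L) {
    stop("axon_tree must have exactly one root (parent == -1), found ",
         length(roots))
  }
  pos <- match(nodes$parent, nodes$id)
  bad <- which(nodes$parent != -1L & (is.na(pos) | pos >= seq_len(nrow(nodes))))
  if (length(bad) > 0) {
    stop("dangling or forward parent pointer at node id ", nodes$id[bad[1]])
  }
  structure(nodes, class = c("axon_tree", "data.frame"))
}

#' @export
print.axon_tree <- function(x, ...) {
  cat(sprintf("<axon_tree: %d nodes, %d tip(s), length %.1f um>\n",
              nrow(x), length(tree_tips(x)), tree_length(x)))
  invisible(x)
}

parent_index <- function(tree) match(tree$parent, tree$id)

#' Tip (terminal leaf) node ids of an axon tree
#'
#' Tips are nodes with no children, excluding the root: an unbranched axon has
#' exactly one tip, a tree with one bifurcation has two.
#'
#' @param tree an `axon_tree`.
#' @return Integer vector of node ids.
#' @export
tree_tips <- function(tree) {
  has_child <- tree$id %in% tree$parent
  is_root <- tree$parent == -1L
  tree$id[!has_child & !is_root]
}

#' Branch-point node ids (nodes with two or more children)
#' @param tree an `axon_tree`.
#' @return Integer vector of node ids.
#' @export
tree_branch_points <- function(tree) {
  tab <- table(tree$parent[tree$parent != -1L])
  as.integer(names(tab)[tab >= 2L])
}

# cumulative arc length from the root to every node
node_arclen <- function(tree) {
  pidx <- parent_index(tree)
  seg <- numeric(nrow(tree))
  ok <- !is.na(pidx)
  seg[ok] <- sqrt((tree$x[ok] - tree$x[pidx[ok]])^2 +
                  (tree$y[ok] - tree$y[pidx[ok]])^2 +
                  (tree$z[ok] - tree$z[pidx[ok]])^2)
  arclen <- numeric(nrow(tree))
  for (i in seq_len(nrow(tree))) {
    arclen[i] <- if (is.na(pidx[i])) 0 else arclen[pidx[i]] + seg[i]
  }
  arclen
}

#' Arc length of the longest root-to-tip path
#'
#' The regeneration length of an axon: measured from the terminal end back to
#' the crush-site root along the tree.
#'
#' @param tree an `axon_tree`.
#' @return Length in micrometres (0 for a single-node tree).
#' @export
tree_length <- function(tree) {
  if (nrow(tree) == 1L) return(0)
  max(node_arclen(tree))
}

#' Node ids along the main (longest) root-to-tip path
#'
#' Ties between equally long tips are broken by the smaller node id so results
#' are deterministic.
#'
#' @param tree an `axon_tree`.
#' @return Integer vector of node ids ordered root first.
#' @export
tree_main_path <- function(tree) {
  arclen <- node_arclen(tree)
  tips <- tree_tips(tree)
  if (length(tips) == 0L) return(tree$id[tree$parent == -1L])
  tip_rows <- match(tips, tree$id)
  best <- tips[order(-arclen[tip_rows], tips)][1]
  path_to_root(tree, best)
}

# ids from root down to `node_id`
path_to_root <- function(tree, node_id) {
  pidx <- parent_index(tree)
  ids <- integer(0)
  row <- match(node_id, tree$id)
  while (!is.na(row)) {
    ids <- c(tree$id[row], ids)
    row <- pidx[row]
  }
  ids
}

# coordinates (matrix) for a vector of node ids
node_xyz <- function(tree, ids) {
  rows <- match(ids, tree$id)
  cbind(x = tree$x[rows], y = tree$y[rows], z = tree$z[rows])
}

#' Direction of the axonal tip
#'
#' Unit vector from the point `window` micrometres of arc length before the
#' terminal end of a root-to-tip path to the terminal point itself; this is
#' the "direction of the axonal tip" used for U-turn scoring.
#'
#' @param tree an `axon_tree`.
#' @param window arc-length window (um) over which the direction is taken.
#' @param tip_id tip node; defaults to the terminal of the main path.
#' @return Numeric length-3 unit vector.
#' @export
tip_direction <- function(tree, window = 20, tip_id = NULL) {
  path <- if (is.null(tip_id)) tree_main_path(tree) else path_to_root(tree, tip_id)
  xyz <- node_xyz(tree, path)
  n <- nrow(xyz)
  if (n < 2L) stop("cannot take a tip direction on a single-node path")
  seg <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-n, , drop = FALSE])^2))
  cum_from_tip <- rev(cumsum(rev(seg)))  # arc length from node i to the tip
  total <- cum_from_tip[1]
  if (total <= 0) stop("degenerate zero-length path")
  w <- min(window, total)
  # first node whose remaining arc to the tip is <= w, then interpolate back
  i <- which(cum_from_tip <= w)[1]
  if (is.na(i)) i <- n - 1L
  base <- xyz[i, ]
  if (i > 1L && cum_from_tip[i] < w) {
    # interpolate within segment (i-1, i) to sit exactly w before the tip
    excess <- w - cum_from_tip[i]
    dir_seg <- xyz[i - 1L, ] - xyz[i, ]
    len <- sqrt(sum(dir_seg^2))
    if (len > 0) base <- xyz[i, ] + dir_seg / len * min(excess, len)
  }
  v <- xyz[n, ] - base
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("degenerate zero-length tip direction")
  v / nv
}

#' Remove short terminal spurs from a tree
#'
#' Terminal branches (tip back to the nearest branch point) shorter than
#' `min_spur` are removed iteratively; the longest remaining path is never
#' removed, so a tree never collapses below a single root-to-tip path.
#' Pruning is idempotent.
#'
#' @param tree an `axon_tree`.
#' @param min_spur minimum terminal branch length to keep (um).
#' @return Pruned `axon_tree`.
#' @export
prune_spurs <- function(tree, min_spur = 10) {
  repeat {
    tips <- tree_tips(tree)
    if (length(tips) <= 1L) break
    arclen <- node_arclen(tree)
    main_tip <- tree_main_path(tree)
    main_tip <- main_tip[length(main_tip)]
    branch_ids <- tree_branch_points(tree)
    pidx <- parent_index(tree)
    removed_any <- FALSE
    drop_ids <- integer(0)
    for (tip in setdiff(tips, main_tip)) {
      # walk back to the first branch point (or root)
      seg_ids <- integer(0)
      row <- match(tip, tree$id)
      while (!is.na(row) && !(tree$id[row] %in% branch_ids) &&
             tree$parent[row] != -1L) {
        seg_ids <- c(seg_ids, tree$id[row])
        row <- pidx[row]
      }
      if (length(seg_ids) == 0L) next
      anchor_row <- row
      spur_len <- arclen[match(tip, tree$id)] -
        (if (is.na(anchor_row)) 0 else arclen[anchor_row])
      if (spur_len < min_spur) {
        drop_ids <- c(drop_ids, seg_ids)
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
    tree <- axon_tree(tree[!(tree$id %in% drop_ids), , drop = FALSE])
  }
  tree
}
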