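#' Read axon trees from an SWC file
#'
#' Standard 7-column SWC (`id type x y z radius parent`), micrometre units,
#' 1-based node ids, parent `-1` for roots, parents preceding children. A file
#' may hold several trees (one root each); each connected tree becomes one
#' [axon_tree()]. The SWC type field is not interpreted (axons are written
#' with type 2); comment lines start with `#`.
#'
#' @param path file path.
#' @return List of `axon_tree` objects.
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(list())
  fields <- strsplit(lines, "[[:space:]]+")
  nfield <- lengths(fields)
  if (any(nfield != 7L)) {
    stop("malformed SWC line (expected 7 columns): '",
         lines[which(nfield != 7L)[1]], "'")
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  if (anyNA(m)) stop("non-numeric field in SWC file ", path)
  nodes <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                      parent = as.integer(m[, 7]))
  if (anyDuplicated(nodes$id)) stop("duplicate node id in SWC file ", path)
  # check parent pointers: every non-root parent must exist and precede child
  pos <- match(nodes$parent, nodes$id)
  bad <- which(nodes$parent != -1L & (is.na(pos) | pos >= seq_len(nrow(nodes))))
  if (length(bad) > 0) {
    stop("SWC parent pointer error at line with node id ", nodes$id[bad[1]],
         " (dangling parent or parent does not precede child)")
  }
  # split into trees by following roots
  comp <- integer(nrow(nodes))
  root_rows <- which(nodes$parent == -1L)
  for (i in seq_len(nrow(nodes))) {
    comp[i] <- if (nodes$parent[i] == -1L) i else comp[pos[i]]
  }
  lapply(root_rows, function(r) {
    sub <- nodes[comp == r, c("id", "parent", "x", "y", "z", "radius")]
    axon_tree(sub)
  })
}

#' Write axon trees to an SWC file
#'
#' Node ids are renumbered consecutively across trees so the output is a valid
#' single SWC forest; coordinates, radii and topology are preserved exactly
#' (round-trip identity up to comment lines).
#'
#' @param trees list of `axon_tree` objects (a single tree is accepted).
#' @param path output file path.
#' @param type SWC structure type code written for every node (2 = axon).
#' @param comment optional character vector of header comment lines.
#' @return Invisibly, `path`.
#' @export
write_swc <- function(trees, path, type = 2L, comment = NULL) {
  if (inherits(trees, "axon_tree")) trees <- list(trees)
  out <- character(0)
  if (!is.null(comment)) out <- paste0("# ", comment)
  offset <- 0L
  for (tree in trees) {
    id_new <- seq_len(nrow(tree)) + offset
    parent_new <- ifelse(tree$parent == -1L, -1L,
                         id_new[match(tree$parent, tree$id)])
    out <- c(out, sprintf("%d %d %.6g %.6g %.6g %.6g %d",
                          id_new, type, tree$x, tree$y, tree$z, tree$radius,
                          parent_new))
    offset <- offset + nrow(tree)
  }
  writeLines(out, path)
  invisible(path)
}
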