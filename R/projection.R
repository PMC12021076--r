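#' Maximum-intensity Z-projections over groups of consecutive slices
#'
#' Projects every `group` consecutive z slices to one 2D maximum-intensity
#' image: the default group of 4 slices at 2-um spacing yields the standard
#' series of 8-um optical sections. `group` equal to the slice count yields
#' the single full maximum-intensity projection.
#'
#' @param stack an [image_stack()].
#' @param group number of consecutive slices per projection (>= 1).
#' @return Object of class `z_projection_set`: list with `projections` (list
#'   of matrices), `slice_ranges` (data frame `first`, `last`), `voxel`,
#'   `origin`, `group`.
#' @export
project_z <- function(stack, group = 4L) {
  stopifnot(inherits(stack, "image_stack"))
  group <- as.integer(group)
  if (group < 1L) stop("group must be >= 1")
  nz <- dim(stack$data)[3]
  if (group > nz) {
    warning("group (", group, ") exceeds slice count (", nz,
            "); returning a single full projection")
    group <- nz
  }
  n_proj <- ceiling(nz / group)
  projections <- vector("list", n_proj)
  first <- integer(n_proj)
  last <- integer(n_proj)
  for (p in seq_len(n_proj)) {
    first[p] <- (p - 1L) * group + 1L
    last[p] <- min(p * group, nz)
    proj <- stack$data[, , first[p]]
    if (last[p] > first[p]) {
      for (k in (first[p] + 1L):last[p]) proj <- pmax(proj, stack$data[, , k])
    }
    projections[[p]] <- proj
  }
  structure(list(projections = projections,
                 slice_ranges = data.frame(first = first, last = last),
                 voxel = stack$voxel, origin = stack$origin, group = group),
            class = "z_projection_set")
}

#' @export
print.z_projection_set <- function(x, ...) {
  cat(sprintf("<z_projection_set: %d projection(s) of %d slice(s) each>\n",
              length(x$projections), x$group))
  invisible(x)
}

#' Full maximum-intensity projection as a one-slice stack
#'
#' Convenience for measurements performed on the merged Z-projection image
#' (tip morphometry, trajectory overlays): returns a single-slice
#' [image_stack()] whose lateral geometry matches the input. Coordinates of
#' 3D trees can be used against it directly (the z index clamps to the single
#' slice).
#'
#' @param stack an [image_stack()].
#' @return A one-slice [image_stack()].
#' @export
project_stack <- function(stack) {
  mip <- project_z(stack, group = dim(stack$data)[3])$projections[[1]]
  image_stack(array(mip, c(dim(mip), 1L)),
              voxel = c(stack$voxel[1], stack$voxel[2], 1),
              origin = c(stack$origin[1], stack$origin[2], 0),
              channel = stack$channel)
}
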