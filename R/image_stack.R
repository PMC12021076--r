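#' Fluorescence image stack
#'
#' A 3D voxel grid of intensities with physical voxel sizes and a channel
#' tag. Voxel `[i, j, k]` is centred at `origin + (i-1, j-1, k-1) * voxel`
#' in micrometres, with the first array dimension along the nerve axis (x).
#'
#' @param data numeric 3D array (2D matrices are promoted to one slice).
#' @param voxel voxel sizes `c(dx, dy, dz)` in um.
#' @param origin physical position of the first voxel centre (um).
#' @param channel channel tag.
#' @return Object of class `image_stack`.
#' @export
image_stack <- function(data, voxel, origin = c(0, 0, 0), channel = "CTB") {
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3L) stop("data must be a 2D or 3D array")
  if (length(voxel) == 2L) voxel <- c(voxel, 1)
  if (length(voxel) != 3L || any(!is.finite(voxel)) || any(voxel <= 0)) {
    stop("voxel must be three positive sizes (um)")
  }
  structure(list(data = data, voxel = as.numeric(voxel),
                 origin = as.numeric(origin), channel = channel),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_stack '%s': %d x %d x %d voxels at %.3g x %.3g x %.3g um>\n",
    x$channel, d[1], d[2], d[3], x$voxel[1], x$voxel[2], x$voxel[3]))
  invisible(x)
}

#' Write an image stack as a multi-page TIFF
#'
#' One 16-bit page per z slice; intensities are scaled by `scale` (default the
#' stack maximum) into `[0, 1]` as the TIFF format requires. The physical
#' metadata (voxel sizes, origin, channel, scale) is written to a JSON sidecar
#' `<path>.meta.json` so that [read_stack_tiff()] can restore the stack.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @param scale intensity mapped to the 16-bit maximum.
#' @return Invisibly, `path`.
#' @export
write_stack_tiff <- function(stack, path, scale = NULL) {
  if (is.null(scale)) scale <- max(stack$data, 1e-12)
  pages <- lapply(seq_len(dim(stack$data)[3]), function(k) {
    # tiff expects row-major images; store x along columns
    t(pmin(pmax(stack$data[, , k] / scale, 0), 1))
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(voxel = stack$voxel, origin = stack$origin,
               channel = stack$channel, scale = scale)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF written by [write_stack_tiff()]
#'
#' @param path TIFF path (the `<path>.meta.json` sidecar must exist; without
#'   it, unit voxel sizes are assumed).
#' @return An [image_stack()].
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(voxel = c(1, 1, 1), origin = c(0, 0, 0), channel = "unknown",
         scale = 1)
  }
  arr <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]]) * meta$scale
  image_stack(arr, voxel = meta$voxel, origin = meta$origin,
              channel = meta$channel)
}
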