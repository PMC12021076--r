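#' Rasterize ground-truth axons into a fluorescence stack
#'
#' Axons are drawn as tubes of the configured shaft diameter with the
#' terminal region widened to the ground-truth tip/shaft ratio (a sphere of
#' radius `ratio x shaft radius` at the terminal point of each axon's main
#' path, emulating a retraction bulb or growth cone). The local chord
#' thickness of the structure is converted to expected photons
#' (`photon_scale` per um of thickness), blurred by a Gaussian PSF, and
#' degraded by Poisson shot noise, constant background and optional Gaussian
#' read noise. With `psf_sigma = 0` and noise off, the suprathreshold mask
#' equals the exact tube rasterization.
#'
#' @param truth a [simulate_nerve()] / [simulate_chiasm()] result.
#' @param imaging an [imaging_config()].
#' @param pad spatial margin around the axon bounding box (um); defaults to
#'   the largest tip radius plus 3 PSF sigma plus one shaft diameter.
#' @param allow_large override the `max_voxels` resource cap.
#' @return An [image_stack()] (channel `"CTB"`).
#' @export
rasterize_stack <- function(truth, imaging, pad = NULL, allow_large = FALSE) {
  stopifnot(inherits(truth, "ground_truth"), inherits(imaging, "imaging_config"))
  shaft_r <- truth$config$shaft_diameter / 2
  tipr <- truth$labels$true_tip_ratio * shaft_r
  if (is.null(pad)) {
    pad <- max(tipr, 0) + 3 * max(imaging$psf_sigma, imaging$psf_sigma_z) +
      truth$config$shaft_diameter
  }

  segs <- list()
  for (tree in truth$axons) {
    pidx <- parent_index(tree)
    ok <- which(!is.na(pidx))
    if (length(ok) > 0) {
      segs[[length(segs) + 1L]] <- cbind(
        tree$x[pidx[ok]], tree$y[pidx[ok]], tree$z[pidx[ok]],
        tree$x[ok], tree$y[ok], tree$z[ok], tree$radius[ok])
    }
  }
  segs <- if (length(segs) > 0) do.call(rbind, segs) else
    matrix(numeric(0), ncol = 7)

  spheres <- matrix(numeric(0), ncol = 4)
  if (length(truth$axons) > 0) {
    sp <- lapply(seq_along(truth$axons), function(i) {
      tree <- truth$axons[[i]]
      path <- tree_main_path(tree)
      tip <- node_xyz(tree, path[length(path)])
      c(tip, truth$labels$true_tip_ratio[i] * shaft_r)
    })
    spheres <- do.call(rbind, sp)
  }

  if (nrow(segs) == 0 && nrow(spheres) == 0) {
    # zero axons: a small stack of pure background/noise
    bbox <- rbind(c(0, 0, 0), c(50, 50, 10))
  } else {
    pts <- rbind(segs[, 1:3, drop = FALSE], segs[, 4:6, drop = FALSE],
                 spheres[, 1:3, drop = FALSE])
    bbox <- rbind(apply(pts, 2, min) - pad, apply(pts, 2, max) + pad)
  }
  voxel <- c(imaging$pixel_size_xy, imaging$pixel_size_xy, imaging$z_spacing)
  dims <- pmax(2L, as.integer(ceiling((bbox[2, ] - bbox[1, ]) / voxel)) + 1L)
  if (prod(as.numeric(dims)) > imaging$max_voxels && !allow_large) {
    stop("rasterization grid of ", paste(dims, collapse = " x "),
         " voxels exceeds max_voxels (", imaging$max_voxels,
         "); pass allow_large = TRUE to override")
  }
  origin <- bbox[1, ]

  thickness <- draw_structures(dims, voxel, origin, segs, spheres)
  signal <- thickness * imaging$photon_scale
  if (imaging$psf_sigma > 0 || imaging$psf_sigma_z > 0) {
    sig_vox <- c(imaging$psf_sigma, imaging$psf_sigma,
                 imaging$psf_sigma_z) / voxel
    signal <- gauss_blur3d(signal, dims, sig_vox)
  }
  img <- with_seed(imaging$seed, {
    out <- if (imaging$shot_noise) {
      array(stats::rpois(length(signal), signal + imaging$background),
            dim = dims)
    } else signal + imaging$background
    if (imaging$read_noise_sd > 0) {
      out <- out + array(stats::rnorm(length(out), 0, imaging$read_noise_sd),
                         dim = dims)
    }
    out
  })
  dim(img) <- dims
  image_stack(img, voxel = voxel, origin = origin, channel = "CTB")
}
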