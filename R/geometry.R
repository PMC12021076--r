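#' Nerve coordinate frame
#'
#' Defines the physical frame in which all regeneration distances are
#' measured: the crush plane, the nerve's longitudinal unit axis, and the
#' nerve extent. The convention throughout the package is micrometre
#' coordinates with the crush plane at `x = 0` and regeneration toward `+x`,
#' but any crush position and unit axis may be supplied. Optional chiasm
#' landmarks (see [chiasm_landmarks()]) support fate classification.
#'
#' @param crush_x position of the crush plane along the axis (um).
#' @param axis longitudinal unit axis (length-3); normalised internally.
#' @param extent total nerve extent distal to the crush plane (um).
#' @param radius nerve radius (um).
#' @param chiasm optional [chiasm_landmarks()] record.
#' @return Object of class `nerve_geometry`.
#' @export
nerve_geometry <- function(crush_x = 0, axis = c(1, 0, 0), extent = 2000,
                           radius = 100, chiasm = NULL) {
  axis <- as.numeric(axis)
  nv <- sqrt(sum(axis^2))
  if (!is.finite(nv) || nv == 0) stop("axis must be a nonzero vector")
  if (!is.finite(crush_x)) stop("crush_x must be finite")
  if (!is.finite(extent) || extent <= 0) stop("extent must be positive")
  structure(list(crush_x = crush_x, axis = axis / nv, extent = extent,
                 radius = radius, chiasm = chiasm),
            class = "nerve_geometry")
}

#' Optic-chiasm landmark planes and regions
#'
#' Landmarks used to classify the fate of regenerating axons at the chiasm,
#' all expressed in the injured nerve's frame (axis `+x`): the optic
#' nerve-chiasm transition zone (OCTZ) plane at `x = octz_x`, the plane at
#' which the optic tracts begin (`x = tract_x`), and the chiasm midline plane
#' at `y = midline_y`. The injured nerve approaches on the ipsilateral side
#' (`y < midline_y`). Fate regions for a terminal point:
#' proximal to the OCTZ and ipsilateral = pre-chiasmic; at or beyond the
#' tract plane = ipsi- or contralateral optic tract by side of the midline;
#' proximal to the OCTZ but across the midline = contralateral optic nerve.
#'
#' @param octz_x OCTZ plane position (um, distal to the crush plane).
#' @param tract_x tract-entry plane position (um); must exceed `octz_x`.
#' @param midline_y chiasm midline position (um).
#' @return Object of class `chiasm_landmarks`.
#' @export
chiasm_landmarks <- function(octz_x = 500, tract_x = 900, midline_y = 100) {
  if (!(tract_x > octz_x)) stop("tract_x must lie distal to octz_x")
  structure(list(octz_x = octz_x, tract_x = tract_x, midline_y = midline_y),
            class = "chiasm_landmarks")
}

# signed distance of points distal to the crush plane, along the axis
axial_distance <- function(geometry, xyz) {
  xyz <- rbind(xyz)
  sweep(xyz, 2, c(geometry$crush_x * geometry$axis[1],
                  geometry$crush_x * geometry$axis[2],
                  geometry$crush_x * geometry$axis[3])) %*% geometry$axis
}
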