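#' Count regenerating fibers at fixed intervals distal to the crush site
#'
#' In each Z-projection, a counting line is drawn perpendicular to the nerve
#' axis at every `interval` distal to the crush site, and the fibers crossing
#' it are counted as maximal suprathreshold pixel runs of at least `min_run`
#' pixels (runs separated by at least one background pixel are distinct).
#' Counts at each distance are summed over all Z-projections — deliberately
#' replicating the stated sum-over-projections procedure, under which an axon
#' spanning several optical sections is counted in each. Scanning stops at
#' the first distance at which every projection gives zero (the formalization
#' of "no visible fluorescence signal"); counts beyond the stop distance are
#' reported as zero.
#'
#' The nerve axis must coincide with the image x axis (crushed nerves are
#' imaged straightened); the crush plane must fall inside the image.
#'
#' @param projections a [project_z()] result.
#' @param geometry a [nerve_geometry()].
#' @param interval counting interval (um, default 250).
#' @param threshold suprathreshold criterion: a numeric intensity, or `NULL`
#'   for an Otsu threshold pooled over all projections.
#' @param min_run minimum run length in pixels counted as a fiber.
#' @param max_distance furthest counting line considered (um); defaults to
#'   the nerve extent.
#' @return Data frame `distance_um`, `count`, plus attributes `stop_distance`
#'   (um) and `threshold`.
#' @export
count_fibers <- function(projections, geometry, interval = 250,
                         threshold = NULL, min_run = 2L,
                         max_distance = NULL) {
  stopifnot(inherits(projections, "z_projection_set"))
  if (abs(abs(geometry$axis[1]) - 1) > 1e-6) {
    stop("count_fibers requires the nerve axis to lie along image x")
  }
  dx <- projections$voxel[1]
  nx <- nrow(projections$projections[[1]])
  x0 <- projections$origin[1]
  crush_col <- (geometry$crush_x - x0) / dx + 1
  if (crush_col < 0.5 || crush_col > nx + 0.5) {
    stop("crush plane lies outside the image")
  }
  if (is.null(max_distance)) max_distance <- geometry$extent
  if (is.null(threshold)) {
    threshold <- otsu_threshold(unlist(lapply(projections$projections,
                                              as.numeric)))
  }
  distances <- seq(interval, max_distance, by = interval)
  counts <- integer(length(distances))
  stop_distance <- NA_real_
  for (j in seq_along(distances)) {
    col <- round((geometry$crush_x + distances[j] - x0) / dx) + 1
    if (col < 1 || col > nx) {
      stop_distance <- if (is.na(stop_distance)) distances[j] else stop_distance
      break
    }
    total <- 0L
    for (proj in projections$projections) {
      total <- total + count_runs(proj[col, ] > threshold, min_run)
    }
    if (total == 0L) {
      stop_distance <- distances[j]
      break
    }
    counts[j] <- total
  }
  if (is.na(stop_distance)) {
    stop_distance <- max(distances) + interval
  }
  out <- data.frame(distance_um = distances, count = counts)
  attr(out, "stop_distance") <- stop_distance
  attr(out, "threshold") <- threshold
  out
}

# number of maximal TRUE runs of length >= min_run
count_runs <- function(above, min_run = 2L) {
  if (!any(above)) return(0L)
  r <- rle(above)
  sum(r$values & r$lengths >= min_run)
}
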