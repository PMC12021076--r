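#' Simulate paired control / injured whole-mount retina fields
#'
#' Control fields draw Tuj1+ cell counts from a Poisson law at
#' `cell_density`; injured fields at `cell_density x survival_fraction`
#' (modeling post-injury cell loss). Cells are placed without overlap
#' (centre separation at least 2.2 cell radii; exceeding the rejection cap
#' raises a configuration error), and each carries Cre and p-S6 marker flags
#' drawn at the configured co-expression fractions, per-cell peak
#' intensities, and rendered Gaussian-spot channel images (`tuj1`, `cre`,
#' `ps6`) with additive noise and background.
#'
#' @param config a [retina_sim_config()].
#' @return Object of class `retina_pair`: list with `control` and `injured`
#'   (each a list of fields: `channels` (list of matrices), `cells` (truth
#'   data frame `x`, `y`, `tuj1_intensity`, `cre`, `ps6`), `pixel_size`) and
#'   `truth` (per-field count table with `arm`, `field`, `n_tuj1`, `n_cre`,
#'   `n_ps6`).
#' @export
simulate_retina_pair <- function(config) {
  stopifnot(inherits(config, "retina_sim_config"))
  arms <- list(control = config$cell_density,
               injured = config$cell_density * config$survival_fraction)
  out <- list()
  truth <- list()
  counter <- 0L
  for (arm in names(arms)) {
    fields <- vector("list", config$n_fields)
    for (f in seq_len(config$n_fields)) {
      counter <- counter + 1L
      fields[[f]] <- with_seed(derive_seed(config$seed, counter),
                               simulate_field(config, arms[[arm]]))
      truth[[length(truth) + 1L]] <- data.frame(
        arm = arm, field = f, n_tuj1 = nrow(fields[[f]]$cells),
        n_cre = sum(fields[[f]]$cells$cre),
        n_ps6 = sum(fields[[f]]$cells$ps6))
    }
    out[[arm]] <- fields
  }
  structure(list(control = out$control, injured = out$injured,
                 truth = do.call(rbind, truth), config = config),
            class = "retina_pair")
}

#' @export
print.retina_pair <- function(x, ...) {
  tt <- stats::aggregate(n_tuj1 ~ arm, x$truth, sum)
  cat(sprintf("<retina_pair: %d fields/arm; Tuj1+ control %d, injured %d>\n",
              x$config$n_fields, tt$n_tuj1[tt$arm == "control"],
              tt$n_tuj1[tt$arm == "injured"]))
  invisible(x)
}

simulate_field <- function(config, density) {
  w <- config$field_size[1]
  h <- config$field_size[2]
  area_mm2 <- w * h / 1e6
  n <- stats::rpois(1, density * area_mm2)
  min_sep <- 2.2 * config$cell_radius
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (a in seq_len(config$max_place_attempts)) {
      x <- stats::runif(1, config$cell_radius, w - config$cell_radius)
      y <- stats::runif(1, config$cell_radius, h - config$cell_radius)
      if (length(xs) == 0 || min((xs - x)^2 + (ys - y)^2) >= min_sep^2) {
        xs <- c(xs, x); ys <- c(ys, y)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("cell_density too high to place cells without overlap ",
           "(rejection cap reached)")
    }
  }
  n <- length(xs)
  cells <- data.frame(
    x = xs, y = ys,
    tuj1_intensity = pmax(stats::rnorm(n, config$intensity_mean,
                                       config$intensity_sd),
                          config$intensity_mean / 4),
    cre = stats::runif(n) < config$cre_fraction,
    ps6 = stats::runif(n) < config$ps6_fraction)
  cells$cre_intensity <- ifelse(
    cells$cre, pmax(stats::rnorm(n, config$intensity_mean,
                                 config$intensity_sd),
                    config$intensity_mean / 4), 0)
  cells$ps6_intensity <- ifelse(
    cells$ps6, pmax(stats::rnorm(n, config$intensity_mean,
                                 config$intensity_sd),
                    config$intensity_mean / 4), 0)
  channels <- list(
    tuj1 = render_spots(cells$x, cells$y, cells$tuj1_intensity, config),
    cre = render_spots(cells$x[cells$cre], cells$y[cells$cre],
                       cells$cre_intensity[cells$cre], config),
    ps6 = render_spots(cells$x[cells$ps6], cells$y[cells$ps6],
                       cells$ps6_intensity[cells$ps6], config))
  list(channels = channels, cells = cells, pixel_size = config$pixel_size)
}

# Gaussian spots of SD cell_radius/2 plus background and Gaussian noise
render_spots <- function(xs, ys, amps, config) {
  nx <- ceiling(config$field_size[1] / config$pixel_size)
  ny <- ceiling(config$field_size[2] / config$pixel_size)
  img <- matrix(0, nx, ny)
  if (length(xs) > 0) {
    sig <- config$cell_radius / 2 / config$pixel_size
    r <- ceiling(3 * sig)
    for (i in seq_along(xs)) {
      cx <- xs[i] / config$pixel_size + 0.5
      cy <- ys[i] / config$pixel_size + 0.5
      i0 <- max(1, floor(cx - r)); i1 <- min(nx, ceiling(cx + r))
      j0 <- max(1, floor(cy - r)); j1 <- min(ny, ceiling(cy + r))
      gx <- exp(-((i0:i1) - cx)^2 / (2 * sig^2))
      gy <- exp(-((j0:j1) - cy)^2 / (2 * sig^2))
      img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + amps[i] * outer(gx, gy)
    }
  }
  img + config$background +
    matrix(stats::rnorm(nx * ny, 0, config$noise_sd), nx, ny)
}

#' Detect cells in a single-channel field image
#'
#' Gaussian smoothing at the cell-radius scale, robust global thresholding
#' (background median plus `k` robust SDs, estimated by the MAD), connected
#' component labeling, and size filtering. Components large enough to hold
#' several touching cells are split by intensity peaks: local maxima at
#' least `1.5 x cell_radius` apart seed a nearest-peak assignment of the
#' component's pixels. Per-cell mean intensity is computed over the cell
#' mask on the raw image after subtracting the background median. Detection
#' is invariant to an overall intensity scaling and, after background
#' subtraction, to a constant offset.
#'
#' @param img numeric matrix (single-channel field).
#' @param pixel_size pixel size (um).
#' @param cell_radius expected cell radius (um).
#' @param k threshold in robust SDs above the background median.
#' @param min_area_frac minimum detected area as a fraction of the nominal
#'   cell area.
#' @return Data frame of cell records: `x`, `y` (centroid, um), `area_um2`,
#'   `mean_intensity` (background-subtracted).
#' @export
detect_cells <- function(img, pixel_size = 1, cell_radius = 5, k = 3,
                         min_area_frac = 0.15) {
  if (max(img) - min(img) < .Machine$double.eps) {
    stop("degenerate input: constant-intensity field")
  }
  sig <- cell_radius / 2 / pixel_size
  dims <- c(nrow(img), ncol(img), 1L)
  sm <- array(gauss_blur3d(array(img, dims), dims, c(sig, sig, 0)),
              dims)[, , 1]
  bg <- stats::median(img)
  spread <- stats::mad(img)   # noise estimated on the raw image
  if (spread == 0) spread <- stats::sd(img)
  # noise floor (median + k robust SDs) OR the Otsu split of the smoothed
  # histogram, whichever is higher: the floor rejects empty fields, Otsu
  # keeps dense fields segmented at spot cores instead of merged halos
  thr <- max(bg + k * spread, otsu_threshold(as.numeric(sm)))
  mask <- sm > thr
  if (!any(mask)) {
    return(data.frame(x = numeric(0), y = numeric(0), area_um2 = numeric(0),
                      mean_intensity = numeric(0)))
  }
  lab <- EBImage::bwlabel(mask)
  raw_bg <- stats::median(img[!mask])
  n_lab <- max(lab)
  px <- which(lab > 0, arr.ind = TRUE)
  lab_id <- lab[lab > 0]
  area <- tabulate(lab_id, n_lab)
  min_area <- min_area_frac * pi * (cell_radius / pixel_size)^2
  keep <- which(area >= min_area)
  if (length(keep) == 0) {
    return(data.frame(x = numeric(0), y = numeric(0), area_um2 = numeric(0),
                      mean_intensity = numeric(0)))
  }
  ref_area <- stats::median(area[keep])
  min_peak_sep <- 1.5 * cell_radius / pixel_size
  rows <- list()
  for (id in keep) {
    sel <- lab_id == id
    pxy <- px[sel, , drop = FALSE]
    vals_sm <- sm[pxy]
    n_est <- max(1L, round(area[id] / ref_area))
    if (n_est > 1L) {
      # split merged cells: greedy intensity peaks with a minimum separation
      ord <- order(-vals_sm)
      peaks <- integer(0)
      for (i in ord) {
        if (length(peaks) == 0L ||
            min(sqrt((pxy[peaks, 1] - pxy[i, 1])^2 +
                     (pxy[peaks, 2] - pxy[i, 2])^2)) >= min_peak_sep) {
          peaks <- c(peaks, i)
        }
      }
      assign_to <- max.col(-(outer(pxy[, 1], pxy[peaks, 1], "-")^2 +
                             outer(pxy[, 2], pxy[peaks, 2], "-")^2),
                           ties.method = "first")
    } else {
      assign_to <- rep(1L, nrow(pxy))
    }
    for (sub in unique(assign_to)) {
      ss <- assign_to == sub
      if (sum(ss) < min_area) next
      rows[[length(rows) + 1L]] <- data.frame(
        x = (mean(pxy[ss, 1]) - 0.5) * pixel_size,
        y = (mean(pxy[ss, 2]) - 0.5) * pixel_size,
        area_um2 = sum(ss) * pixel_size^2,
        mean_intensity = mean(img[pxy[ss, , drop = FALSE]] - raw_bg))
    }
  }
  if (length(rows) == 0) {
    return(data.frame(x = numeric(0), y = numeric(0), area_um2 = numeric(0),
                      mean_intensity = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Match detected cells across two channels
#'
#' Greedy nearest-neighbour matching under a distance cap: the closest
#' remaining pair is matched first and each cell matches at most once. Used
#' for double-positive counting (e.g. Cre/Tuj1, p-S6/Tuj1).
#'
#' @param cells_a,cells_b data frames with `x`, `y` columns (um).
#' @param radius maximum matching distance (um, default 5).
#' @return List with `n_matched` and `pairs` (data frame of row indices
#'   `a`, `b`, `dist`).
#' @export
match_channels <- function(cells_a, cells_b, radius = 5) {
  na <- nrow(cells_a); nb <- nrow(cells_b)
  if (na == 0 || nb == 0) {
    return(list(n_matched = 0L,
                pairs = data.frame(a = integer(0), b = integer(0),
                                   dist = numeric(0))))
  }
  d <- sqrt(outer(cells_a$x, cells_b$x, "-")^2 +
            outer(cells_a$y, cells_b$y, "-")^2)
  pairs <- list()
  repeat {
    m <- which.min(d)
    if (length(m) == 0 || d[m] > radius) break
    i <- (m - 1) %% na + 1
    j <- (m - 1) %/% na + 1
    pairs[[length(pairs) + 1L]] <- data.frame(a = i, b = j, dist = d[m])
    d[i, ] <- Inf
    d[, j] <- Inf
  }
  pairs <- if (length(pairs) > 0) do.call(rbind, pairs) else
    data.frame(a = integer(0), b = integer(0), dist = numeric(0))
  list(n_matched = nrow(pairs), pairs = pairs)
}

#' RGC survival rate
#'
#' One hundred times the ratio of the summed Tuj1+ cell count over the
#' injured fields to that over the control fields. The ratio is computed on
#' summed counts (robust to empty fields); per-field counts should be
#' retained by the caller for dispersion reporting. Values above 120% are
#' flagged as implausible (sampling noise can push a true 100% slightly
#' above, not far above).
#'
#' @param injured_counts,control_counts per-field Tuj1+ counts.
#' @return Survival rate in percent, with attribute `flag_high` if > 120.
#' @export
survival_rate <- function(injured_counts, control_counts) {
  if (length(injured_counts) < 1 || length(control_counts) < 1) {
    stop("need at least one field per arm")
  }
  ctrl <- sum(control_counts)
  if (ctrl == 0) stop("undefined ratio: control arm has zero Tuj1+ cells")
  rate <- 100 * sum(injured_counts) / ctrl
  attr(rate, "flag_high") <- rate > 120
  rate
}

#' Marker-positive fraction
#'
#' One hundred times the double-positive count over the denominator count:
#' the form used for AAV transduction efficiency (Cre/Tuj1 over Tuj1) and
#' the p-S6+ RGC percentage (p-S6/Tuj1 over Tuj1).
#'
#' @param double_count double-positive cell count.
#' @param denominator_count denominator (e.g. Tuj1+) cell count.
#' @return Percentage in `[0, 100]`.
#' @export
marker_fraction <- function(double_count, denominator_count) {
  if (denominator_count <= 0) {
    stop("undefined ratio: denominator count must be positive")
  }
  if (double_count > denominator_count) {
    stop("double-positive count exceeds denominator count")
  }
  100 * double_count / denominator_count
}

#' Mean fluorescence intensity relative to control
#'
#' Per-cell background-subtracted mean intensities are averaged within each
#' condition and reported relative to the control mean (control = 1.0).
#' An optional per-section sampling cap emulates selecting a fixed number of
#' cells per section.
#'
#' @param condition_values per-cell intensities in the test condition.
#' @param control_values per-cell intensities in the control condition.
#' @param cap optional maximum number of cells used per condition (first
#'   `cap` cells, matching a fixed sampling protocol).
#' @return List with `relative` (condition mean / control mean),
#'   `condition_mean`, `control_mean`, `n_condition`, `n_control`.
#' @export
relative_intensity <- function(condition_values, control_values, cap = NULL) {
  if (length(condition_values) < 1 || length(control_values) < 1) {
    stop("need at least one cell per condition")
  }
  if (!is.null(cap)) {
    condition_values <- utils::head(condition_values, cap)
    control_values <- utils::head(control_values, cap)
  }
  cm <- mean(control_values)
  if (cm == 0) stop("undefined ratio: control mean intensity is zero")
  list(relative = mean(condition_values) / cm,
       condition_mean = mean(condition_values), control_mean = cm,
       n_condition = length(condition_values),
       n_control = length(control_values))
}
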