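#' Configuration for the nerve regeneration simulator
#'
#' Parameterizes the ground-truth generator: how many axons emanate from the
#' crush plane, how far they extend (truncated-exponential law with mean
#' `length_scale`), how tortuous their correlated-random-walk trajectories
#' are, and the rates of the scored phenomena (terminal U-turns, branch
#' events, retraction-bulb versus growth-cone terminal morphology).
#'
#' Ground-truth tip ratios are drawn from `bulb_ratio_range` (entirely above
#' the classification threshold 4) or `gc_ratio_range` (entirely below it), so
#' the generated labels are unambiguous under the tip/shaft > 4 rule.
#'
#' Axon starting points are laid out on a jittered grid over the crush-plane
#' disc and each axon is confined to a lateral corridor of radius
#' `corridor_radius` around its start, so that with sufficient `lane_spacing`
#' simulated axons are guaranteed not to touch (which the oracle-equivalence
#' checks rely on).
#'
#' @param n_axons number of regenerating axons.
#' @param crush_x crush-plane position along the axis (um); conventionally 0.
#' @param nerve_length nerve extent distal to the crush plane (um).
#' @param nerve_radius nerve radius (um).
#' @param length_scale mean of the truncated-exponential axon extension (um).
#' @param min_length lower truncation of the extension law (um).
#' @param step polyline step length (um).
#' @param tortuosity_sd per-step angular perturbation SD (degrees).
#' @param p_uturn probability that an axon ends in one terminal reversal.
#' @param branch_rate branch events per mm of arc length.
#' @param branch_max_len maximum side-branch length (um); bounds the lateral
#'   reach of branches so lane separation guarantees still hold.
#' @param p_bulb probability that the terminal tip is a retraction bulb.
#' @param bulb_ratio_range ground-truth tip/shaft ratio interval for bulbs
#'   (must lie entirely above 4).
#' @param gc_ratio_range tip/shaft ratio interval for growth cones (entirely
#'   below 4).
#' @param shaft_diameter axon shaft diameter (um).
#' @param lane_spacing spacing of the start-point grid (um).
#' @param corridor_radius lateral corridor radius confining each walk (um).
#' @param turn_radius radius of the terminal U-turn arc (um).
#' @param uturn_tail length of the reversed tail after a U-turn (um).
#' @param flat if `TRUE`, trajectories stay in the start z-plane (single
#'   optical section geometry).
#' @param seed integer root seed; per-axon substreams are derived by counter
#'   so adding axons does not perturb earlier ones.
#' @return Object of class `nerve_sim_config`.
#' @export
nerve_sim_config <- function(n_axons = 50, crush_x = 0, nerve_length = 2000,
                             nerve_radius = 200, length_scale = 400,
                             min_length = 60, step = 5, tortuosity_sd = 4,
                             p_uturn = 0.1, branch_rate = 0.2,
                             branch_max_len = 80, p_bulb = 0.5,
                             bulb_ratio_range = c(5, 8),
                             gc_ratio_range = c(1, 2), shaft_diameter = 2,
                             lane_spacing = 25, corridor_radius = 8,
                             turn_radius = 8, uturn_tail = 50, flat = FALSE,
                             seed = 1L) {
  cfg <- list(n_axons = as.integer(n_axons), crush_x = crush_x,
              nerve_length = nerve_length, nerve_radius = nerve_radius,
              length_scale = length_scale, min_length = min_length,
              step = step, tortuosity_sd = tortuosity_sd, p_uturn = p_uturn,
              branch_rate = branch_rate,
              branch_max_len = branch_max_len, p_bulb = p_bulb,
              bulb_ratio_range = as.numeric(bulb_ratio_range),
              gc_ratio_range = as.numeric(gc_ratio_range),
              shaft_diameter = shaft_diameter, lane_spacing = lane_spacing,
              corridor_radius = corridor_radius, turn_radius = turn_radius,
              uturn_tail = uturn_tail, flat = isTRUE(flat),
              seed = as.integer(seed))
  pos <- c("nerve_length", "nerve_radius", "length_scale", "min_length",
           "step", "shaft_diameter", "lane_spacing", "corridor_radius",
           "turn_radius", "uturn_tail", "branch_max_len")
  for (f in pos) {
    v <- cfg[[f]]
    if (!is.finite(v) || v <= 0) stop("config field '", f, "' must be positive")
  }
  for (f in c("tortuosity_sd", "branch_rate")) {
    v <- cfg[[f]]
    if (!is.finite(v) || v < 0) stop("config field '", f, "' must be non-negative")
  }
  for (f in c("p_uturn", "p_bulb")) {
    v <- cfg[[f]]
    if (!is.finite(v) || v < 0 || v > 1) {
      stop("config field '", f, "' must lie in [0, 1]")
    }
  }
  if (cfg$n_axons < 0) stop("n_axons must be non-negative")
  if (length(cfg$bulb_ratio_range) != 2 || any(cfg$bulb_ratio_range <= 4)) {
    stop("bulb_ratio_range must lie entirely above the threshold 4")
  }
  if (length(cfg$gc_ratio_range) != 2 || any(cfg$gc_ratio_range >= 4)) {
    stop("gc_ratio_range must lie entirely below the threshold 4")
  }
  structure(cfg, class = "nerve_sim_config")
}

#' Configuration for fluorescence stack rasterization
#'
#' The imaging model: axons are rendered as tubes (terminal regions widened
#' according to the ground-truth tip ratio), the optical point-spread function
#' is approximated by a Gaussian blur of SD `psf_sigma`, and the recorded
#' intensity is Poisson shot noise on the blurred signal plus a constant
#' background and optional Gaussian read noise. The default z spacing of 2 um
#' matches standard confocal acquisition of cleared nerves.
#'
#' @param pixel_size_xy lateral pixel size (um).
#' @param z_spacing axial slice spacing (um, default 2).
#' @param psf_sigma lateral Gaussian PSF SD (um); 0 disables blurring.
#' @param psf_sigma_z axial PSF SD (um); defaults to 3 x `psf_sigma`, the
#'   typical confocal axial elongation.
#' @param background constant background intensity (photons).
#' @param photon_scale expected photons per um of axon thickness.
#' @param read_noise_sd Gaussian read noise SD (intensity units).
#' @param shot_noise apply Poisson shot noise (`FALSE` gives the exact
#'   noise-free rendering).
#' @param max_voxels resource cap on the rasterized grid.
#' @param seed integer seed for the noise draws.
#' @return Object of class `imaging_config`.
#' @export
imaging_config <- function(pixel_size_xy = 0.5, z_spacing = 2, psf_sigma = 0.5,
                           psf_sigma_z = NULL, background = 5,
                           photon_scale = 50, read_noise_sd = 0,
                           shot_noise = TRUE, max_voxels = 5e7, seed = 1L) {
  if (is.null(psf_sigma_z)) psf_sigma_z <- 3 * psf_sigma
  if (!is.finite(pixel_size_xy) || pixel_size_xy <= 0) {
    stop("pixel_size_xy must be positive")
  }
  if (!is.finite(z_spacing) || z_spacing <= 0) stop("z_spacing must be positive")
  if (!is.finite(psf_sigma) || psf_sigma < 0) stop("psf_sigma must be >= 0")
  if (!is.finite(psf_sigma_z) || psf_sigma_z < 0) stop("psf_sigma_z must be >= 0")
  structure(list(pixel_size_xy = pixel_size_xy, z_spacing = z_spacing,
                 psf_sigma = psf_sigma, psf_sigma_z = psf_sigma_z,
                 background = background,
                 photon_scale = photon_scale, read_noise_sd = read_noise_sd,
                 shot_noise = isTRUE(shot_noise), max_voxels = max_voxels,
                 seed = as.integer(seed)),
            class = "imaging_config")
}

#' Configuration for whole-mount retina field simulation
#'
#' Emulates randomly sampled fields from the peripheral region of a
#' whole-mount retina: Tuj1-positive cells placed at `cell_density`
#' (`survival_fraction` of it in the injured arm), with Cre and p-S6
#' co-expression drawn per cell at the configured fractions, rendered as
#' Gaussian spots with per-cell intensities plus additive noise.
#'
#' @param field_size field width and height (um).
#' @param n_fields number of fields per retina.
#' @param cell_density Tuj1+ cells per mm^2 in the control arm.
#' @param survival_fraction injured density / control density, in `[0, 1]`.
#' @param cre_fraction probability a Tuj1+ cell is Cre+ (AAV transduction).
#' @param ps6_fraction probability a Tuj1+ cell is p-S6+.
#' @param cell_radius cell body radius (um).
#' @param intensity_mean,intensity_sd per-cell peak intensity distribution
#'   (arbitrary units).
#' @param noise_sd additive Gaussian noise SD.
#' @param background constant background intensity.
#' @param pixel_size pixel size of rendered fields (um).
#' @param max_place_attempts rejection-sampling cap for non-overlapping
#'   placement; exceeding it raises a configuration error.
#' @param seed integer seed.
#' @return Object of class `retina_sim_config`.
#' @export
retina_sim_config <- function(field_size = c(300, 300), n_fields = 15,
                              cell_density = 1000, survival_fraction = 1,
                              cre_fraction = 0.888, ps6_fraction = 0.2,
                              cell_radius = 5, intensity_mean = 100,
                              intensity_sd = 15, noise_sd = 3, background = 10,
                              pixel_size = 1, max_place_attempts = 200L,
                              seed = 1L) {
  for (f in c("cell_density", "cell_radius", "intensity_mean", "pixel_size")) {
    v <- get(f)
    if (!is.finite(v) || v <= 0) stop("config field '", f, "' must be positive")
  }
  for (f in c("survival_fraction", "cre_fraction", "ps6_fraction")) {
    v <- get(f)
    if (!is.finite(v) || v < 0 || v > 1) {
      stop("config field '", f, "' must lie in [0, 1]")
    }
  }
  if (length(field_size) != 2 || any(field_size <= 0)) {
    stop("field_size must be two positive lengths (um)")
  }
  structure(list(field_size = as.numeric(field_size),
                 n_fields = as.integer(n_fields), cell_density = cell_density,
                 survival_fraction = survival_fraction,
                 cre_fraction = cre_fraction, ps6_fraction = ps6_fraction,
                 cell_radius = cell_radius, intensity_mean = intensity_mean,
                 intensity_sd = intensity_sd, noise_sd = noise_sd,
                 background = background, pixel_size = pixel_size,
                 max_place_attempts = as.integer(max_place_attempts),
                 seed = as.integer(seed)),
            class = "retina_sim_config")
}

# per-axon RNG substream: derived from the root seed by counter so that the
# i-th axon's draw does not depend on how many axons precede it
derive_seed <- function(root_seed, counter) {
  as.integer((as.numeric(root_seed) * 48271 + counter * 16807) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}
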