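test_that("zero axons rasterize to pure background", {
  cfg <- nerve_sim_config(n_axons = 0, seed = 1)
  gt <- simulate_nerve(cfg)
  img <- imaging_config(psf_sigma = 0, shot_noise = FALSE, background = 7)
  st <- rasterize_stack(gt, img)
  expect_true(all(st$data == 7))
  noisy <- rasterize_stack(gt, imaging_config(psf_sigma = 0, background = 7,
                                              seed = 2))
  expect_equal(mean(noisy$data), 7, tolerance = 0.1)
})

test_that("noise-free mask matches an independently computed tube rasterization", {
  cfg <- nerve_sim_config(n_axons = 1, tortuosity_sd = 0, p_uturn = 0,
                          branch_rate = 0, p_bulb = 0,
                          gc_ratio_range = c(1, 1.001), seed = 3)
  gt <- simulate_nerve(cfg, lengths = 60)
  img <- imaging_config(pixel_size_xy = 0.5, z_spacing = 1, psf_sigma = 0,
                        shot_noise = FALSE, background = 0)
  st <- rasterize_stack(gt, img)
  mask <- st$data > 0
  # oracle: voxel centre within the tube radius of the axis polyline,
  # with the axial distance taken from the voxel's z slab
  tree <- gt$axons[[1]]
  r <- cfg$shaft_diameter / 2
  dims <- dim(st$data)
  oracle <- array(FALSE, dims)
  for (k in seq_len(dims[3])) for (j in seq_len(dims[2])) {
    py <- st$origin[2] + (j - 1) * st$voxel[2]
    pz <- st$origin[3] + (k - 1) * st$voxel[3]
    for (i in seq_len(dims[1])) {
      px <- st$origin[1] + (i - 1) * st$voxel[1]
      # straight axon along +x at (y0, z0); slab-adjusted z distance
      dy <- py - tree$y[1]
      dz <- max(0, abs(pz - tree$z[1]) - st$voxel[3] / 2)
      xc <- min(max(px, tree$x[1]), max(tree$x))  # clamp onto the segment
      inside_tube <- ((px - xc)^2 + dy^2 + dz^2) <= r^2
      # terminal sphere of the (ratio about 1) tip
      ds2 <- (px - max(tree$x))^2 + dy^2 + dz^2
      inside_sphere <- ds2 <= (gt$labels$true_tip_ratio[1] * r)^2
      oracle[i, j, k] <- inside_tube || inside_sphere
    }
  }
  mismatch <- mean(mask != oracle)
  expect_lt(mismatch, 0.002)  # boundary voxels only
})

test_that("bulb tips widen the mask to the ground-truth width", {
  cfg <- nerve_sim_config(n_axons = 1, tortuosity_sd = 0, p_uturn = 0,
                          branch_rate = 0, p_bulb = 1,
                          bulb_ratio_range = c(5, 5.0001), seed = 4)
  gt <- simulate_nerve(cfg, lengths = 80)
  img <- imaging_config(pixel_size_xy = 0.5, z_spacing = 1, psf_sigma = 0,
                        shot_noise = FALSE, background = 0)
  st <- rasterize_stack(gt, img)
  mask <- st$data > 0
  # distance-transform oracle: maximal width = 2 x max EDT inside the bulb
  dt <- axonreg:::edt3d(as.logical(mask), dim(mask), st$voxel)
  max_width <- 2 * max(dt)
  expect_equal(max_width, 5 * cfg$shaft_diameter,
               tolerance = 2 * img$pixel_size_xy / (5 * cfg$shaft_diameter))
})

test_that("rasterization is deterministic per seed and capped in size", {
  cfg <- nerve_sim_config(n_axons = 2, seed = 5, nerve_radius = 100)
  gt <- simulate_nerve(cfg, lengths = c(100, 150))
  img <- imaging_config(seed = 42)
  expect_identical(rasterize_stack(gt, img)$data,
                   rasterize_stack(gt, img)$data)
  tiny <- imaging_config(max_voxels = 100, seed = 42)
  expect_error(rasterize_stack(gt, tiny), "max_voxels")
  expect_s3_class(rasterize_stack(gt, tiny, allow_large = TRUE),
                  "image_stack")
})

test_that("stack TIFF round trip preserves data and metadata", {
  cfg <- nerve_sim_config(n_axons = 1, seed = 6)
  gt <- simulate_nerve(cfg, lengths = 80)
  st <- rasterize_stack(gt, imaging_config(seed = 1))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack_tiff(st, path)
  back <- read_stack_tiff(path)
  expect_equal(dim(back$data), dim(st$data))
  expect_equal(back$voxel, st$voxel)
  expect_equal(back$origin, st$origin)
  # 16-bit quantization error bounded by scale / 2^16
  expect_lt(max(abs(back$data - st$data)), max(st$data) / 65535 * 1.01)
})
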