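test_that("an empty stack counts zero everywhere with the first stop distance", {
  st <- image_stack(array(0, c(400, 40, 4)), voxel = c(1, 1, 2))
  geom <- nerve_geometry(crush_x = 10, extent = 300)
  prof <- count_fibers(project_z(st, 4), geom, interval = 250, threshold = 5)
  expect_true(all(prof$count == 0))
  expect_equal(attr(prof, "stop_distance"), 250)
})

test_that("noise-free straight axons reproduce the ground-truth crossing table", {
  cfg <- nerve_sim_config(n_axons = 3, tortuosity_sd = 0, p_uturn = 0,
                          branch_rate = 0, p_bulb = 0, flat = TRUE,
                          lane_spacing = 20, nerve_radius = 100,
                          nerve_length = 1000, seed = 2)
  gt <- simulate_nerve(cfg, lengths = c(300, 600, 900))
  st <- rasterize_stack(gt, imaging_config(psf_sigma = 0, shot_noise = FALSE,
                                           background = 0))
  pz <- project_z(st, group = dim(st$data)[3])   # one optical section
  prof <- count_fibers(pz, gt$geometry, threshold = 5)
  expect_equal(prof$count[1:3], c(3L, 2L, 1L))
  expect_equal(prof$count, gt$crossing_table$count[seq_len(nrow(prof))])
})

test_that("the literal sum-over-projections rule double counts across sections", {
  # one axon present in two optical-section groups at the 250-um line
  arr <- array(0, c(300, 30, 8))
  arr[, 14:16, 4:5] <- 100   # tube spanning slices 4 (group 1) and 5 (group 2)
  st <- image_stack(arr, voxel = c(1, 1, 2), origin = c(0, 0, 0))
  geom <- nerve_geometry(crush_x = 10, extent = 280)
  prof <- count_fibers(project_z(st, group = 4), geom, interval = 250,
                       threshold = 50)
  expect_equal(prof$count[1], 2L)   # counted once per projection, summed
})

test_that("counting is invariant to rigid translation of stack and geometry", {
  cfg <- nerve_sim_config(n_axons = 4, flat = TRUE, lane_spacing = 20,
                          nerve_radius = 100, p_uturn = 0, branch_rate = 0,
                          p_bulb = 0, tortuosity_sd = 2, seed = 13)
  gt <- simulate_nerve(cfg, lengths = c(300, 420, 510, 640))
  st <- rasterize_stack(gt, imaging_config(psf_sigma = 0, shot_noise = FALSE,
                                           background = 0))
  pz <- project_z(st, group = dim(st$data)[3])
  base <- count_fibers(pz, gt$geometry, threshold = 5)
  shifted <- pz
  shifted$origin[1] <- shifted$origin[1] + 137
  geom2 <- nerve_geometry(crush_x = gt$geometry$crush_x + 137,
                          extent = gt$geometry$extent)
  moved <- count_fibers(shifted, geom2, threshold = 5)
  expect_equal(moved$count, base$count)
})

test_that("adding an axon never decreases any distance count", {
  lens <- c(300, 420, 510, 640)
  counts <- list()
  for (n in 3:4) {
    cfg <- nerve_sim_config(n_axons = n, flat = TRUE, lane_spacing = 20,
                            nerve_radius = 100, p_uturn = 0, branch_rate = 0,
                            p_bulb = 0, tortuosity_sd = 2, seed = 13)
    gt <- simulate_nerve(cfg, lengths = lens[seq_len(n)])
    st <- rasterize_stack(gt, imaging_config(psf_sigma = 0,
                                             shot_noise = FALSE,
                                             background = 0))
    pz <- project_z(st, group = dim(st$data)[3])
    prof <- count_fibers(pz, gt$geometry, threshold = 5)
    counts[[as.character(n)]] <- prof$count[1:3]
  }
  expect_true(all(counts[["4"]] >= counts[["3"]]))
})

test_that("a crush plane outside the image is a geometry error", {
  st <- image_stack(array(0, c(50, 10, 2)), c(1, 1, 2))
  geom <- nerve_geometry(crush_x = 500, extent = 100)
  expect_error(count_fibers(project_z(st, 2), geom, threshold = 1),
               "outside")
})
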