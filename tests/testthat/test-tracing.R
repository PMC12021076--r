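make_fixture_stack <- function(lengths, seed = 3, lane_spacing = 30,
                               px = 0.5, tortuosity = 0) {
  cfg <- nerve_sim_config(n_axons = length(lengths),
                          tortuosity_sd = tortuosity, p_uturn = 0,
                          branch_rate = 0, p_bulb = 0,
                          gc_ratio_range = c(1, 1.001),
                          shaft_diameter = 1.2, flat = TRUE,
                          lane_spacing = lane_spacing,
                          nerve_radius = lane_spacing * length(lengths),
                          seed = seed)
  gt <- simulate_nerve(cfg, lengths = lengths)
  st <- rasterize_stack(gt, imaging_config(pixel_size_xy = px, psf_sigma = 0,
                                           shot_noise = FALSE,
                                           background = 0))
  list(gt = gt, st = st)
}

test_that("binarize obeys its method contracts", {
  zeros <- image_stack(array(0, c(20, 20, 3)), voxel = c(1, 1, 2))
  m <- binarize(zeros, "fixed", threshold = 10)
  expect_equal(sum(m$data), 0)
  expect_equal(m$method, "fixed")
  expect_error(binarize(zeros, "otsu"), "constant")

  fx <- make_fixture_stack(100)
  # monotone: a lower threshold yields a superset mask
  lo <- binarize(fx$st, "fixed", threshold = 1)
  hi <- binarize(fx$st, "fixed", threshold = 45)
  expect_true(all(lo$data[hi$data]))
  expect_gt(sum(lo$data), sum(hi$data))
  # percentile and background record their realized thresholds
  expect_true(is.finite(binarize(fx$st, "percentile", 0.99)$threshold))
  expect_true(binarize(fx$st, "background")$threshold > 0)
})

test_that("a straight noise-free tube traces to one accurate tree", {
  fx <- make_fixture_stack(300)
  mask <- binarize(fx$st, "fixed", threshold = 1)
  tr <- trace_axons(mask, fx$gt$geometry)
  expect_length(tr$trees, 1)
  expect_equal(tree_length(tr$trees[[1]]), 300,
               tolerance = 2 * fx$st$voxel[1] / 300)
  expect_length(tree_branch_points(tr$trees[[1]]), 0)
})

test_that("two parallel non-touching tubes trace to exactly two trees", {
  fx <- make_fixture_stack(c(200, 250))
  tr <- trace_axons(binarize(fx$st, "fixed", threshold = 1),
                    fx$gt$geometry)
  expect_length(tr$trees, 2)
})

test_that("branch tips are recovered exactly on noise-free rasterizations", {
  cfg <- nerve_sim_config(n_axons = 6, branch_rate = 2, branch_max_len = 60,
                          p_uturn = 0, p_bulb = 0, tortuosity_sd = 3,
                          flat = TRUE, lane_spacing = 55, nerve_radius = 400,
                          length_scale = 250, min_length = 150, seed = 31)
  gt <- simulate_nerve(cfg)
  st <- rasterize_stack(gt, imaging_config(psf_sigma = 0, shot_noise = FALSE,
                                           background = 0))
  tr <- trace_axons(binarize(st, "fixed", threshold = 1), gt$geometry)
  expect_length(tr$trees, 6)
  expect_equal(sum(vapply(tr$trees, function(t) length(tree_tips(t)),
                          integer(1))),
               sum(gt$labels$n_tips))
})

test_that("masks with no crush-plane component give an empty result with warning", {
  fx <- make_fixture_stack(150)
  mask <- binarize(fx$st, "fixed", threshold = 1)
  # excise everything within 40 um of the crush plane
  cut_col <- ceiling((40 - fx$st$origin[1]) / fx$st$voxel[1])
  mask$data[seq_len(cut_col), , ] <- FALSE
  expect_warning(tr <- trace_axons(mask, fx$gt$geometry), "crush")
  expect_length(tr$trees, 0)
  empty <- binarize(image_stack(array(0, c(10, 10, 2)), c(1, 1, 2)),
                    "fixed", threshold = 1)
  expect_error(trace_axons(empty, fx$gt$geometry), "empty")
})
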