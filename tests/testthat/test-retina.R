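sim_one_field <- function(seed = 5, density = 1200, ...) {
  cfg <- retina_sim_config(field_size = c(300, 300), n_fields = 1,
                           cell_density = density, seed = seed, ...)
  list(cfg = cfg, field = simulate_retina_pair(cfg)$control[[1]])
}

test_that("cell detection counts well-separated cells accurately", {
  fx <- sim_one_field(seed = 5, density = 1300)  # about 117 cells expected
  truth_n <- nrow(fx$field$cells)
  det <- detect_cells(fx$field$channels$tuj1, fx$field$pixel_size,
                      fx$cfg$cell_radius)
  expect_lte(abs(nrow(det) - truth_n), 2)

  # doubling all intensities leaves detections unchanged
  det2 <- detect_cells(fx$field$channels$tuj1 * 2, fx$field$pixel_size,
                       fx$cfg$cell_radius)
  expect_equal(nrow(det2), nrow(det))
  expect_equal(det2$x, det$x, tolerance = 1e-6)

  # empty field: no detections; constant field: degenerate error
  empty <- matrix(stats::rnorm(200 * 200, 10, 2), 200, 200)
  expect_equal(nrow(detect_cells(empty, 1, 5)), 0)
  expect_error(detect_cells(matrix(7, 50, 50), 1, 5), "degenerate")
})

test_that("channel matching is greedy, one-to-one and distance-capped", {
  a <- data.frame(x = c(10, 50, 90), y = c(10, 50, 90))
  expect_equal(match_channels(a, a)$n_matched, 3L)
  far <- data.frame(x = a$x + 500, y = a$y)
  expect_equal(match_channels(a, far)$n_matched, 0L)
  expect_equal(match_channels(a, a[0, ])$n_matched, 0L)
  # two candidates within radius of one target still match at most once
  b <- data.frame(x = c(11, 12), y = c(10, 10))
  expect_equal(match_channels(a, b, radius = 5)$n_matched, 1L)
})

test_that("double-positive fraction recovers the co-expression parameter", {
  counts_cre <- 0L; counts_all <- 0L
  for (seed in 1:8) {
    cfg <- retina_sim_config(field_size = c(300, 300), n_fields = 4,
                             cell_density = 1300, cre_fraction = 0.888,
                             seed = 40 + seed)
    pair <- simulate_retina_pair(cfg)
    counts_cre <- counts_cre + sum(pair$truth$n_cre)
    counts_all <- counts_all + sum(pair$truth$n_tuj1)
  }
  lo <- stats::qbinom(0.005, counts_all, 0.888)
  hi <- stats::qbinom(0.995, counts_all, 0.888)
  expect_true(counts_cre >= lo && counts_cre <= hi)
})

test_that("survival rate arithmetic and invariances hold", {
  x <- c(120, 130, 110)
  expect_equal(as.numeric(survival_rate(x, x)), 100)
  expect_equal(as.numeric(survival_rate(400, 2000)), 20)
  # invariant to field ordering and splitting with fixed totals
  expect_equal(as.numeric(survival_rate(c(250, 150), c(900, 1100))),
               as.numeric(survival_rate(400, 2000)))
  expect_error(survival_rate(10, 0), "zero")
  expect_error(survival_rate(numeric(0), 10), "at least one")
  high <- survival_rate(150, 100)
  expect_true(attr(high, "flag_high"))
})

test_that("marker fractions are exact percentages with validated inputs", {
  expect_equal(marker_fraction(0, 100), 0)
  expect_equal(marker_fraction(50, 200), 25)
  expect_error(marker_fraction(5, 0), "positive")
  expect_error(marker_fraction(201, 200), "exceeds")
})

test_that("relative intensity is ratio-correct and offset invariant", {
  ctrl <- c(90, 100, 110)
  expect_equal(relative_intensity(ctrl, ctrl)$relative, 1.0)
  expect_equal(relative_intensity(ctrl * 2, ctrl)$relative, 2.0)
  expect_error(relative_intensity(ctrl, c(0, 0)), "zero")
  # simulated 2x condition recovered within 5 percent through detection
  fx <- sim_one_field(seed = 9, density = 900)
  det1 <- detect_cells(fx$field$channels$tuj1, 1, fx$cfg$cell_radius)
  det2 <- detect_cells(fx$field$channels$tuj1 * 2, 1, fx$cfg$cell_radius)
  rel <- relative_intensity(det2$mean_intensity, det1$mean_intensity)
  expect_equal(rel$relative, 2, tolerance = 0.05)
  # constant offset on both images cancels after background subtraction
  det3 <- detect_cells(fx$field$channels$tuj1 + 50, 1, fx$cfg$cell_radius)
  rel2 <- relative_intensity(det3$mean_intensity, det1$mean_intensity)
  expect_equal(rel2$relative, 1, tolerance = 0.02)
})

test_that("survival estimation is unbiased over repeated simulations", {
  ests <- numeric(0)
  for (seed in 1:50) {
    cfg <- retina_sim_config(field_size = c(200, 200), n_fields = 6,
                             cell_density = 1200, survival_fraction = 0.5,
                             seed = 600 + seed)
    pair <- simulate_retina_pair(cfg)
    inj <- pair$truth$n_tuj1[pair$truth$arm == "injured"]
    ctl <- pair$truth$n_tuj1[pair$truth$arm == "control"]
    ests <- c(ests, as.numeric(survival_rate(inj, ctl)))
  }
  expect_lt(abs(mean(ests) - 50), 2)
})
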