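test_that("length statistics follow the top-k rule with deterministic ties", {
  lens <- seq(100, 700, by = 100)
  trees <- lapply(lens, make_straight_tree)
  res <- axon_lengths(trees, k = 5)
  expect_equal(res$per_axon_lengths, lens)
  expect_equal(res$top_k_mean, 500)   # mean of the 5 largest: 300..700

  expect_warning(single <- axon_lengths(list(make_straight_tree(500)), k = 5),
                 "top-5")
  expect_equal(single$top_k_mean, 500)
  expect_equal(single$k_used, 1L)
  expect_error(axon_lengths(list()), "no axons")

  # removing the longest axon never increases the top-5 mean
  res6 <- axon_lengths(trees[-7], k = 5)
  expect_lte(res6$top_k_mean, res$top_k_mean)
})

test_that("simulated lengths agree with the generator to within 1 percent", {
  gt <- simulate_nerve(nerve_sim_config(n_axons = 10, nerve_radius = 120,
                                        tortuosity_sd = 6, seed = 17))
  res <- axon_lengths(gt$axons, k = 5)
  expect_equal(res$per_axon_lengths, gt$labels$length_um, tolerance = 0.01)
})

test_that("tip classification is strict at the threshold", {
  expect_equal(classify_tip(c(3.9, 4, 4.0001, 7)),
               c("growth_cone", "growth_cone", "retraction_bulb",
                 "retraction_bulb"))
})

test_that("tip morphometry recovers ground-truth ratios on noise-free masks", {
  imaging <- imaging_config(pixel_size_xy = 0.25, z_spacing = 1,
                            psf_sigma = 0, shot_noise = FALSE,
                            background = 0)
  for (ratio in c(1, 2, 5, 8)) {
    bulb <- ratio > 4
    cfg <- nerve_sim_config(
      n_axons = 1, tortuosity_sd = 0, p_uturn = 0, branch_rate = 0,
      p_bulb = as.numeric(bulb),
      bulb_ratio_range = c(max(ratio, 4.01), max(ratio, 4.01) + 0.001),
      gc_ratio_range = c(min(ratio, 3.98), min(ratio, 3.98) + 0.001),
      seed = 2)
    gt <- simulate_nerve(cfg, lengths = 80)
    mask <- binarize(rasterize_stack(gt, imaging), "fixed",
                     threshold = 1e-6)
    tm <- measure_tip(gt$axons[[1]], mask)
    expect_equal(tm$ratio, gt$labels$true_tip_ratio, tolerance = 0.2)
    expect_equal(tm$klass,
                 if (bulb) "retraction_bulb" else "growth_cone")
  }
})

test_that("a uniform tube measures ratio about 1 and short axons error", {
  cfg <- nerve_sim_config(n_axons = 1, tortuosity_sd = 0, p_uturn = 0,
                          branch_rate = 0, p_bulb = 0,
                          gc_ratio_range = c(1, 1.001), seed = 2)
  gt <- simulate_nerve(cfg, lengths = 80)
  mask <- binarize(rasterize_stack(gt, imaging_config(
    pixel_size_xy = 0.25, z_spacing = 1, psf_sigma = 0,
    shot_noise = FALSE, background = 0)), "fixed", threshold = 1e-6)
  tm <- measure_tip(gt$axons[[1]], mask)
  expect_equal(tm$ratio, 1, tolerance = 0.15)
  expect_equal(tm$klass, "growth_cone")
  short <- simulate_nerve(cfg, lengths = 30)
  expect_error(measure_tip(short$axons[[1]], mask), "too short")
})

test_that("the U-turn detector reads terminal angles as defined", {
  straight <- make_straight_tree(300)
  res <- detect_uturn(straight, c(1, 0, 0))
  expect_equal(res$angle_deg, 0)
  expect_false(res$is_uturn)

  turned <- make_uturn_tree()
  res2 <- detect_uturn(turned, c(1, 0, 0))
  expect_equal(res2$angle_deg, 180)
  expect_true(res2$is_uturn)
  expect_equal(count_reversal_events(turned), 1L)
  expect_equal(count_reversal_events(straight), 0L)

  expect_error(detect_uturn(make_straight_tree(10), direction_window = 20),
               "shorter")
})

test_that("trajectory metrics follow the per-axon accounting rules", {
  straight20 <- lapply(seq(100, 2000, by = 100), make_straight_tree)
  tm <- trajectory_metrics(straight20, selection = "top_20_longest")
  expect_equal(tm$n_axons_analyzed, 20L)
  expect_equal(tm$uturn_rate, 0)
  expect_equal(tm$branching_index, 1.0)

  # one forked tree with 3 tips among 20 -> 22 tips, index 1.1
  three_tip <- make_forked_tree(trunk = 2100, branch = 100)
  extra <- axon_tree(rbind(three_tip, data.frame(
    id = max(three_tip$id) + 1L, parent = three_tip$id[3],
    x = three_tip$x[3] + 10, y = 40, z = 0, radius = 1)))
  expect_length(tree_tips(extra), 3)
  tm2 <- trajectory_metrics(c(straight20[-1], list(extra)),
                            selection = "top_20_longest")
  expect_equal(tm2$tip_count, 22L)
  expect_equal(tm2$branching_index, 1.1)

  expect_warning(trajectory_metrics(straight20[1:5],
                                    selection = "top_20_longest"),
                 "fewer than 20")
})

test_that("the mean recovered U-turn rate converges to p_uturn", {
  rates <- numeric(0)
  for (seed in 1:50) {
    gt <- simulate_nerve(nerve_sim_config(n_axons = 20, p_uturn = 0.5,
                                          branch_rate = 0,
                                          nerve_radius = 150,
                                          seed = 700 + seed))
    tm <- trajectory_metrics(gt$axons, selection = "all_in_region")
    rates <- c(rates, tm$uturn_rate)
  }
  expect_lt(abs(mean(rates) - 0.5), 0.05)
})

test_that("sciatic QC excludes nerves below the minimum axon count", {
  fifteen <- lapply(rep(1000, 15), make_straight_tree)
  res <- sciatic_regeneration(fifteen)
  expect_true(res$qc_pass)
  expect_equal(res$mean_length, 1000)

  expect_warning(fail <- sciatic_regeneration(fifteen[1:14]), "QC")
  expect_false(fail$qc_pass)
  expect_null(fail$mean_length)

  # simulated sciatic set recovers generator lengths within 1 percent
  gt <- simulate_nerve(nerve_sim_config(n_axons = 16, flat = TRUE,
                                        lane_spacing = 20,
                                        nerve_radius = 200, seed = 19))
  sc <- sciatic_regeneration(gt$axons)
  expect_true(sc$qc_pass)
  expect_equal(mean(sc$per_axon_lengths), mean(gt$labels$length_um),
               tolerance = 0.01)
})

test_that("chiasm fate classification matches generator labels exactly", {
  lm <- chiasm_landmarks(octz_x = 500, tract_x = 900, midline_y = 100)
  cfg <- nerve_sim_config(n_axons = 80, nerve_length = 1200,
                          nerve_radius = 150, seed = 23)
  gt <- simulate_chiasm(cfg, lm)
  ft <- classify_chiasm_fates(gt$axons, gt$geometry)
  expect_identical(unname(attr(ft, "per_axon")), gt$labels$fate)
  expect_equal(sum(ft$fraction), 1)
  expect_equal(sum(ft$count), 80L)
  expect_error(classify_chiasm_fates(gt$axons, nerve_geometry()),
               "landmarks")
})
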