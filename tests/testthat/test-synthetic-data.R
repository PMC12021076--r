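test_that("config validation enforces the documented invariants", {
  expect_error(nerve_sim_config(length_scale = -1), "positive")
  expect_error(nerve_sim_config(p_uturn = 1.5), "\\[0, 1\\]")
  expect_error(nerve_sim_config(bulb_ratio_range = c(3, 6)), "above")
  expect_error(nerve_sim_config(gc_ratio_range = c(2, 5)), "below")
  expect_error(imaging_config(pixel_size_xy = 0), "positive")
  expect_error(retina_sim_config(survival_fraction = 2), "\\[0, 1\\]")
})

test_that("degenerate straight-growth case yields straight rays with clean labels", {
  cfg <- nerve_sim_config(n_axons = 8, tortuosity_sd = 0, p_uturn = 0,
                          branch_rate = 0, nerve_radius = 120, seed = 5)
  gt <- simulate_nerve(cfg)
  expect_length(gt$axons, 8)
  expect_false(any(gt$labels$uturn))
  expect_equal(sum(gt$labels$n_tips), 8)
  for (tree in gt$axons) {
    # straight ray along +x: y and z constant
    expect_lt(max(abs(tree$y - tree$y[1])), 1e-9)
    expect_lt(max(abs(tree$z - tree$z[1])), 1e-9)
  }
})

test_that("fixed-length fixture reproduces the 3/2/1 crossing table", {
  cfg <- nerve_sim_config(n_axons = 3, tortuosity_sd = 0, p_uturn = 0,
                          branch_rate = 0, nerve_length = 1000, seed = 7)
  gt <- simulate_nerve(cfg, lengths = c(300, 600, 900))
  expect_equal(gt$crossing_table$count[1:4], c(3L, 2L, 1L, 0L))
  expect_equal(gt$crossing_table$distance_um[1:3], c(250, 500, 750))
})

test_that("crossing table equals the brute-force intersection oracle", {
  for (seed in 1:4) {
    cfg <- nerve_sim_config(n_axons = 25, p_uturn = 0.2, branch_rate = 0.5,
                            tortuosity_sd = 5, nerve_radius = 250,
                            length_scale = 350, seed = seed)
    gt <- simulate_nerve(cfg)
    for (j in seq_len(nrow(gt$crossing_table))) {
      expect_identical(gt$crossing_table$count[j],
                       oracle_crossings(gt$axons,
                                        gt$crossing_table$distance_um[j]))
    }
  }
})

test_that("identical seeds reproduce identical ground truth; different seeds differ", {
  cfg <- nerve_sim_config(n_axons = 10, seed = 11)
  a <- simulate_nerve(cfg)
  b <- simulate_nerve(cfg)
  expect_identical(a$labels, b$labels)
  for (i in seq_along(a$axons)) expect_identical(a$axons[[i]], b$axons[[i]])
  c <- simulate_nerve(nerve_sim_config(n_axons = 10, seed = 12))
  expect_false(isTRUE(all.equal(a$axons[[1]]$y, c$axons[[1]]$y)))
})

test_that("per-axon substreams are counter-derived: adding axons keeps earlier ones", {
  a <- simulate_nerve(nerve_sim_config(n_axons = 5, seed = 9))
  b <- simulate_nerve(nerve_sim_config(n_axons = 9, seed = 9))
  for (i in 1:5) {
    expect_identical(a$axons[[i]][, c("x", "y", "z")],
                     b$axons[[i]][, c("x", "y", "z")])
  }
})

test_that("U-turn labels are geometrically consistent and converge to p_uturn", {
  hits <- 0; total <- 0
  rates <- numeric(0)
  for (seed in 1:50) {
    cfg <- nerve_sim_config(n_axons = 20, p_uturn = 0.3, branch_rate = 0,
                            nerve_radius = 150, seed = 100 + seed)
    gt <- simulate_nerve(cfg)
    flags <- vapply(gt$axons,
                    function(t) detect_uturn(t, c(1, 0, 0))$is_uturn,
                    logical(1))
    expect_identical(flags, gt$labels$uturn)
    hits <- hits + sum(gt$labels$uturn); total <- total + 20
    rates <- c(rates, mean(gt$labels$uturn))
  }
  ci <- stats::binom.test(hits, total, 0.3)$conf.int
  expect_true(ci[1] <= 0.3 && 0.3 <= ci[2] ||
                abs(hits / total - 0.3) < 0.05)
})

test_that("ground-truth tip ratios never straddle the classification threshold", {
  for (seed in 1:10) {
    gt <- simulate_nerve(nerve_sim_config(n_axons = 30, nerve_radius = 250,
                                          seed = seed))
    bulbs <- gt$labels$tip_class == "retraction_bulb"
    expect_true(all(gt$labels$true_tip_ratio[bulbs] > 4))
    expect_true(all(gt$labels$true_tip_ratio[!bulbs] < 4))
  }
})

test_that("chiasm simulation places terminals in their fate regions", {
  lm <- chiasm_landmarks(octz_x = 500, tract_x = 900, midline_y = 100)
  cfg <- nerve_sim_config(n_axons = 50, nerve_length = 1200,
                          nerve_radius = 150, seed = 3)
  # all mass on pre_chiasmic: every terminal proximal to the OCTZ
  gt <- simulate_chiasm(cfg, lm, fate_probs = c(1, 0, 0, 0))
  tips_x <- vapply(gt$axons, function(t) {
    p <- tree_main_path(t); t$x[match(p[length(p)], t$id)]
  }, numeric(1))
  expect_true(all(tips_x < lm$octz_x))

  # mixed fates: empirical counts within exact binomial 99% bounds
  cfg2 <- nerve_sim_config(n_axons = 200, nerve_length = 1200,
                           nerve_radius = 150, seed = 8)
  probs <- c(pre_chiasmic = 0.6, ipsi_tract = 0.3, contra_tract = 0.05,
             contra_nerve = 0.05)
  gt2 <- simulate_chiasm(cfg2, lm, fate_probs = probs)
  counts <- table(factor(gt2$labels$fate, levels = names(probs)))
  for (f in names(probs)) {
    lo <- stats::qbinom(0.005, 200, probs[[f]])
    hi <- stats::qbinom(0.995, 200, probs[[f]])
    expect_true(counts[[f]] >= lo && counts[[f]] <= hi)
  }

  # contra-nerve axons must cross the midline at least once
  cn <- gt2$axons[gt2$labels$fate == "contra_nerve"]
  for (tree in cn) {
    expect_true(any(tree$y > lm$midline_y) && any(tree$y < lm$midline_y))
  }

  expect_error(simulate_chiasm(cfg, lm, fate_probs = c(0.5, 0.2, 0.1, 0.1)),
               "summing to 1")
})

test_that("retina pair honours survival and co-expression parameters", {
  cfg <- retina_sim_config(field_size = c(500, 500), n_fields = 20,
                           cell_density = 1000, survival_fraction = 1,
                           cre_fraction = 0, seed = 6)
  pair <- simulate_retina_pair(cfg)
  expect_equal(sum(pair$truth$n_cre), 0)
  # survival 1: equal expected counts; totals within Poisson bounds of 5000
  tot <- sum(pair$truth$n_tuj1[pair$truth$arm == "control"])
  expect_true(tot >= stats::qpois(0.005, 5000) &&
                tot <= stats::qpois(0.995, 5000))
  # determinism
  pair2 <- simulate_retina_pair(cfg)
  expect_identical(pair$truth, pair2$truth)
  expect_identical(pair$control[[1]]$channels$tuj1,
                   pair2$control[[1]]$channels$tuj1)
  # overlap-free placement impossible at absurd densities
  expect_error(simulate_retina_pair(
    retina_sim_config(field_size = c(50, 50), cell_density = 2e5,
                      n_fields = 1, seed = 1)), "overlap")
})
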