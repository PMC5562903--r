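test_that("gen_two_group is seeded, calibrated and validated", {
  a <- gen_two_group(5, 5, true_smd = 0, sd = 1, seed = 42)
  b <- gen_two_group(5, 5, true_smd = 0, sd = 1, seed = 42)
  expect_identical(a, b)
  expect_length(a$control, 5)
  expect_error(gen_two_group(5, 5, 0, sd = -1), "sd")
  expect_error(gen_two_group(0, 5, 0, sd = 1), "n_c")
  # large-n consistency: the estimated g sits on the configured truth
  g <- gen_two_group(1e4, 1e4, true_smd = 2, sd = 1, seed = 7)
  expect_equal(hedges_g(g$control, g$treatment), 2, tolerance = 0.05 / 2)
})

test_that("latent-shift calibration inverts the normal dominance curve", {
  expect_equal(calibrate_latent_shift(0), 0)
  expect_equal(calibrate_latent_shift(0.5), 0.9539, tolerance = 1e-4)
  expect_equal(calibrate_latent_shift(-0.5), -calibrate_latent_shift(0.5))
  expect_error(calibrate_latent_shift(1), "unattainable")
  expect_error(calibrate_latent_shift(-1.2), "unattainable")
  # round trip at Monte-Carlo scale: sample delta recovers the target
  set.seed(13)
  for (target in c(-0.62, 0.3, 0.8)) {
    d <- calibrate_latent_shift(target)
    expect_lt(abs(cliffs_delta(rnorm(1e4), rnorm(1e4, d)) - target), 0.02)
  }
})

test_that("trajectories respect the arena, the clock and the pause state", {
  p <- walk_params()
  tr <- gen_trajectory(10, p, seed = 1)
  expect_equal(nrow(tr), 100)
  expect_true(all(diff(tr$t_s) > 0))
  expect_equal(diff(tr$t_s), rep(0.1, 99))
  expect_true(all(tr$x_mm >= 0 & tr$x_mm <= 20))
  expect_true(all(tr$y_mm >= 0 & tr$y_mm <= 22))
  # always paused: the fly never moves and the activity index is zero
  frozen <- gen_trajectory(10, walk_params(pause_probability = 1), seed = 2)
  expect_equal(length(unique(frozen$x_mm)), 1)
  expect_equal(activity_index(frozen), 0)
  # never paused at 10 mm/s: every 0.5 s bin covers well over 1 mm of
  # recorded path (wall reflections can only shave a fraction of a step)
  busy <- gen_trajectory(10, walk_params(pause_probability = 0,
                                         move_speed_mean = 10), seed = 3)
  expect_equal(activity_index(busy), 1)
  # the bin-level guarantee itself, wall-free: constant 2 mm/s straight run
  run <- make_straight_run(1, 1, speed = 2, duration = 10)
  expect_equal(activity_index(run), 1)
  expect_identical(gen_trajectory(5, p, seed = 9), gen_trajectory(5, p, seed = 9))
})

test_that("foraging sessions have the stated epoch structure", {
  s <- gen_snac_session(walk_params(), alcove_bias = 0.3, seed = 4)
  expect_equal(nrow(s$epochs), 6)
  expect_true(all(s$epochs$food_off - s$epochs$food_on <= 100 + 1e-9))
  # inter-epoch interval: next epoch starts 120 s after food-off
  gaps <- s$epochs$start[-1] - s$epochs$food_off[-6]
  expect_equal(gaps, rep(120, 5), tolerance = 1e-6)
  expect_true(all(diff(s$trajectory$t_s) > 0))
  # beeline bias: entry in every epoch, task performance 1
  bee <- gen_snac_session(walk_params(pause_probability = 0), alcove_bias = 1,
                          seed = 5)
  expect_true(all(!is.na(bee$epochs$entry_time)))
  expect_equal(snac_metrics(bee)$task_performance, 1)
  # paused fly far from the alcove: all latencies censored
  still <- gen_snac_session(walk_params(pause_probability = 1),
                            alcove_bias = 0, seed = 6)
  expect_true(all(is.na(still$epochs$entry_time)))
  m <- snac_metrics(still)
  expect_equal(m$entries, 0)
  expect_equal(m$task_performance, 0)
  expect_true(all(is.na(m$per_epoch$time_to_feed)))
  # alcove outside the arena is a geometry error
  expect_error(
    gen_snac_session(walk_params(), alcove = square_alcove(30, 30), seed = 1),
    "geometry"
  )
})

test_that("the assay bundle is deterministic and validates its config", {
  cfg <- scenario_config(drivers = c("TH", "Trh"), n_per_arm = 8, seed = 11)
  b1 <- gen_assay_bundle(cfg)
  b2 <- gen_assay_bundle(cfg)
  for (part in c("cafe", "climbing", "respirometry", "body", "behaviour")) {
    expect_identical(b1[[part]], b2[[part]])
  }
  expect_error(scenario_config(n_per_arm = 0), "n_per_arm")
  expect_error(
    scenario_config(true_smd = c(bogus_metric = 1)),
    "config error"
  )
  bad <- scenario_config(seed = 1)
  bad$metrics$sd[3] <- -1
  expect_error(validate_scenario_config(bad), "must be > 0")
})

test_that("a null bundle at large n produces only negligible estimates", {
  cfg <- scenario_config(drivers = "TH", true_smd = 0, n_per_arm = 1000,
                         seed = 19)
  metrics <- compute_assay_metrics(gen_assay_bundle(cfg))
  effects <- vapply(split(metrics, metrics$metric), function(d) {
    ctl <- d$value[d$condition == "uninduced"]
    trt <- d$value[d$condition == "induced"]
    if (d$metric[1] == "entries") cliffs_delta(ctl, trt) else hedges_g(ctl, trt)
  }, numeric(1))
  expect_lt(max(abs(effects)), 0.1)
})

test_that("per-assay substreams keep other assays stable when one is added", {
  full <- scenario_config(drivers = "TH", n_per_arm = 10, seed = 23)
  smaller <- full
  smaller$metrics <- smaller$metrics[smaller$metrics$metric != "climbing", ]
  smaller$effects <- smaller$effects[smaller$effects$metric != "climbing", ]
  b_full <- gen_assay_bundle(full)
  b_small <- gen_assay_bundle(validate_scenario_config(smaller))
  expect_identical(b_full$respirometry, b_small$respirometry)
  expect_identical(b_full$behaviour, b_small$behaviour)
})
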