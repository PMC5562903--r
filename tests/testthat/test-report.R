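make_estimates <- function(effects, estimators = "g") {
  n <- length(effects)
  tibble::tibble(
    driver = paste0("drv", seq_len(n)),
    metric = "m",
    estimator = rep(estimators, length.out = n),
    effect = effects
  )
}

test_that("emphasis flags follow the strict moderate-effect thresholds", {
  em <- effect_matrix(make_estimates(c(0.51, 0.49, 0.50, -0.51)))
  expect_equal(em$cells$emphasis, c(TRUE, FALSE, FALSE, TRUE))
  # Cliff's delta threshold is 0.47, strict
  ed <- effect_matrix(make_estimates(c(0.47, 0.48, -0.50, 0.33), "delta"))
  expect_equal(ed$cells$emphasis, c(FALSE, TRUE, TRUE, FALSE))
  # missing cells render as a dot and are never emphasised
  miss <- make_estimates(c(NA, 0.9))
  em_miss <- effect_matrix(miss)
  expect_equal(em_miss$cells$emphasis, c(FALSE, TRUE))
  expect_match(format_effect_matrix(em_miss, "md"), "·")
})

test_that("duplicate (driver, metric) cells collide loudly", {
  est <- make_estimates(c(0.1, 0.2))
  est$driver <- "same"
  expect_error(effect_matrix(est), "collision")
})

test_that("the effect matrix round-trips through CSV and JSON", {
  set.seed(99)
  est <- tibble::tibble(
    driver = rep(c("TH", "Trh"), each = 3),
    metric = rep(c("activity", "climbing", "entries"), 2),
    estimator = rep(c("g", "g", "delta"), 2),
    effect = round(rnorm(6), 6),
    delta_raw = round(rnorm(6), 6)
  )
  em <- effect_matrix(est)
  for (ext in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_effect_matrix(em, path)
    back <- read_effect_matrix(path)
    expect_equal(back$cells, em$cells)
  }
  md <- format_effect_matrix(em, "md")
  expect_match(md, "\\| metric \\| TH \\| Trh \\|")
  expect_match(md, "D[+-]") # delta cells carry the distinguishing prefix
})

test_that("run_pipeline produces a full 14 x 5 matrix with provenance", {
  cfg <- scenario_config(n_per_arm = 12, seed = 101)
  run <- run_pipeline(cfg, B = 1000)
  expect_equal(nrow(run$estimates), 14 * 5)
  expect_setequal(unique(run$estimates$driver),
                  c("TH", "Ddc", "Tdc2", "Trh", "NPF"))
  expect_equal(length(run$matrix$metrics), 14)
  expect_equal(length(run$matrix$drivers), 5)
  expect_equal(run$manifest$seed, 101)
  expect_equal(run$manifest$bootstrap_B, 1000L)
  expect_true(nzchar(run$manifest$config_hash))
  # every estimate is traceable: one cell per (driver, metric), CIs bracket
  expect_true(all(run$estimates$ci_low <= run$estimates$effect + 1e-12))
  expect_true(all(run$estimates$ci_high >= run$estimates$effect - 1e-12))
})

test_that("run_pipeline is idempotent for a fixed config and writes outputs", {
  cfg <- scenario_config(drivers = "Tdc2", n_per_arm = 10, seed = 55)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  r1 <- run_pipeline(cfg, out_dir = dir1, B = 1000)
  r2 <- run_pipeline(cfg, out_dir = dir2, B = 1000)
  expect_identical(r1$estimates, r2$estimates)
  expect_identical(readLines(file.path(dir1, "estimates.csv")),
                   readLines(file.path(dir2, "estimates.csv")))
  expect_identical(readLines(file.path(dir1, "effect_matrix.md")),
                   readLines(file.path(dir2, "effect_matrix.md")))
  expect_true(file.exists(file.path(dir1, "manifest.json")))
  man <- jsonlite::fromJSON(file.path(dir1, "manifest.json"))
  expect_equal(man$seed, 55)
})

test_that("config files read back into validated scenarios", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "drivers: [TH, Trh]",
    "true_smd:",
    "  activity: -1.0",
    "  entries: -0.5",
    "n_per_arm: 9",
    "seed: 77"
  ), path)
  cfg <- read_scenario_config(path)
  expect_s3_class(cfg, "scenario_config")
  expect_equal(cfg$drivers, c("TH", "Trh"))
  expect_equal(cfg$seed, 77L)
  expect_true(all(cfg$metrics$n_c == 9))
  eff <- cfg$effects
  expect_equal(unique(eff$true_smd[eff$metric == "activity"]), -1.0)
  expect_equal(unique(eff$true_smd[eff$metric == "time_to_alcove"]), 0)
  # schema violations name the offending key
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("true_smd:", "  made_up_metric: 2"), bad)
  expect_error(read_scenario_config(bad), "made_up_metric")
})

test_that("trajectory and session files round-trip through disk", {
  traj <- gen_trajectory(5, walk_params(), seed = 3)
  tpath <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, tpath)
  expect_equal(read_trajectory_csv(tpath), traj, tolerance = 1e-12)
  s <- gen_snac_session(walk_params(pause_probability = 0.2),
                        alcove_bias = 0.8, n_epochs = 2, epoch_timeout = 20,
                        inter_epoch = 10, seed = 13)
  spath <- file.path(withr::local_tempdir(), "session.json")
  write_snac_session(s, spath)
  back <- read_snac_session(spath)
  expect_equal(back$epochs$food_off, s$epochs$food_off, tolerance = 1e-9)
  expect_equal(back$alcove, s$alcove, ignore_attr = TRUE)
  m1 <- snac_metrics(s)
  m2 <- snac_metrics(back)
  expect_equal(m1$entries, m2$entries)
  expect_equal(m1$per_epoch$distance_mm, m2$per_epoch$distance_mm,
               tolerance = 1e-9)
})
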