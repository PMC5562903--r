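test_that("activity index counts mobile half-second bins", {
  # stationary fly: zero
  still <- make_trajectory(rep(5, 51), rep(5, 51))
  expect_equal(activity_index(still), 0)
  # constant 3 mm/s: every bin moves 1.5 mm
  fast <- make_straight_run(5, 1, speed = 3, duration = 5)
  expect_equal(activity_index(fast), 1)
  # hand-built: 10 complete bins, exactly 4 of them mobile
  # 5 s at 10 Hz; move 0.3 mm per step during bins 1, 4, 7, 10
  mobile_bins <- c(1, 4, 7, 10)
  step_dx <- numeric(50)
  bin_of_step <- floor((0:49) / 5) + 1
  step_dx[bin_of_step %in% mobile_bins] <- 0.3 # 5 steps x 0.3 = 1.5 mm
  x <- cumsum(c(0, step_dx))
  traj <- make_trajectory(x, rep(0, 51))
  expect_equal(activity_index(traj), 0.4)
  # net-displacement variant scores a loop as immobile, path variant mobile
  theta <- seq(0, 2 * pi, length.out = 6)[-6]
  loop <- make_trajectory(rep(0.4 * cos(theta), 2), rep(0.4 * sin(theta), 2))
  expect_equal(activity_index(loop, method = "net"), 0)
  expect_equal(activity_index(loop, method = "path"), 1)
  expect_error(activity_index(make_trajectory(0, 0)), "insufficient data")
})

test_that("activity index never decreases when motion is added to a bin", {
  set.seed(3)
  base <- gen_trajectory(20, walk_params(pause_probability = 0.6,
                                         move_speed_mean = 3), seed = 8)
  ai0 <- activity_index(base)
  boosted <- base
  boosted$x_mm <- boosted$x_mm + cumsum(rep(0.05, nrow(base))) # extra drift
  boosted$x_mm <- pmin(boosted$x_mm, 20)
  expect_gte(activity_index(boosted), ai0)
  expect_gte(ai0, 0)
  expect_lte(ai0, 1)
})

test_that("exclusion filter applies the 200 mm and 10% rules", {
  res <- exclusion_filter(
    distance = c(150, 250, 250, 199.99, 150),
    activity = c(0.50, 0.05, 0.50, 0.10, 0.05)
  )
  expect_equal(res$keep, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(res$exclusion_reason,
               c("distance", "activity", NA, "distance", "distance;activity"))
  # boundary values are kept: the rules are strict inequalities
  edge <- exclusion_filter(distance = c(200, 200), activity = c(0.10, 0.10))
  expect_true(all(edge$keep))
})

test_that("distance_travelled sums Euclidean steps over half-open windows", {
  expect_equal(distance_travelled(make_trajectory(5, 5)), 0)
  two <- make_trajectory(c(0, 3), c(0, 4))
  expect_equal(distance_travelled(two), 5)
  set.seed(5)
  traj <- gen_trajectory(12, walk_params(), seed = 12)
  d_all <- distance_travelled(traj, c(0, 12))
  d_split <- distance_travelled(traj, c(0, 4.03)) +
    distance_travelled(traj, c(4.03, 12))
  expect_equal(d_split, d_all)
  bad <- make_trajectory(c(0, 1), c(0, 1))
  bad$t_s <- c(1, 0)
  expect_error(distance_travelled(bad), "strictly increasing")
})

test_that("snac_metrics extracts entries, latency and path efficiency exactly", {
  alcove <- square_alcove(10, 20, half = 1)
  # straight run up the y axis at 10 mm/s from (10, 4): crosses y = 19 at
  # t = 1.5; debounce makes entry the second inside sample at t = 1.6
  traj <- make_straight_run(10, 4, speed = 10, duration = 3)
  epochs <- tibble::tibble(epoch = 1L, start = 0, food_on = 0, food_off = 3,
                           entry_time = NA, start_x = 10, start_y = 4)
  s <- make_session(traj, epochs, alcove)
  m <- snac_metrics(s)
  expect_equal(m$entries, 1)
  expect_equal(m$task_performance, 1)
  expect_equal(m$per_epoch$time_to_feed, 1.6)
  expect_equal(m$per_epoch$distance_mm, 16)
  expect_equal(m$per_epoch$path_efficiency, 1)

  # dog-leg: out 8 mm along x and back, then straight to the alcove --
  # path length is exactly twice the direct distance
  y_leg <- seq(4, 20, by = 1)
  x_out <- c(seq(10, 18, by = 1), seq(17, 10, by = -1))
  dog <- make_trajectory(c(x_out, rep(10, length(y_leg))),
                         c(rep(4, length(x_out)), y_leg), rate = 10)
  epochs_d <- tibble::tibble(epoch = 1L, start = 0, food_on = 0,
                             food_off = 10, entry_time = NA,
                             start_x = 10, start_y = 4)
  m_d <- snac_metrics(make_session(dog, epochs_d, alcove))
  expect_equal(m_d$per_epoch$path_efficiency, 0.5)

  # never entering: censored epoch
  far <- make_straight_run(2, 2, speed = 0, duration = 3)
  m_far <- snac_metrics(make_session(far, epochs, alcove))
  expect_equal(m_far$entries, 0)
  expect_true(is.na(m_far$per_epoch$time_to_feed))

  # degenerate alcove polygon
  flat <- cbind(x = c(1, 2, 3), y = c(1, 1, 1))
  expect_error(snac_metrics(make_session(traj, epochs, flat)), "degenerate")
})

test_that("session metrics agree with the generator's own entry bookkeeping", {
  s <- gen_snac_session(walk_params(pause_probability = 0.1),
                        alcove_bias = 0.6, seed = 33)
  m <- snac_metrics(s)
  gen_entries <- sum(!is.na(s$epochs$entry_time))
  expect_equal(m$entries, gen_entries)
  ok <- m$per_epoch$entered
  expect_equal(m$per_epoch$time_to_feed[ok],
               s$epochs$entry_time[ok] - s$epochs$food_on[ok])
  expect_true(all(m$per_epoch$path_efficiency[ok] > 0))
  expect_true(all(m$per_epoch$path_efficiency[ok] <= 1))
})
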