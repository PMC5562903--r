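# Synthetic raw-assay generators. Every downstream stage of the pipeline is
# exercised against data with a known ground-truth effect structure, so the
# estimators can be validated by parameter recovery rather than against an
# unavailable reference dataset.

#' Generate one two-group dataset with a known standardized effect
#'
#' Control values are drawn from Normal(baseline, sd) and treatment values
#' from Normal(baseline + true_smd * sd, sd), so the population standardized
#' mean difference is exactly `true_smd`.
#'
#' @param n_c,n_t Group sizes (>= 1).
#' @param true_smd True standardized mean difference (dimensionless).
#' @param sd Common standard deviation in native units (> 0).
#' @param baseline Control-group mean in native units.
#' @param seed Integer seed; identical seeds give identical samples.
#' @return A list with numeric elements `control` and `treatment`.
#' @examples
#' gen_two_group(5, 5, true_smd = 1, seed = 1)
#' @export
gen_two_group <- function(n_c, n_t, true_smd, sd = 1, baseline = 0, seed = NULL) {
  n_c <- check_count(n_c, "n_c")
  n_t <- check_count(n_t, "n_t")
  check_number(true_smd, "true_smd")
  check_number(sd, "sd", lower = 0, strict_lower = TRUE)
  check_number(baseline, "baseline")
  with_seed(seed, list(
    control = stats::rnorm(n_c, baseline, sd),
    treatment = stats::rnorm(n_t, baseline + true_smd * sd, sd)
  ))
}

#' Latent normal shift that attains a target Cliff's delta
#'
#' For X ~ N(0, 1) and Y ~ N(d, 1), Cliff's delta is
#' `2 * P(Y > X) - 1 = 2 * pnorm(d / sqrt(2)) - 1`. Inverting gives
#' `d = sqrt(2) * qnorm((delta + 1) / 2)`: the shift to apply to a latent
#' normal score so that continuous samples exhibit the requested dominance
#' statistic. Used to simulate ordinal metrics (e.g. alcove-entry counts) at
#' a chosen effect size.
#'
#' @param target_delta Target Cliff's delta, strictly inside (-1, 1).
#' @return The latent shift d (dimensionless).
#' @examples
#' calibrate_latent_shift(0.5) # 0.9539
#' @export
calibrate_latent_shift <- function(target_delta) {
  check_number(target_delta, "target_delta")
  if (abs(target_delta) >= 1) {
    stop_invalid("unattainable shift: |target_delta| must be < 1")
  }
  sqrt(2) * stats::qnorm((target_delta + 1) / 2)
}

#' Movement-model parameters for the arena random walk
#'
#' The locomotion model is a two-state (move/pause) correlated random walk:
#' at each sample the fly pauses with probability `pause_probability`,
#' otherwise it steps `move_speed_mean / sample_rate` mm along a heading
#' that persists between steps with angular noise scaled by
#' `1 - heading_persistence`. Walls reflect. The default arena is the
#' 20 x 22 mm chamber of the foraging chip.
#'
#' @param sample_rate Samples per second (Hz).
#' @param move_speed_mean Walking speed while moving (mm/s).
#' @param pause_probability Per-step probability of pausing, in `[0, 1]`.
#' @param heading_persistence Directional persistence in `[0, 1]`; 1 means
#'   the heading never changes, 0 a fully uniform turn each step.
#' @param arena_width,arena_height Arena dimensions (mm).
#' @return A `walk_params` list.
#' @export
walk_params <- function(sample_rate = 10, move_speed_mean = 10,
                        pause_probability = 0.2, heading_persistence = 0.7,
                        arena_width = 20, arena_height = 22) {
  check_number(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  check_number(move_speed_mean, "move_speed_mean", lower = 0)
  check_number(pause_probability, "pause_probability", lower = 0, upper = 1)
  check_number(heading_persistence, "heading_persistence", lower = 0, upper = 1)
  check_number(arena_width, "arena_width", lower = 0, strict_lower = TRUE)
  check_number(arena_height, "arena_height", lower = 0, strict_lower = TRUE)
  structure(list(
    sample_rate = sample_rate, move_speed_mean = move_speed_mean,
    pause_probability = pause_probability,
    heading_persistence = heading_persistence,
    arena_width = arena_width, arena_height = arena_height
  ), class = "walk_params")
}

# One step of the walk. Returns c(x, y, heading). Reflective walls: the
# position is folded back into the box and the heading mirrored.
walk_step <- function(x, y, heading, moving, params, dt, target = NULL,
                      bias = 0) {
  if (!moving) return(c(x, y, heading))
  turn_sd <- pi * (1 - params$heading_persistence)
  heading <- heading + stats::rnorm(1, 0, turn_sd)
  if (bias > 0 && !is.null(target)) {
    to_target <- atan2(target[2] - y, target[1] - x)
    # blend unit vectors; bias = 1 is a deterministic beeline
    vx <- (1 - bias) * cos(heading) + bias * cos(to_target)
    vy <- (1 - bias) * sin(heading) + bias * sin(to_target)
    if (vx != 0 || vy != 0) heading <- atan2(vy, vx)
  }
  step <- params$move_speed_mean * dt
  x <- x + step * cos(heading)
  y <- y + step * sin(heading)
  w <- params$arena_width
  h <- params$arena_height
  if (x < 0) { x <- -x; heading <- pi - heading }
  if (x > w) { x <- 2 * w - x; heading <- pi - heading }
  if (y < 0) { y <- -y; heading <- -heading }
  if (y > h) { y <- 2 * h - y; heading <- -heading }
  unname(c(x, y, heading))
}

#' Simulate an arena trajectory
#'
#' Runs the two-state correlated random walk of [walk_params()] for
#' `duration` seconds and returns time-stamped positions, the same record a
#' video-tracking system would emit.
#'
#' @param duration Length of the recording (s, > 0).
#' @param params A [walk_params()] object.
#' @param seed Integer seed.
#' @param start Optional `c(x, y)` start position (mm); default is the arena
#'   centre.
#' @return A tibble with columns `t_s`, `x_mm`, `y_mm`.
#' @examples
#' traj <- gen_trajectory(10, walk_params(), seed = 1)
#' @export
gen_trajectory <- function(duration, params = walk_params(), seed = NULL,
                           start = NULL) {
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  stopifnot(inherits(params, "walk_params"))
  if (is.null(start)) {
    start <- c(params$arena_width / 2, params$arena_height / 2)
  }
  n <- max(1L, floor(duration * params$sample_rate))
  dt <- 1 / params$sample_rate
  with_seed(seed, {
    x <- numeric(n)
    y <- numeric(n)
    x[1] <- start[1]
    y[1] <- start[2]
    heading <- stats::runif(1, -pi, pi)
    if (n > 1) {
      moving <- stats::runif(n - 1) >= params$pause_probability
      for (i in 2:n) {
        s <- walk_step(x[i - 1], y[i - 1], heading, moving[i - 1], params, dt)
        x[i] <- s[1]; y[i] <- s[2]; heading <- s[3]
      }
    }
    tibble::tibble(t_s = (seq_len(n) - 1) * dt, x_mm = x, y_mm = y)
  })
}

#' Default feeding-alcove polygon
#'
#' A 3 x 1.5 mm rectangular alcove centred on the top wall of the arena.
#'
#' @param params A [walk_params()] object giving the arena size.
#' @return A two-column matrix of polygon vertices (mm).
#' @export
default_alcove <- function(params = walk_params()) {
  cx <- params$arena_width / 2
  h <- params$arena_height
  cbind(
    x = c(cx - 1.5, cx + 1.5, cx + 1.5, cx - 1.5),
    y = c(h - 1.5, h - 1.5, h, h)
  )
}

polygon_centroid <- function(poly) unname(colMeans(poly))

check_alcove <- function(alcove, params) {
  if (!is.matrix(alcove) || ncol(alcove) != 2 || nrow(alcove) < 3) {
    stop_invalid("geometry error: alcove must be a polygon matrix with >= 3 vertices")
  }
  if (any(alcove[, 1] < 0 | alcove[, 1] > params$arena_width |
            alcove[, 2] < 0 | alcove[, 2] > params$arena_height)) {
    stop_invalid("geometry error: alcove polygon lies outside the arena")
  }
  invisible(alcove)
}

#' Simulate a foraging-chip session with timed food epochs
#'
#' Food is presented for up to `epoch_timeout` seconds per epoch (default
#' 100 s) over `n_epochs` epochs (default 6) separated by `inter_epoch`
#' seconds (default 120 s). Within an epoch the food is withdrawn at the
#' first alcove entry (two consecutive samples inside the alcove polygon)
#' or at the timeout, whichever comes first. `alcove_bias` > 0 biases the
#' walk heading toward the alcove while food is on, producing flies that
#' find the food; `alcove_bias = 1` is a deterministic beeline.
#'
#' @param walk A [walk_params()] object.
#' @param alcove_bias Heading bias toward the alcove in `[0, 1]`.
#' @param n_epochs Number of food epochs (>= 1).
#' @param epoch_timeout Maximum food-on duration per epoch (s).
#' @param inter_epoch Interval between food-off and the next epoch (s).
#' @param seed Integer seed.
#' @param alcove Alcove polygon matrix (mm); default [default_alcove()].
#' @return A `snac_session` list: `trajectory` (tibble), `epochs` (tibble
#'   with `epoch`, `start`, `food_on`, `food_off`, `entry_time`,
#'   `start_x`, `start_y`), `alcove`, `params`.
#' @export
gen_snac_session <- function(walk = walk_params(), alcove_bias = 0.25,
                             n_epochs = 6, epoch_timeout = 100,
                             inter_epoch = 120, seed = NULL,
                             alcove = default_alcove(walk)) {
  stopifnot(inherits(walk, "walk_params"))
  n_epochs <- check_count(n_epochs, "n_epochs")
  check_number(epoch_timeout, "epoch_timeout", lower = 0, strict_lower = TRUE)
  check_number(inter_epoch, "inter_epoch", lower = 0)
  check_number(alcove_bias, "alcove_bias", lower = 0, upper = 1)
  check_alcove(alcove, walk)
  target <- polygon_centroid(alcove)
  dt <- 1 / walk$sample_rate
  n_max <- ceiling(n_epochs * (epoch_timeout + inter_epoch) / dt) + n_epochs + 2L
  with_seed(seed, {
    # start away from the alcove so the first epoch is a real search
    x <- walk$arena_width / 2
    y <- walk$arena_height / 4
    heading <- stats::runif(1, -pi, pi)
    ts <- xs <- ys <- numeric(n_max)
    k <- 0L
    record <- function() {
      k <<- k + 1L
      ts[k] <<- t_now; xs[k] <<- x; ys[k] <<- y
    }
    advance <- function(bias = 0) {
      moving <- stats::runif(1) >= walk$pause_probability
      s <- walk_step(x, y, heading, moving, walk, dt,
                     target = target, bias = bias)
      x <<- s[1]; y <<- s[2]; heading <<- s[3]
      t_now <<- t_now + dt
    }
    epochs <- vector("list", n_epochs)
    t_now <- 0
    for (ep in seq_len(n_epochs)) {
      food_on <- t_now
      start_x <- x
      start_y <- y
      inside_run <- 0L
      entry_time <- NA_real_
      n_steps <- floor(epoch_timeout / dt + 1e-9)
      for (i in seq_len(n_steps)) {
        record()
        inside_run <- if (point_in_polygon(cbind(x, y), alcove)) {
          inside_run + 1L
        } else 0L
        if (inside_run >= 2L) {
          entry_time <- t_now
          advance(bias = alcove_bias)
          break
        }
        advance(bias = alcove_bias)
      }
      food_off <- if (is.na(entry_time)) food_on + epoch_timeout else entry_time
      epochs[[ep]] <- tibble::tibble(
        epoch = ep, start = food_on, food_on = food_on, food_off = food_off,
        entry_time = entry_time, start_x = start_x, start_y = start_y
      )
      # inter-epoch interval: unbiased wandering, food off
      if (ep < n_epochs) {
        gap_end <- food_off + inter_epoch
        while (t_now < gap_end - dt / 2) {
          record()
          advance()
        }
        t_now <- gap_end
      }
    }
    record()
    structure(list(
      trajectory = tibble::tibble(t_s = ts[seq_len(k)], x_mm = xs[seq_len(k)],
                                  y_mm = ys[seq_len(k)]),
      epochs = dplyr::bind_rows(epochs),
      alcove = alcove,
      params = walk
    ), class = "snac_session")
  })
}
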