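# Fixture builders and independent oracles shared across the suite.

# Brute-force all-pairs enumeration of Cliff's delta, independent of the
# rank-based implementation.
oracle_cliffs_delta <- function(control, treatment) {
  mean(sign(outer(treatment, control, "-")))
}

# A trajectory at uniform sample rate from explicit positions.
make_trajectory <- function(x, y, rate = 10) {
  tibble::tibble(t_s = (seq_along(x) - 1) / rate, x_mm = x, y_mm = y)
}

# A straight run at constant speed (mm/s) along +y starting at (x0, y0).
make_straight_run <- function(x0, y0, speed, duration, rate = 10) {
  n <- duration * rate + 1
  make_trajectory(rep(x0, n), y0 + speed * (seq_len(n) - 1) / rate, rate)
}

# Hand-built foraging session: one epoch, explicit trajectory and alcove.
make_session <- function(traj, epochs, alcove,
                         params = walk_params()) {
  structure(list(trajectory = traj, epochs = epochs, alcove = alcove,
                 params = params), class = "snac_session")
}

square_alcove <- function(cx, cy, half = 1) {
  cbind(x = cx + c(-half, half, half, -half),
        y = cy + c(-half, -half, half, half))
}
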