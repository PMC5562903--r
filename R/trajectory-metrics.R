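# Trajectory-derived behavioural metrics: activity index, travelled
# distance, and the foraging-session metrics (alcove entries, latency, path
# efficiency), with the standard exclusion rules.

check_trajectory <- function(traj) {
  need <- c("t_s", "x_mm", "y_mm")
  if (!is.data.frame(traj) || !all(need %in% names(traj))) {
    stop_invalid("malformed trajectory: expected columns t_s, x_mm, y_mm")
  }
  if (nrow(traj) < 1) stop_invalid("malformed trajectory: no samples")
  if (any(!is.finite(traj$t_s)) || any(!is.finite(traj$x_mm)) ||
        any(!is.finite(traj$y_mm))) {
    stop_invalid("malformed trajectory: non-finite values")
  }
  if (nrow(traj) > 1 && any(diff(traj$t_s) <= 0)) {
    stop_invalid("malformed trajectory: timestamps must be strictly increasing")
  }
  traj
}

# Per-step Euclidean lengths; step i runs from sample i to sample i + 1 and
# is indexed by its start time.
step_lengths <- function(traj) {
  n <- nrow(traj)
  if (n < 2) return(numeric(0))
  sqrt(diff(traj$x_mm)^2 + diff(traj$y_mm)^2)
}

#' Activity index: proportion of time bins spent moving
#'
#' The trajectory is cut into consecutive bins of `bin` seconds aligned to
#' its first timestamp; a trailing partial bin is discarded. The fly counts
#' as immobile in a bin if it moved less than `move_threshold` mm there,
#' and the index is the fraction of complete bins with movement at or above
#' the threshold. Movement is measured as within-bin path length by default
#' (the stricter reading); `method = "net"` uses net displacement across
#' the bin instead.
#'
#' @param traj A trajectory data frame (`t_s`, `x_mm`, `y_mm`).
#' @param bin Bin width in seconds (default 0.5).
#' @param move_threshold Minimum within-bin movement in mm to count as
#'   mobile (default 1).
#' @param method `"path"` (summed step lengths, default) or `"net"`
#'   (displacement between bin boundaries).
#' @return Fraction of mobile bins, in `[0, 1]`.
#' @export
activity_index <- function(traj, bin = 0.5, move_threshold = 1,
                           method = c("path", "net")) {
  method <- match.arg(method)
  traj <- check_trajectory(traj)
  check_number(bin, "bin", lower = 0, strict_lower = TRUE)
  check_number(move_threshold, "move_threshold", lower = 0)
  t0 <- traj$t_s[1]
  duration <- traj$t_s[nrow(traj)] - t0
  n_bins <- floor(duration / bin + 1e-9)
  if (n_bins < 1) {
    stop_invalid("insufficient data: trajectory shorter than one bin")
  }
  # bin index of each step (by its start time); steps beyond the last
  # complete bin are dropped with the partial bin
  idx <- floor((traj$t_s[-nrow(traj)] - t0) / bin + 1e-9) + 1
  keep <- idx <= n_bins
  if (method == "path") {
    steps <- step_lengths(traj)
    moved <- numeric(n_bins)
    if (any(keep)) {
      agg <- rowsum(steps[keep], group = idx[keep])
      moved[as.integer(rownames(agg))] <- agg[, 1]
    }
  } else {
    # positions at bin boundaries: first sample at or after each boundary
    bounds <- t0 + (0:n_bins) * bin
    pos_at <- findInterval(bounds - 1e-9, traj$t_s) + 1
    pos_at <- pmin(pos_at, nrow(traj))
    moved <- sqrt(diff(traj$x_mm[pos_at])^2 + diff(traj$y_mm[pos_at])^2)
  }
  # nanometre slack so accumulated float error cannot flip a boundary bin
  mean(moved >= move_threshold - 1e-9)
}

#' Epoch-level inclusion rule for trajectory metrics
#'
#' A fly is excluded for an epoch when its total travelled distance is below
#' 200 mm or its activity index is below 10%; both reasons are recorded
#' when both apply.
#'
#' @param distance Travelled distance per epoch (mm).
#' @param activity Activity index per epoch, in `[0, 1]`.
#' @param min_distance,min_activity The exclusion thresholds.
#' @return A tibble with columns `distance`, `activity`, `keep` and
#'   `exclusion_reason` (`NA` when kept).
#' @export
exclusion_filter <- function(distance, activity, min_distance = 200,
                             min_activity = 0.10) {
  stopifnot(length(distance) == length(activity))
  low_d <- distance < min_distance
  low_a <- activity < min_activity
  reason <- dplyr::case_when(
    low_d & low_a ~ "distance;activity",
    low_d ~ "distance",
    low_a ~ "activity",
    .default = NA_character_
  )
  tibble::tibble(
    distance = distance, activity = activity,
    keep = !(low_d | low_a), exclusion_reason = reason
  )
}

# Point-in-polygon test (mgcv's in/out routine); poly is an open ring.
point_in_polygon <- function(points, poly) {
  ring <- rbind(poly, poly[1, , drop = FALSE])
  mgcv::in.out(ring, matrix(as.numeric(points), ncol = 2))
}

#' Travelled distance within a time window
#'
#' Sum of Euclidean step lengths over the half-open window
#' `[window[1], window[2])`, each step indexed by its start timestamp so
#' that distances over adjacent windows add up exactly.
#'
#' @param traj A trajectory data frame.
#' @param window Numeric `c(start, end)` in seconds; default spans the
#'   whole trajectory.
#' @return Distance in mm (>= 0); 0 for a single-sample trajectory.
#' @export
distance_travelled <- function(traj, window = NULL) {
  traj <- check_trajectory(traj)
  if (nrow(traj) < 2) return(0)
  steps <- step_lengths(traj)
  start_t <- traj$t_s[-nrow(traj)]
  if (is.null(window)) return(sum(steps))
  stopifnot(is.numeric(window), length(window) == 2)
  if (window[2] < window[1]) stop_invalid("window end precedes its start")
  sum(steps[start_t >= window[1] & start_t < window[2]])
}

check_session <- function(session) {
  if (!inherits(session, "snac_session")) {
    stop_invalid("`session` must be a snac_session object")
  }
  check_trajectory(session$trajectory)
  poly <- session$alcove
  if (!is.matrix(poly) || nrow(poly) < 3 ||
        nrow(unique(round(poly, 12))) < 3) {
    stop_invalid("geometry error: degenerate alcove polygon")
  }
  # degenerate (zero-area) polygon check via the shoelace formula
  xs <- poly[, 1]; ys <- poly[, 2]
  area <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  if (area <= 0) stop_invalid("geometry error: degenerate alcove polygon")
  ep <- session$epochs
  if (nrow(ep) > 1 && any(ep$start[-1] < ep$food_off[-nrow(ep)])) {
    stop_invalid("epochs overlap or are out of order")
  }
  session
}

#' Foraging-session metrics: entries, latency, path efficiency, distance
#'
#' For each epoch, an alcove entry is the first run of two consecutive
#' trajectory samples inside the alcove polygon during the food-on window
#' (a debounce against single-frame jitter). Successful epochs yield the
#' latency from food-on to entry, the path length travelled over that
#' interval, and path efficiency — straight-line distance from the
#' epoch-start position to the entry point divided by the path length, so
#' 1 exactly for a straight monotone run. Epochs without an entry are
#' censored: they count toward task performance but contribute no latency
#' or path metrics.
#'
#' @param session A `snac_session` as built by [gen_snac_session()] (or
#'   assembled from recorded data with the same fields).
#' @return A list of class `snac_metrics`: `entries`, `n_epochs`,
#'   `task_performance`, and `per_epoch`, a tibble with one row per epoch
#'   (`epoch`, `entered`, `time_to_feed`, `distance_mm`, `path_efficiency`).
#' @export
snac_metrics <- function(session) {
  session <- check_session(session)
  traj <- session$trajectory
  inside <- point_in_polygon(cbind(traj$x_mm, traj$y_mm), session$alcove)
  per_epoch <- purrr::pmap_dfr(
    session$epochs[, c("epoch", "food_on", "food_off", "start_x", "start_y")],
    function(epoch, food_on, food_off, start_x, start_y) {
      # schedules that have passed through text serialisation can be off in
      # the last ulp; a nanosecond of slack keeps boundary samples in
      eps <- 1e-9
      in_window <- which(traj$t_s >= food_on - eps & traj$t_s <= food_off + eps)
      ent <- NA_integer_
      if (length(in_window) >= 2) {
        runs <- inside[in_window]
        two_in <- which(runs[-1] & runs[-length(runs)])
        if (length(two_in)) ent <- in_window[two_in[1] + 1]
      }
      if (is.na(ent)) {
        return(tibble::tibble(
          epoch = epoch, entered = FALSE, time_to_feed = NA_real_,
          distance_mm = NA_real_, path_efficiency = NA_real_
        ))
      }
      entry_t <- traj$t_s[ent]
      # half-open window: the step ending at the entry sample starts before
      # entry_t and is therefore included
      dist <- distance_travelled(traj, c(food_on, entry_t))
      direct <- sqrt((traj$x_mm[ent] - start_x)^2 + (traj$y_mm[ent] - start_y)^2)
      eff <- if (dist == 0) 1 else min(direct / dist, 1)
      tibble::tibble(
        epoch = epoch, entered = TRUE, time_to_feed = entry_t - food_on,
        distance_mm = dist, path_efficiency = eff
      )
    }
  )
  entries <- sum(per_epoch$entered)
  structure(list(
    entries = entries,
    n_epochs = nrow(per_epoch),
    task_performance = entries / nrow(per_epoch),
    per_epoch = per_epoch
  ), class = "snac_metrics")
}

#' @export
print.snac_metrics <- function(x, ...) {
  cat("Foraging-session metrics: ", x$entries, "/", x$n_epochs,
      " alcove entries (task performance ",
      format(x$task_performance, digits = 3), ")\n", sep = "")
  print(x$per_epoch)
  invisible(x)
}
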