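# Plain-text interchange formats: trajectory CSV, foraging-session JSON,
# tidy assay CSV. All files are UTF-8 with decimal points and headers.

#' Write / read a trajectory CSV
#'
#' Columns `t_s,x_mm,y_mm` with a header row.
#'
#' @param traj A trajectory data frame.
#' @param path File path.
#' @return The path (write) or a validated trajectory tibble (read).
#' @export
write_trajectory_csv <- function(traj, path) {
  check_trajectory(traj)
  readr::write_csv(traj[, c("t_s", "x_mm", "y_mm")], path)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  traj <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            t_s = readr::col_double(),
                            x_mm = readr::col_double(),
                            y_mm = readr::col_double()
                          ))
  check_trajectory(tibble::as_tibble(traj))
}

#' Write / read a foraging session as JSON plus a trajectory CSV
#'
#' The JSON document holds the arena size, alcove polygon and epoch
#' schedule (start, food-on, food-off, entry time) and references the
#' trajectory CSV by relative path.
#'
#' @param session A `snac_session`.
#' @param path JSON file path; the trajectory CSV is written next to it
#'   with the same stem.
#' @return The path (write) or a `snac_session` (read).
#' @export
write_snac_session <- function(session, path) {
  stopifnot(inherits(session, "snac_session"))
  traj_path <- sub("\\.json$", "_trajectory.csv", path)
  write_trajectory_csv(session$trajectory, traj_path)
  doc <- list(
    arena = list(width_mm = session$params$arena_width,
                 height_mm = session$params$arena_height),
    alcove = apply(session$alcove, 1, function(r) list(x = r[[1]], y = r[[2]])),
    epochs = session$epochs,
    trajectory_file = basename(traj_path),
    sample_rate_hz = session$params$sample_rate
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' @rdname write_snac_session
#' @export
read_snac_session <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  traj <- read_trajectory_csv(file.path(dirname(path), doc$trajectory_file))
  epochs <- tibble::as_tibble(doc$epochs)
  if (!"entry_time" %in% names(epochs)) epochs$entry_time <- NA_real_
  epochs$entry_time <- as.numeric(epochs$entry_time)
  params <- walk_params(
    sample_rate = doc$sample_rate_hz,
    arena_width = doc$arena$width_mm,
    arena_height = doc$arena$height_mm
  )
  alcove <- cbind(x = doc$alcove$x, y = doc$alcove$y)
  structure(list(trajectory = traj, epochs = epochs, alcove = alcove,
                 params = params), class = "snac_session")
}

#' Write / read the tidy assay metric CSV
#'
#' Schema `driver,condition,feeding_state,unit_id,metric,value,unit`.
#'
#' @param metrics The tidy metric tibble from [compute_assay_metrics()].
#' @param path File path.
#' @return The path (write) or the tibble (read).
#' @export
write_assay_csv <- function(metrics, path) {
  need <- c("driver", "condition", "feeding_state", "unit_id", "metric",
            "value", "unit")
  miss <- setdiff(need, names(metrics))
  if (length(miss)) stop_invalid("metrics table missing column `", miss[1], "`")
  readr::write_csv(metrics[, need], path)
  invisible(path)
}

#' @rdname write_assay_csv
#' @export
read_assay_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    value = readr::col_double(),
                    .default = readr::col_character()
                  ))
}
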