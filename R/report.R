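# Pipeline orchestration and the driver-by-metric effect matrix.

#' Assemble the driver-by-metric effect matrix
#'
#' One cell per (driver, metric) pair, carrying the standardized effect and
#' an emphasis flag set exactly when `|g| > 0.50` or `|delta| > 0.47`
#' (strict inequalities) -- the conventional moderate-or-larger emphasis
#' rule. Cliff's-delta cells are rendered with a distinguishing "D" prefix.
#'
#' @param estimates A tibble of effect estimates (rows as produced by
#'   [estimate_effect()]) with a `driver` column; at most one row per
#'   (driver, metric).
#' @return An `effect_matrix` object: the long tibble plus render helpers;
#'   see [format_effect_matrix()].
#' @export
effect_matrix <- function(estimates) {
  need <- c("driver", "metric", "estimator", "effect")
  miss <- setdiff(need, names(estimates))
  if (length(miss)) {
    stop_invalid("estimates table missing column `", miss[1], "`")
  }
  dup <- duplicated(estimates[, c("driver", "metric")])
  if (any(dup)) {
    stop_invalid("collision: duplicate estimate for (",
                 estimates$driver[dup][1], ", ", estimates$metric[dup][1], ")")
  }
  cells <- estimates
  cells$emphasis <- !is.na(cells$effect) & ifelse(
    cells$estimator == "delta",
    abs(cells$effect) > 0.47,
    abs(cells$effect) > 0.50
  )
  structure(list(cells = tibble::as_tibble(cells),
                 drivers = unique(cells$driver),
                 metrics = unique(cells$metric)),
            class = "effect_matrix")
}

format_cell <- function(effect, estimator, emphasis, md = FALSE) {
  if (is.na(effect)) return("·")
  txt <- sprintf("%+.2f", effect)
  if (estimator == "delta") txt <- paste0("D", txt)
  if (md && emphasis) txt <- paste0("**", txt, "**")
  txt
}

#' Render an effect matrix as CSV text, JSON or markdown
#'
#' @param x An `effect_matrix`.
#' @param format `"csv"` (long table), `"json"` (long records) or `"md"`
#'   (wide table with emphasised cells in bold). Missing cells are rendered
#'   as a centred dot and never counted as emphasised.
#' @return A character scalar (`json`, `md`) or the long tibble (`csv`).
#' @export
format_effect_matrix <- function(x, format = c("csv", "json", "md")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "effect_matrix"))
  if (format == "csv") return(x$cells)
  if (format == "json") {
    return(jsonlite::toJSON(x$cells, dataframe = "rows", digits = NA,
                            na = "null", auto_unbox = TRUE, pretty = TRUE))
  }
  wide <- tidyr::expand_grid(metric = x$metrics, driver = x$drivers) |>
    dplyr::left_join(x$cells[, c("driver", "metric", "estimator",
                                 "effect", "emphasis")],
                     by = c("driver", "metric"))
  wide$txt <- mapply(format_cell, wide$effect,
                     ifelse(is.na(wide$estimator), "g", wide$estimator),
                     !is.na(wide$emphasis) & wide$emphasis,
                     MoreArgs = list(md = TRUE))
  tab <- tidyr::pivot_wider(wide[, c("metric", "driver", "txt")],
                            names_from = "driver", values_from = "txt")
  header <- paste0("| metric | ", paste(x$drivers, collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", length(x$drivers) + 1), collapse = "|"), "|")
  body <- apply(tab, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, body), collapse = "\n")
}

#' Write / read the long effect-matrix table
#'
#' CSV and JSON round-trip: reading back what was written reproduces the
#' matrix cells exactly.
#'
#' @param x An `effect_matrix`.
#' @param path Output path; the extension (`.csv` or `.json`) selects the
#'   format.
#' @return `write_effect_matrix` returns `path` invisibly;
#'   `read_effect_matrix` returns an `effect_matrix`.
#' @export
write_effect_matrix <- function(x, path) {
  stopifnot(inherits(x, "effect_matrix"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x$cells, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = TRUE)
  } else {
    readr::write_csv(x$cells, path)
  }
  invisible(path)
}

#' @rdname write_effect_matrix
#' @export
read_effect_matrix <- function(path) {
  cells <- if (grepl("\\.json$", path)) {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
  cells$emphasis <- NULL
  effect_matrix(cells)
}

#' @export
print.effect_matrix <- function(x, ...) {
  cat("Effect matrix: ", length(x$metrics), " metrics x ",
      length(x$drivers), " drivers, ", sum(x$cells$emphasis),
      " emphasised cells\n", sep = "")
  cat(format_effect_matrix(x, "md"), "\n")
  invisible(x)
}

#' Run the full generate-extract-estimate pipeline
#'
#' Generates the raw-assay bundle for the scenario, extracts the tidy
#' per-unit metrics, estimates every (driver, metric) contrast with
#' bootstrap confidence intervals, and assembles the effect matrix plus a
#' run manifest. Idempotent for a fixed config: the same seed reproduces
#' every output byte for byte.
#'
#' @param config A [scenario_config()].
#' @param out_dir Optional directory; when given, writes `estimates.csv`,
#'   `metrics.csv`, `effect_matrix.csv`, `effect_matrix.json`,
#'   `effect_matrix.md` and `manifest.json` there.
#' @param B Bootstrap resamples per contrast (default 10000).
#' @param level Confidence level (default 0.95).
#' @return A list of class `fly_pipeline`: `bundle`, `metrics`,
#'   `estimates`, `matrix`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, B = 10000, level = 0.95) {
  config <- validate_scenario_config(config)
  bundle <- gen_assay_bundle(config)
  metrics <- compute_assay_metrics(bundle)
  est_info <- config$metrics[, c("metric", "estimator")]
  groups <- metrics |>
    dplyr::left_join(est_info, by = "metric") |>
    dplyr::group_by(.data$driver, .data$metric, .data$feeding_state,
                    .data$estimator) |>
    tidyr::nest() |>
    dplyr::ungroup()
  estimates <- purrr::pmap_dfr(
    groups[, c("driver", "metric", "feeding_state", "estimator", "data")],
    function(driver, metric, feeding_state, estimator, data) {
      ctl <- data$value[data$condition == "uninduced"]
      trt <- data$value[data$condition == "induced"]
      est <- estimate_effect(
        ctl, trt, metric = metric, estimator = estimator, B = B,
        level = level,
        seed = derive_seed(config$seed, paste("boot", driver, metric, sep = "/"))
      )
      dplyr::bind_cols(tibble::tibble(driver = driver,
                                      feeding_state = feeding_state),
                       est)
    }
  )
  estimates <- dplyr::arrange(
    estimates,
    match(.data$metric, config$metrics$metric),
    match(.data$driver, config$drivers)
  )
  mat <- effect_matrix(estimates)
  manifest <- list(
    package = "flyfx",
    version = as.character(utils::packageVersion("flyfx")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    bootstrap_B = as.integer(B),
    level = level,
    drivers = config$drivers,
    metrics = config$metrics$metric,
    n_estimates = nrow(estimates),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  out <- structure(list(bundle = bundle, metrics = metrics,
                        estimates = estimates, matrix = mat,
                        manifest = manifest), class = "fly_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(metrics, file.path(out_dir, "metrics.csv"))
    readr::write_csv(estimates, file.path(out_dir, "estimates.csv"))
    write_effect_matrix(mat, file.path(out_dir, "effect_matrix.csv"))
    write_effect_matrix(mat, file.path(out_dir, "effect_matrix.json"))
    writeLines(format_effect_matrix(mat, "md"),
               file.path(out_dir, "effect_matrix.md"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.fly_pipeline <- function(x, ...) {
  cat("Pipeline run (seed ", x$manifest$seed, ", B = ",
      x$manifest$bootstrap_B, ")\n", sep = "")
  print(x$matrix)
  invisible(x)
}

#' Estimator recovery at a design point
#'
#' Simulates `reps` replicate two-group datasets at a given true effect and
#' sample sizes, applies the chosen estimator to each, and returns the mean
#' estimate. For `estimator = "g"` data are normal with the true
#' standardized mean difference; for `"delta"` data are normal with the
#' latent shift calibrated so the population Cliff's delta equals
#' `true_effect`; for `"mean_difference"` the groups differ by
#' `true_effect` in native units with common SD `sd`.
#'
#' @param true_effect The ground-truth effect on the estimator's scale.
#' @param n_c,n_t Group sizes.
#' @param estimator `"g"`, `"delta"` or `"mean_difference"`.
#' @param reps Number of replicate datasets (default 2000).
#' @param sd Common SD in native units (used for `"mean_difference"`).
#' @param seed Integer seed.
#' @return Mean estimate over the replicates.
#' @export
simulate_estimator_recovery <- function(true_effect, n_c, n_t,
                                        estimator = c("g", "delta",
                                                      "mean_difference"),
                                        reps = 2000, sd = 1, seed = NULL) {
  estimator <- match.arg(estimator)
  n_c <- check_count(n_c, "n_c", min = 2L)
  n_t <- check_count(n_t, "n_t", min = 2L)
  reps <- check_count(reps, "reps")
  shift <- switch(estimator,
    g = true_effect * sd,
    delta = calibrate_latent_shift(true_effect) * sd,
    mean_difference = true_effect
  )
  fun <- switch(estimator,
    g = hedges_g,
    delta = cliffs_delta,
    mean_difference = mean_difference
  )
  with_seed(seed, {
    mean(vapply(seq_len(reps), function(i) {
      fun(stats::rnorm(n_c, 0, sd), stats::rnorm(n_t, shift, sd))
    }, numeric(1)))
  })
}
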