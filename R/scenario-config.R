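# Scenario configuration: the study design under which synthetic assay data
# are generated. The defaults encode the two-arm design used throughout the
# assay panel -- an uninduced control arm against a warm-induced
# neuronal-silencing arm -- across five driver lines and fourteen metrics
# from eleven assays.

#' Default metric panel
#'
#' One row per metric: the assay it comes from, native units, the
#' estimator used for it (Hedges' g, or Cliff's delta for the ordinal
#' alcove-entry count), the feeding state of the flies, the control-arm
#' baseline and standard deviation in native units, and default group
#' sizes. Baselines and SDs are plausible values for the respective assay
#' (activity as a proportion, intake in ul over 6 h, respirometry in
#' ul/fly/h, masses in mg); group sizes follow typical published designs
#' for each assay type.
#'
#' @return A tibble with columns `metric`, `assay`, `unit`, `estimator`,
#'   `feeding_state`, `baseline`, `sd`, `n_c`, `n_t`.
#' @export
metric_defaults <- function() {
  tibble::tribble(
    ~metric,           ~assay,         ~unit,       ~estimator, ~feeding_state, ~baseline, ~sd,   ~n_c, ~n_t,
    "activity",        "activity",     "proportion", "g",      "fed",          0.50,      0.20,  82,   83,
    "climbing",        "climbing",     "index",      "g",      "fed",          0.70,      0.15,  10,   10,
    "intake_single",   "cafe_single",  "ul",         "g",      "starved",      0.25,      0.13,  50,   50,
    "intake_group",    "cafe_group",   "ul/fly",     "g",      "starved",      0.40,      0.10,  8,    8,
    "entries",         "snac",         "count",      "delta",  "starved",      3,         1,     82,   75,
    "time_to_alcove",  "snac",         "s",          "g",      "starved",      30,        12,    82,   75,
    "path_efficiency", "snac",         "fraction",   "g",      "starved",      0.55,      0.15,  82,   75,
    "distance",        "snac",         "mm",         "g",      "starved",      250,       103,   82,   75,
    "vco2_fed",        "respirometry", "ul/fly/h",   "g",      "fed",          7.0,       1.4,   51,   52,
    "vco2_starved",    "respirometry", "ul/fly/h",   "g",      "starved",      8.0,       2.7,   55,   45,
    "lipid_fed",       "body_lipid",   "%",          "g",      "fed",          15,        3.0,   8,    8,
    "lipid_starved",   "body_lipid",   "%",          "g",      "starved",      12,        4.4,   8,    8,
    "weight_fed",      "body_weight",  "mg",         "g",      "fed",          0.90,      0.14,  8,    8,
    "weight_starved",  "body_weight",  "mg",         "g",      "starved",      0.85,      0.12,  8,    8
  )
}

#' Build a simulation scenario
#'
#' Defines drivers, per-driver-per-metric true standardized effects, group
#' sizes and the metric panel for one synthetic study. With all defaults
#' the scenario reproduces the published five-driver design with the
#' reported effect-size matrix as ground truth.
#'
#' For metrics estimated with Hedges' g the `true_smd` entry is the true
#' standardized mean difference; for the ordinal `entries` metric it is
#' interpreted as the target Cliff's delta of the latent score (see
#' [calibrate_latent_shift()]).
#'
#' @param drivers Character vector of driver-line labels.
#' @param true_smd Either a single number applied to every driver x metric
#'   cell (0 gives a null scenario), a named numeric vector per metric
#'   (recycled over drivers), a data frame with columns
#'   `driver`, `metric`, `true_smd`, or `NULL` for the published
#'   effect-matrix defaults ([published_effects()]).
#' @param n_per_arm Optional single group size overriding both arms of all
#'   metrics; `NULL` keeps the per-metric defaults.
#' @param metrics Metric panel, default [metric_defaults()].
#' @param seed Root integer seed. Every assay generator draws from its own
#'   substream derived from this seed, so adding an assay never perturbs
#'   the others.
#' @return A validated `scenario_config` object.
#' @export
scenario_config <- function(drivers = c("TH", "Ddc", "Tdc2", "Trh", "NPF"),
                            true_smd = NULL, n_per_arm = NULL,
                            metrics = metric_defaults(), seed = 1) {
  stopifnot(is.character(drivers), length(drivers) >= 1, !anyDuplicated(drivers))
  effects <- build_effects(drivers, true_smd, metrics)
  if (!is.null(n_per_arm)) {
    n_per_arm <- check_count(n_per_arm, "n_per_arm")
    metrics$n_c <- n_per_arm
    metrics$n_t <- n_per_arm
  }
  cfg <- structure(list(
    drivers = drivers,
    metrics = metrics,
    effects = effects,
    seed = as.integer(seed)
  ), class = "scenario_config")
  validate_scenario_config(cfg)
}

build_effects <- function(drivers, true_smd, metrics) {
  grid <- tidyr::expand_grid(driver = drivers, metric = metrics$metric)
  if (is.null(true_smd)) {
    pub <- published_effects()
    eff <- dplyr::left_join(grid, pub[, c("driver", "metric", "effect")],
                            by = c("driver", "metric"))
    eff$true_smd <- ifelse(is.na(eff$effect), 0, eff$effect)
    return(eff[, c("driver", "metric", "true_smd")])
  }
  if (is.data.frame(true_smd)) {
    need <- c("driver", "metric", "true_smd")
    if (!all(need %in% names(true_smd))) {
      stop_invalid("config error: true_smd data frame needs columns ",
                   paste(need, collapse = ", "))
    }
    eff <- dplyr::left_join(grid, true_smd[, need], by = c("driver", "metric"))
    eff$true_smd[is.na(eff$true_smd)] <- 0
    return(eff)
  }
  if (is.numeric(true_smd) && length(true_smd) == 1L && is.null(names(true_smd))) {
    grid$true_smd <- true_smd
    return(grid)
  }
  if (is.numeric(true_smd) && !is.null(names(true_smd))) {
    unknown <- setdiff(names(true_smd), metrics$metric)
    if (length(unknown)) {
      stop_invalid("config error: true_smd names not in the metric panel: ",
                   paste(unknown, collapse = ", "))
    }
    grid$true_smd <- unname(true_smd[grid$metric])
    grid$true_smd[is.na(grid$true_smd)] <- 0
    return(grid)
  }
  stop_invalid("config error: unsupported `true_smd` specification")
}

#' Validate a scenario configuration
#'
#' Checks the structural invariants: positive group sizes, positive
#' baseline SDs, every effect entry mapping to exactly one metric of the
#' panel, and Cliff's-delta targets inside (-1, 1). Errors name the
#' offending key.
#'
#' @param config A `scenario_config` object (or a bare list with the same
#'   fields, e.g. parsed from YAML/JSON).
#' @return The validated config, invisibly classed as `scenario_config`.
#' @export
validate_scenario_config <- function(config) {
  need <- c("drivers", "metrics", "effects", "seed")
  missing <- setdiff(need, names(config))
  if (length(missing)) {
    stop_invalid("config error: missing field `", missing[1], "`")
  }
  m <- config$metrics
  need_m <- c("metric", "assay", "unit", "estimator", "feeding_state",
              "baseline", "sd", "n_c", "n_t")
  miss_m <- setdiff(need_m, names(m))
  if (length(miss_m)) {
    stop_invalid("config error: metrics table missing column `", miss_m[1], "`")
  }
  if (anyDuplicated(m$metric)) {
    stop_invalid("config error: duplicated metric in panel: ",
                 m$metric[duplicated(m$metric)][1])
  }
  bad_n <- m$metric[m$n_c < 1 | m$n_t < 1 | m$n_c != round(m$n_c) |
                      m$n_t != round(m$n_t)]
  if (length(bad_n)) {
    stop_invalid("config error: group_sizes for metric `", bad_n[1],
                 "` must be integers >= 1")
  }
  bad_sd <- m$metric[!is.finite(m$sd) | m$sd <= 0]
  if (length(bad_sd)) {
    stop_invalid("config error: baseline_sd for metric `", bad_sd[1],
                 "` must be > 0")
  }
  if (!all(m$estimator %in% c("g", "delta"))) {
    stop_invalid("config error: estimator must be \"g\" or \"delta\"")
  }
  e <- config$effects
  unknown <- setdiff(unique(e$metric), m$metric)
  if (length(unknown)) {
    stop_invalid("config error: effect entry for unknown metric `",
                 unknown[1], "`")
  }
  unknown_d <- setdiff(unique(e$driver), config$drivers)
  if (length(unknown_d)) {
    stop_invalid("config error: effect entry for unknown driver `",
                 unknown_d[1], "`")
  }
  if (anyDuplicated(e[, c("driver", "metric")])) {
    stop_invalid("config error: duplicated (driver, metric) effect entry")
  }
  delta_metrics <- m$metric[m$estimator == "delta"]
  bad_delta <- e$metric %in% delta_metrics & abs(e$true_smd) >= 1
  if (any(bad_delta)) {
    stop_invalid("config error: Cliff's-delta target for metric `",
                 e$metric[bad_delta][1], "` must lie strictly inside (-1, 1)")
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1L) {
    stop_invalid("config error: seed must be a single integer")
  }
  structure(config[need], class = "scenario_config")
}

#' Read a scenario configuration from YAML or JSON
#'
#' The document may carry `drivers`, `true_smd` (scalar, per-metric map, or
#' a list of `driver`/`metric`/`true_smd` records), `n_per_arm`, `seed`,
#' and optional `metrics` overrides (a list of per-metric records merged
#' over [metric_defaults()]).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  metrics <- metric_defaults()
  if (!is.null(doc$metrics)) {
    override <- dplyr::bind_rows(lapply(doc$metrics, tibble::as_tibble))
    if (!"metric" %in% names(override)) {
      stop_invalid("config error: metrics overrides need a `metric` key")
    }
    for (i in seq_len(nrow(override))) {
      j <- match(override$metric[i], metrics$metric)
      if (is.na(j)) {
        stop_invalid("config error: metrics override for unknown metric `",
                     override$metric[i], "`")
      }
      for (col in setdiff(names(override), "metric")) {
        if (!col %in% names(metrics)) {
          stop_invalid("config error: unknown metrics column `", col, "`")
        }
        metrics[[col]][j] <- override[[col]][i]
      }
    }
  }
  true_smd <- doc$true_smd
  if (is.list(true_smd) && !is.null(names(true_smd))) {
    true_smd <- unlist(true_smd)
  } else if (is.list(true_smd)) {
    true_smd <- dplyr::bind_rows(lapply(true_smd, tibble::as_tibble))
  }
  scenario_config(
    drivers = if (is.null(doc$drivers)) c("TH", "Ddc", "Tdc2", "Trh", "NPF") else doc$drivers,
    true_smd = true_smd,
    n_per_arm = doc$n_per_arm,
    metrics = metrics,
    seed = if (is.null(doc$seed)) 1 else doc$seed
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario: ", length(x$drivers), " drivers x ", nrow(x$metrics),
      " metrics (seed ", x$seed, ")\n", sep = "")
  cat("Drivers:", paste(x$drivers, collapse = ", "), "\n")
  nz <- sum(x$effects$true_smd != 0)
  cat(nz, "non-null true effects\n")
  invisible(x)
}
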