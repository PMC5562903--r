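# Raw-assay bundle generator: one synthetic analogue per assay of the
# panel, drawn so that the metric-level standardized effects match the
# scenario's ground truth. Measurement chains that add noise downstream of
# the fly (capillary evaporation) are compensated at generation time so the
# *corrected* metric, not the latent one, carries the target effect.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Per-fly (or per-unit) normal draws for both arms of one driver x metric
# cell. For delta-estimated metrics the shift is the calibrated latent one.
cell_arm_means <- function(baseline, sd, true_smd, estimator) {
  if (estimator == "delta") {
    baseline + c(0, calibrate_latent_shift(true_smd) * sd)
  } else {
    baseline + c(0, true_smd * sd)
  }
}

#' Generate the full raw-assay bundle for a scenario
#'
#' Emits, per driver and condition (uninduced control vs induced), raw
#' records for every assay of the metric panel: capillary start/end level
#' drops for experimental and paired fly-free evaporation chambers
#' (single-fly and ten-fly group feeding), per-fly climbing times with
#' failures beyond 60 s recorded as missing, respirometry chamber volumes,
#' body-mass panels (wet/dry/lean-dry), and tracker-derived behavioural
#' metrics (activity index and the four foraging-session metrics).
#'
#' For the feeding assays the evaporation noise that the paired-control
#' correction re-introduces is budgeted out of the latent intake SD, so
#' the evaporation-corrected intake has exactly the configured SD and
#' standardized effect. Bounded metrics (activity in `[0, 1]`, climbing
#' index on a five-fly grid, ordinal entry counts) are clamped or
#' discretised after the calibrated draw, which attenuates very large
#' effects slightly; a null effect is preserved exactly.
#'
#' All draws descend from per-cell substreams of `config$seed`, so the
#' bundle is byte-identical for a fixed config and adding one assay does
#' not perturb the others.
#'
#' @param config A [scenario_config()] object.
#' @return A list of class `assay_bundle` with tibbles `cafe`, `climbing`,
#'   `respirometry`, `body`, `behaviour`, plus the `config`.
#' @export
gen_assay_bundle <- function(config) {
  config <- validate_scenario_config(config)
  m <- config$metrics
  cells <- dplyr::left_join(config$effects, m, by = "metric")
  parts <- lapply(seq_len(nrow(cells)), function(i) gen_cell(cells[i, ], config$seed))
  bundle <- list(
    cafe = dplyr::bind_rows(purrr::map(parts, "cafe")),
    climbing = dplyr::bind_rows(purrr::map(parts, "climbing")),
    respirometry = dplyr::bind_rows(purrr::map(parts, "respirometry")),
    body = dplyr::bind_rows(purrr::map(parts, "body")),
    behaviour = dplyr::bind_rows(purrr::map(parts, "behaviour")),
    config = config
  )
  structure(bundle, class = "assay_bundle")
}

gen_cell <- function(cell, root_seed) {
  seed <- derive_seed(root_seed, paste(cell$driver, cell$metric, sep = "/"))
  means <- cell_arm_means(cell$baseline, cell$sd, cell$true_smd, cell$estimator)
  arms <- tibble::tibble(
    condition = c("uninduced", "induced"),
    n = c(cell$n_c, cell$n_t),
    mu = means
  )
  gen <- switch(cell$assay,
    cafe_single = function() gen_cafe_cell(cell, arms, seed, n_flies = 1),
    cafe_group = function() gen_cafe_cell(cell, arms, seed, n_flies = 10),
    climbing = function() gen_climbing_cell(cell, arms, seed),
    respirometry = function() gen_respirometry_cell(cell, arms, seed),
    body_lipid = function() gen_body_lipid_cell(cell, arms, seed),
    body_weight = function() gen_body_weight_cell(cell, arms, seed),
    activity = function() gen_behaviour_cell(cell, arms, seed, lo = 0, hi = 1),
    snac = function() gen_snac_cell(cell, arms, seed),
    stop_invalid("config error: metric `", cell$metric,
                 "` maps to unknown assay `", cell$assay, "`")
  )
  gen()
}

# Evaporation-corrected intake must end up N(mu, sd): the paired correction
# adds back 2 * s_e^2 / n_flies^2 of variance, so the latent per-fly intake
# is drawn with the remainder. s_e is capped at the budget that keeps the
# latent variance positive.
gen_cafe_cell <- function(cell, arms, seed, n_flies) {
  evap_mu <- 0.15 * n_flies
  s_e <- min(0.2 * cell$sd * n_flies, cell$sd * n_flies / 2)
  sd_latent <- sqrt(cell$sd^2 - 2 * s_e^2 / n_flies^2)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(arms)), function(a) {
      n <- arms$n[a]
      intake <- stats::rnorm(n, arms$mu[a], sd_latent)
      evap_exp <- stats::rnorm(n, evap_mu, s_e)
      evap_ctl <- stats::rnorm(n, evap_mu, s_e)
      tibble::tibble(
        driver = cell$driver, condition = arms$condition[a],
        feeding_state = cell$feeding_state, metric = cell$metric,
        chamber_id = sprintf("%s_%s_%03d", cell$driver, arms$condition[a],
                             seq_len(n)),
        n_flies = n_flies, duration_h = 6,
        level_drop_exp_ul = pmax(intake * n_flies + evap_exp, 0),
        level_drop_control_ul = pmax(evap_ctl, 0)
      )
    })
    list(cafe = dplyr::bind_rows(rows))
  })
}

# Trial-level climbing index drawn at the target effect, then realised as
# per-fly times on a five-fly grid: successes uniform below the cutoff,
# failures recorded as NA (the in-memory +Inf sentinel appears only once
# times are read back from CSV, where the field is empty).
gen_climbing_cell <- function(cell, arms, seed, flies_per_trial = 5,
                              cutoff = 60) {
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(arms)), function(a) {
      n_trials <- arms$n[a]
      target <- clamp(stats::rnorm(n_trials, arms$mu[a], cell$sd), 0, 1)
      k <- round(target * flies_per_trial)
      purrr::map_dfr(seq_len(n_trials), function(tr) {
        times <- c(stats::runif(k[tr], 5, cutoff - 5),
                   rep(Inf, flies_per_trial - k[tr]))
        tibble::tibble(
          driver = cell$driver, condition = arms$condition[a],
          feeding_state = cell$feeding_state, metric = cell$metric,
          trial_id = sprintf("%s_%s_t%02d", cell$driver, arms$condition[a], tr),
          fly_id = seq_len(flies_per_trial),
          time_s = times
        )
      })
    })
    list(climbing = dplyr::bind_rows(rows))
  })
}

gen_respirometry_cell <- function(cell, arms, seed) {
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(arms)), function(a) {
      n <- arms$n[a]
      tibble::tibble(
        driver = cell$driver, condition = arms$condition[a],
        feeding_state = cell$feeding_state, metric = cell$metric,
        chamber_id = seq_len(n),
        volume_ul = pmax(stats::rnorm(n, arms$mu[a], cell$sd), 0),
        duration_h = 1, n_flies = 1
      )
    })
    list(respirometry = dplyr::bind_rows(rows))
  })
}

# Lipid panel: the targeted metric is the lipid percentage of dry mass.
# Masses are for a group of five flies.
gen_body_lipid_cell <- function(cell, arms, seed, flies_per_group = 5) {
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(arms)), function(a) {
      n <- arms$n[a]
      pct <- clamp(stats::rnorm(n, arms$mu[a], cell$sd), 0.5, 60)
      dry <- stats::rnorm(n, 0.30 * flies_per_group, 0.05)
      lipid <- pct / 100 * dry
      water <- pmax(stats::rnorm(n, 0.55 * flies_per_group, 0.12), 0.05)
      tibble::tibble(
        driver = cell$driver, condition = arms$condition[a],
        feeding_state = cell$feeding_state, metric = cell$metric,
        replicate_id = seq_len(n), n_flies = flies_per_group,
        wet_mg = dry + water, dry_mg = dry, lean_dry_mg = dry - lipid
      )
    })
    list(body = dplyr::bind_rows(rows))
  })
}

# Weight panel: the targeted metric is per-fly wet mass; dry and lean-dry
# masses are filled in consistently so the panel is a complete record.
gen_body_weight_cell <- function(cell, arms, seed, flies_per_group = 5) {
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(arms)), function(a) {
      n <- arms$n[a]
      wet_per_fly <- pmax(stats::rnorm(n, arms$mu[a], cell$sd), 0.2)
      wet <- wet_per_fly * flies_per_group
      dry_frac <- clamp(stats::rnorm(n, 0.35, 0.03), 0.2, 0.6)
      dry <- wet * dry_frac
      lipid_frac <- clamp(stats::rnorm(n, 0.15, 0.03), 0.02, 0.5)
      tibble::tibble(
        driver = cell$driver, condition = arms$condition[a],
        feeding_state = cell$feeding_state, metric = cell$metric,
        replicate_id = seq_len(n), n_flies = flies_per_group,
        wet_mg = wet, dry_mg = dry, lean_dry_mg = dry * (1 - lipid_frac)
      )
    })
    list(body = dplyr::bind_rows(rows))
  })
}

gen_behaviour_cell <- function(cell, arms, seed, lo = -Inf, hi = Inf) {
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(arms)), function(a) {
      n <- arms$n[a]
      tibble::tibble(
        driver = cell$driver, condition = arms$condition[a],
        feeding_state = cell$feeding_state, metric = cell$metric,
        fly_id = seq_len(n),
        value = clamp(stats::rnorm(n, arms$mu[a], cell$sd), lo, hi),
        unit = cell$unit
      )
    })
    list(behaviour = dplyr::bind_rows(rows))
  })
}

# Foraging-session metrics. The ordinal entry count is discretised from the
# calibrated latent score onto 0..6; the continuous session metrics get
# assay-appropriate clamps.
gen_snac_cell <- function(cell, arms, seed) {
  switch(cell$metric,
    entries = with_seed(seed, {
      rows <- lapply(seq_len(nrow(arms)), function(a) {
        latent <- stats::rnorm(arms$n[a], arms$mu[a], cell$sd)
        tibble::tibble(
          driver = cell$driver, condition = arms$condition[a],
          feeding_state = cell$feeding_state, metric = cell$metric,
          fly_id = seq_len(arms$n[a]),
          value = clamp(round(latent), 0, 6),
          unit = cell$unit
        )
      })
      list(behaviour = dplyr::bind_rows(rows))
    }),
    time_to_alcove = gen_behaviour_cell(cell, arms, seed, lo = 0.1, hi = 100),
    path_efficiency = gen_behaviour_cell(cell, arms, seed, lo = 0.01, hi = 1),
    distance = gen_behaviour_cell(cell, arms, seed, lo = 1),
    gen_behaviour_cell(cell, arms, seed)
  )
}

#' Tidy per-unit metric table from a raw-assay bundle
#'
#' Applies the assay computations ([cafe_intake()], [climbing_index()],
#' [vco2_rate()], [body_composition()]) to the raw records and stacks the
#' results with the tracker-derived behavioural metrics into one tidy
#' table, one row per experimental unit (fly, vial, trial or replicate
#' group, as appropriate for the assay).
#'
#' @param bundle An `assay_bundle` from [gen_assay_bundle()].
#' @return A tibble with columns `driver`, `condition`, `feeding_state`,
#'   `metric`, `unit_id`, `value`, `unit`.
#' @export
compute_assay_metrics <- function(bundle) {
  stopifnot(inherits(bundle, "assay_bundle"))
  units <- bundle$config$metrics[, c("metric", "unit")]
  out <- list()
  if (nrow(bundle$cafe)) {
    cafe <- bundle$cafe
    corrected <- cafe_intake(cafe$level_drop_exp_ul,
                             cafe$level_drop_control_ul,
                             n_flies = 1, duration = 6)
    out$cafe <- tibble::tibble(
      driver = cafe$driver, condition = cafe$condition,
      feeding_state = cafe$feeding_state, metric = cafe$metric,
      unit_id = as.character(cafe$chamber_id),
      value = corrected$intake_ul_per_fly / cafe$n_flies
    )
  }
  if (nrow(bundle$climbing)) {
    out$climbing <- bundle$climbing |>
      dplyr::group_by(.data$driver, .data$condition, .data$feeding_state,
                      .data$metric, .data$trial_id) |>
      dplyr::summarise(value = climbing_index(.data$time_s), .groups = "drop") |>
      dplyr::rename(unit_id = "trial_id")
  }
  if (nrow(bundle$respirometry)) {
    resp <- bundle$respirometry
    out$respirometry <- tibble::tibble(
      driver = resp$driver, condition = resp$condition,
      feeding_state = resp$feeding_state, metric = resp$metric,
      unit_id = as.character(resp$chamber_id),
      value = purrr::pmap_dbl(
        list(resp$volume_ul, resp$duration_h, resp$n_flies), vco2_rate
      )
    )
  }
  if (nrow(bundle$body)) {
    body <- bundle$body
    comp <- body_composition(body$wet_mg, body$dry_mg, body$lean_dry_mg)
    out$body <- tibble::tibble(
      driver = body$driver, condition = body$condition,
      feeding_state = body$feeding_state, metric = body$metric,
      unit_id = as.character(body$replicate_id),
      value = ifelse(grepl("^lipid", body$metric), comp$lipid_pct,
                     body$wet_mg / body$n_flies)
    )
  }
  if (nrow(bundle$behaviour)) {
    beh <- bundle$behaviour
    out$behaviour <- tibble::tibble(
      driver = beh$driver, condition = beh$condition,
      feeding_state = beh$feeding_state, metric = beh$metric,
      unit_id = as.character(beh$fly_id), value = beh$value
    )
  }
  dplyr::bind_rows(out) |>
    dplyr::left_join(units, by = "metric") |>
    dplyr::arrange(.data$driver, .data$metric, .data$condition, .data$unit_id)
}
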