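# Scalar assay computations: climbing index, evaporation-corrected capillary
# feeding intake, respirometry rate, and body-composition measures.

#' Climbing index from per-fly ascent times
#'
#' Each fly scores 1 if it reached the top mark within `cutoff` seconds and
#' 0 otherwise; failures may be encoded as `Inf` or `NA`. The index is the
#' mean score over the flies of one trial, a value between 0 and 1;
#' trial-level indices are averaged across repeats by the caller (see
#' [climbing_index_trials()]).
#'
#' @param times Numeric vector of per-fly climbing times in seconds; `Inf`
#'   or `NA` marks a fly that failed to climb.
#' @param cutoff Time limit in seconds (default 60).
#' @return Fraction of flies that climbed in time, in `[0, 1]`.
#' @examples
#' climbing_index(c(12, 30, 61, Inf, 45)) # 3 of 5 in time -> 0.6
#' @export
climbing_index <- function(times, cutoff = 60) {
  if (!is.numeric(times) || length(times) < 1) {
    stop_invalid("`times` must be a non-empty numeric vector")
  }
  check_number(cutoff, "cutoff", lower = 0, strict_lower = TRUE)
  if (any(times < 0, na.rm = TRUE)) {
    stop_invalid("invalid measurement: negative climbing time")
  }
  score <- !is.na(times) & times <= cutoff
  mean(score)
}

#' Mean climbing index across repeated trials
#'
#' @param trials A list of per-trial climbing-time vectors.
#' @param cutoff Time limit in seconds (default 60).
#' @return Mean of the per-trial indices.
#' @export
climbing_index_trials <- function(trials, cutoff = 60) {
  stopifnot(is.list(trials), length(trials) >= 1)
  mean(vapply(trials, climbing_index, numeric(1), cutoff = cutoff))
}

#' Evaporation-corrected capillary feeding intake
#'
#' The fluid-level drop of a fly-free control chamber measures evaporation;
#' subtracting it from the experimental chamber's drop and dividing by the
#' number of flies gives the volume consumed per fly. Negative corrected
#' intakes (evaporation draw exceeding the experimental drop) are retained
#' and flagged rather than clamped, so the estimation layer sees unbiased
#' values.
#'
#' @param level_drop_exp Capillary level drop in the experimental chamber
#'   (ul, >= 0). Vectorised.
#' @param level_drop_control Level drop in the paired fly-free chamber (ul,
#'   >= 0). Vectorised.
#' @param n_flies Flies per experimental chamber (default 1).
#' @param duration Assay duration in hours (default 6); recorded, not used
#'   in the division.
#' @return A tibble with columns `intake_ul_per_fly`, `flagged` (TRUE when
#'   the corrected intake is <= 0), `n_flies`, `duration_h`.
#' @examples
#' cafe_intake(0.20, 0.05)          # 0.15 ul per fly
#' cafe_intake(1.60, 0.10, n_flies = 10) # 0.15 ul per fly
#' @export
cafe_intake <- function(level_drop_exp, level_drop_control, n_flies = 1,
                        duration = 6) {
  if (!is.numeric(level_drop_exp) || !is.numeric(level_drop_control)) {
    stop_invalid("capillary drops must be numeric")
  }
  if (any(level_drop_exp < 0) || any(level_drop_control < 0)) {
    stop_invalid("malformed reading: capillary level drops must be >= 0")
  }
  n_flies <- check_count(n_flies, "n_flies")
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  intake <- (level_drop_exp - level_drop_control) / n_flies
  tibble::tibble(
    intake_ul_per_fly = intake,
    flagged = intake <= 0,
    n_flies = n_flies,
    duration_h = duration
  )
}

#' Respirometry rate from capillary displacement
#'
#' CO2 produced by the fly is absorbed in the chamber; the resulting volume
#' change displaces the indicator column in the capillary, and the rate is
#' the displaced volume per fly per hour.
#'
#' @param volume Displaced volume over the measurement period (ul, >= 0).
#'   Vectorised.
#' @param duration Measurement period in hours (default 1).
#' @param n_flies Flies per chamber (default 1).
#' @return Rate in ul/fly/h.
#' @examples
#' vco2_rate(2.5)          # 2.5 ul/fly/h
#' vco2_rate(1.2, duration = 0.5) # 2.4 ul/fly/h
#' @export
vco2_rate <- function(volume, duration = 1, n_flies = 1) {
  if (!is.numeric(volume)) stop_invalid("`volume` must be numeric")
  if (any(volume < 0)) stop_invalid("malformed reading: negative volume")
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  n_flies <- check_count(n_flies, "n_flies")
  volume / (duration * n_flies)
}

#' Body composition from wet, dry and lean-dry mass
#'
#' Water is the wet-dry difference; lipid is the dry mass lost to ether
#' extraction (dry minus lean dry). The lipid percentage is reported
#' relative to dry mass by default; the denominator choice is echoed in the
#' output so downstream tables are self-describing.
#'
#' @param wet,dry,lean_dry Masses in mg with `wet >= dry >= lean_dry >= 0`.
#'   Vectorised.
#' @param pct_denominator `"dry"` (default) or `"wet"`: the base for the
#'   lipid percentage.
#' @return A tibble with columns `water_mg`, `lipid_mg`, `lipid_pct`,
#'   `pct_denominator`.
#' @examples
#' body_composition(1.0, 0.30, 0.25) # lipid 0.05 mg, water 0.7 mg
#' @export
body_composition <- function(wet, dry, lean_dry,
                             pct_denominator = c("dry", "wet")) {
  pct_denominator <- match.arg(pct_denominator)
  if (!is.numeric(wet) || !is.numeric(dry) || !is.numeric(lean_dry)) {
    stop_invalid("masses must be numeric")
  }
  if (any(lean_dry < 0)) stop_invalid("ordering error: negative lean dry mass")
  if (any(dry < lean_dry)) {
    stop_invalid("ordering error: lean dry mass exceeds dry mass")
  }
  if (any(wet < dry)) stop_invalid("ordering error: dry mass exceeds wet mass")
  lipid <- dry - lean_dry
  base <- if (pct_denominator == "dry") dry else wet
  tibble::tibble(
    water_mg = wet - dry,
    lipid_mg = lipid,
    lipid_pct = ifelse(base > 0, 100 * lipid / base, NA_real_),
    pct_denominator = pct_denominator
  )
}
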