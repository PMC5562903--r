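# The published effect-size matrix and figure-legend contrasts for the
# five-driver neuronal-silencing panel. These printed values serve two
# purposes: they are the default ground-truth effect structure of
# scenario_config(), and they parameterise estimator-recovery simulations
# (simulate the design at the printed effect size and sample sizes, check
# the estimator's mean recovers the printed value).

#' Published driver-by-metric effect-size matrix
#'
#' The summary effect matrix for the five driver lines across the fourteen
#' metrics: Hedges' g everywhere except the ordinal alcove-entry count,
#' which is reported as Cliff's delta. Effects are induced (treatment)
#' minus uninduced (control).
#'
#' @return A tibble with columns `driver`, `metric`, `estimator`, `effect`.
#' @export
published_effects <- function() {
  m <- tibble::tribble(
    ~metric,           ~TH,    ~Ddc,   ~Tdc2,  ~Trh,   ~NPF,
    "activity",        -1.24,  -0.53,  +0.65,  -0.09,  -0.14,
    "climbing",        -1.55,  -0.35,  +0.41,  -0.56,  -0.00,
    "intake_single",   +0.29,  -0.76,  -0.90,  +0.53,  -1.13,
    "intake_group",    +0.11,  -1.63,  -1.82,  +2.36,  -1.59,
    "entries",         -0.62,  -0.08,  -0.24,  +0.15,  -0.09,
    "time_to_alcove",  +0.12,  -0.06,  +0.27,  -0.11,  +0.10,
    "path_efficiency", +0.32,  +0.00,  +0.18,  +0.24,  -0.08,
    "distance",        -0.55,  -0.10,  -0.24,  -0.25,  +0.02,
    "vco2_fed",        -0.26,  +0.37,  -0.34,  +0.00,  -0.68,
    "vco2_starved",    -0.80,  -0.94,  -0.28,  +1.14,  +0.11,
    "lipid_fed",       -0.35,  -0.21,  +0.06,  +0.01,  +0.11,
    "lipid_starved",   -0.03,  +0.03,  -1.38,  -0.16,  -0.07,
    "weight_fed",      +0.04,  -0.35,  +0.21,  -0.05,  +0.97,
    "weight_starved",  -0.36,  -0.28,  +0.05,  +0.00,  +0.10
  )
  long <- tidyr::pivot_longer(m, -"metric", names_to = "driver",
                              values_to = "effect")
  long$estimator <- ifelse(long$metric == "entries", "delta", "g")
  long[, c("driver", "metric", "estimator", "effect")]
}

#' Published figure-legend contrasts with sample sizes
#'
#' The individual contrasts reported in the figure legends, carrying the
#' raw difference (`delta_raw`, native units) where printed and the control
#' and treatment sample sizes. These are the inputs for parameter-recovery
#' simulations at the published design points.
#'
#' @return A tibble with columns `driver`, `metric`, `estimator`, `effect`,
#'   `delta_raw`, `n_c`, `n_t`.
#' @export
published_contrasts <- function() {
  tibble::tribble(
    ~driver,   ~metric,         ~estimator, ~effect,  ~delta_raw, ~n_c, ~n_t,
    "TH",      "activity",      "g",        -1.24,    -0.25,      82,   83,
    "Ddc",     "activity",      "g",        -0.53,    -0.10,      NA,   NA,
    "Tdc2",    "activity",      "g",        +0.65,    NA,         78,   91,
    "TH",      "climbing",      "g",        -1.55,    -0.45,      10,   10,
    "Trh",     "climbing",      "g",        -0.56,    -0.08,      10,   10,
    "control", "intake_single", "g",        +0.46,    +0.05,      29,   48,
    "Ddc",     "intake_single", "g",        -0.76,    -0.11,      51,   44,
    "Tdc2",    "intake_single", "g",        -0.92,    -0.14,      54,   48,
    "Trh",     "intake_single", "g",        +0.53,    +0.08,      33,   49,
    "NPF",     "intake_single", "g",        -1.125,   -0.15,      45,   56,
    "Ddc",     "intake_group",  "g",        -1.63,    -0.16,      NA,   NA,
    "Tdc2",    "intake_group",  "g",        -1.82,    -0.22,      NA,   NA,
    "Trh",     "intake_group",  "g",        +2.36,    +0.19,      NA,   NA,
    "NPF",     "intake_group",  "g",        -1.59,    -0.12,      NA,   NA,
    "TH",      "entries",       "delta",    -0.62,    NA,         82,   75,
    "Tdc2",    "entries",       "delta",    -0.24,    NA,         NA,   NA,
    "TH",      "distance",      "g",        -0.63,    -65,        82,   75,
    "control", "vco2_fed",      "g",        -0.59,    -0.81,      51,   27,
    "NPF",     "vco2_fed",      "g",        -0.6835,  -0.85,      51,   52,
    "TH",      "vco2_starved",  "g",        -0.60,    -1.63,      17,   37,
    "Ddc",     "vco2_starved",  "g",        -0.96,    -1.32,      55,   45,
    "Trh",     "vco2_starved",  "g",        +1.14,    +3.44,      71,   41,
    "Tdc2",    "lipid_starved", "g",        -1.38,    -6.08,      NA,   NA,
    "NPF",     "weight_fed",    "g",        +0.97,    +0.14,      NA,   NA
  )
}
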