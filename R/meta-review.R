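# Summary-statistics standardized mean differences for the systematic-review
# synthesis: Hedges' g with normal-theory confidence intervals computed from
# digitized per-group means, dispersions and sample sizes, assembled into a
# forest-plot table grouped by neuromodulator and manipulation direction.
# No pooling or heterogeneity statistics: experiments are presented side by
# side.

#' Standardized mean difference from per-group summary statistics
#'
#' Computes Hedges' g (bias-corrected standardized mean difference) from
#' digitized group means, dispersions and sample sizes. SEM dispersions are
#' first converted to SDs via `SD = SEM * sqrt(n)`. The sampling variance
#' uses the standard large-sample formula on the d scale,
#' `var(d) = (n_c + n_t) / (n_c * n_t) + d^2 / (2 (n_c + n_t))`, scaled by
#' `J^2`, and the 95% CI is Wald (`g +/- 1.96 * sqrt(var)`). This
#' normal-theory interval is used because only summary statistics are
#' available for literature records; it is labelled `ci_method = "wald"` to
#' distinguish it from the bootstrap intervals computed on raw data.
#'
#' @param records A data frame of extracted experiments with columns
#'   `mean_c`, `mean_t`, `dispersion_c`, `dispersion_t`, `dispersion_kind`
#'   (`"SD"` or `"SEM"`), `n_c`, `n_t`; further columns (study labels,
#'   `neuromodulator`, `manipulation`, `assay`, `digitized_from`) are
#'   carried through.
#' @param level Confidence level (default 0.95).
#' @return The input tibble with added columns `g`, `var_g`, `ci_low`,
#'   `ci_high`, `ci_method`, `magnitude`.
#' @examples
#' smd_from_summary(data.frame(
#'   mean_c = 10, mean_t = 12, dispersion_c = 2, dispersion_t = 2,
#'   dispersion_kind = "SD", n_c = 16, n_t = 16
#' ))$g # 0.9748
#' @export
smd_from_summary <- function(records, level = 0.95) {
  records <- tibble::as_tibble(records)
  need <- c("mean_c", "mean_t", "dispersion_c", "dispersion_t",
            "dispersion_kind", "n_c", "n_t")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop_invalid("invalid record: missing column `", miss[1], "`")
  }
  if (any(records$dispersion_c <= 0 | records$dispersion_t <= 0)) {
    stop_invalid("invalid record: dispersions must be > 0")
  }
  if (any(records$n_c < 2 | records$n_t < 2)) {
    stop_invalid("invalid record: n must be >= 2 per arm")
  }
  kind <- toupper(records$dispersion_kind)
  if (!all(kind %in% c("SD", "SEM"))) {
    stop_invalid("invalid record: dispersion_kind must be \"SD\" or \"SEM\"")
  }
  sd_c <- ifelse(kind == "SEM", records$dispersion_c * sqrt(records$n_c),
                 records$dispersion_c)
  sd_t <- ifelse(kind == "SEM", records$dispersion_t * sqrt(records$n_t),
                 records$dispersion_t)
  n_c <- records$n_c
  n_t <- records$n_t
  df <- n_c + n_t - 2
  s_p <- sqrt(((n_c - 1) * sd_c^2 + (n_t - 1) * sd_t^2) / df)
  d <- (records$mean_t - records$mean_c) / s_p
  j <- hedges_j(df)
  g <- j * d
  var_g <- j^2 * ((n_c + n_t) / (n_c * n_t) + d^2 / (2 * (n_c + n_t)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  records$g <- g
  records$var_g <- var_g
  records$ci_low <- g - z * sqrt(var_g)
  records$ci_high <- g + z * sqrt(var_g)
  records$ci_method <- "wald"
  records$magnitude <- vapply(g, classify_magnitude, character(1), kind = "g")
  records
}

#' Read digitized experiment records for the review synthesis
#'
#' The CSV must mirror the extracted-experiment schema and carry a
#' `digitized_from` provenance column identifying the figure or table each
#' record was measured from.
#'
#' @param path CSV path.
#' @return A validated tibble of extracted experiments.
#' @export
read_extracted_experiments <- function(path) {
  rec <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("study", "figure_panel", "neuromodulator", "manipulation",
            "assay", "mean_c", "mean_t", "dispersion_c", "dispersion_t",
            "dispersion_kind", "n_c", "n_t", "digitized_from")
  miss <- setdiff(need, names(rec))
  if (length(miss)) {
    stop_invalid("invalid record file: missing column `", miss[1], "`")
  }
  if (!all(rec$manipulation %in% c("activator", "inhibitor"))) {
    stop_invalid("invalid record: manipulation must be activator or inhibitor")
  }
  rec
}

#' Forest-plot table of summary-level standardized effects
#'
#' Computes the SMD for each record and orders rows by neuromodulator,
#' then manipulation (activators before inhibitors), then study and panel
#' -- the layout of a grouped forest plot. No pooled estimate is added.
#'
#' @inheritParams smd_from_summary
#' @return An ordered tibble with one forest row per experiment.
#' @export
forest_table <- function(records, level = 0.95) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    return(records)
  }
  out <- smd_from_summary(records, level = level)
  sort_cols <- intersect(c("neuromodulator", "manipulation", "study",
                           "figure_panel"), names(out))
  dplyr::arrange(out, dplyr::across(dplyr::all_of(sort_cols)))
}

#' Forest plot of summary-level standardized effects
#'
#' Point-and-interval display of the [forest_table()] rows, grouped by
#' neuromodulator, with a reference line at zero.
#'
#' @param table Output of [forest_table()].
#' @return A ggplot object.
#' @export
forest_plot <- function(table) {
  stopifnot(all(c("g", "ci_low", "ci_high") %in% names(table)))
  table$row_label <- paste(table$study, table$figure_panel, table$assay,
                           sep = " / ")
  table$row_label <- factor(table$row_label, levels = rev(table$row_label))
  ggplot2::ggplot(table, ggplot2::aes(x = .data$g, y = .data$row_label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high,
                                          colour = .data$manipulation)) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$neuromodulator),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "Hedges' g (95% CI)", y = NULL,
                  colour = "Manipulation") +
    ggplot2::theme_minimal()
}
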