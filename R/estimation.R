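# Estimation-statistics engine: raw differences, standardized effect sizes,
# bootstrap confidence intervals, pro-forma P values and magnitude labels.
# The reporting philosophy is estimation-based: effect sizes with interval
# estimates are the primary output, P values are carried along pro forma only
# and no significance-testing machinery is built on top of them.

check_sample <- function(x, name, min_n = 1L) {
  if (!is.numeric(x)) stop_invalid("`", name, "` must be numeric")
  x <- x[!is.na(x)]
  if (length(x) < min_n) {
    stop_invalid("insufficient data: `", name, "` has fewer than ", min_n,
                 " non-missing values")
  }
  if (any(!is.finite(x))) stop_invalid("`", name, "` contains non-finite values")
  x
}

#' Raw mean difference between treatment and control
#'
#' The direction convention throughout the package is treatment minus
#' control (induced minus uninduced), so a negative difference means the
#' manipulated group scored lower.
#'
#' @param control,treatment Numeric vectors of per-unit measurements.
#' @return The mean difference `mean(treatment) - mean(control)`.
#' @examples
#' mean_difference(c(1, 3), c(2, 4))
#' @export
mean_difference <- function(control, treatment) {
  control <- check_sample(control, "control")
  treatment <- check_sample(treatment, "treatment")
  mean(treatment) - mean(control)
}

#' Hedges' g standardized mean difference
#'
#' Cohen's d computed with the df-weighted pooled standard deviation,
#' multiplied by the small-sample bias correction
#' `J = 1 - 3 / (4 * df - 1)` with `df = n_c + n_t - 2`. A g of 1 means the
#' two groups differ by one pooled standard deviation.
#'
#' @inheritParams mean_difference
#' @return Hedges' g (dimensionless).
#' @examples
#' hedges_g(c(2, 3, 4), c(0, 1, 2)) # d = -2, J = 0.8 -> -1.6
#' @export
hedges_g <- function(control, treatment) {
  control <- check_sample(control, "control", min_n = 2L)
  treatment <- check_sample(treatment, "treatment", min_n = 2L)
  n_c <- length(control)
  n_t <- length(treatment)
  df <- n_c + n_t - 2
  s_p <- sqrt(((n_c - 1) * stats::var(control) +
                 (n_t - 1) * stats::var(treatment)) / df)
  diff <- mean(treatment) - mean(control)
  if (s_p == 0) {
    if (diff == 0) return(0)
    stop_invalid("degenerate variance: pooled SD is zero but the means differ")
  }
  hedges_j(df) * diff / s_p
}

# Small-sample correction factor.
hedges_j <- function(df) 1 - 3 / (4 * df - 1)

#' Cliff's delta dominance statistic
#'
#' The probability-difference that a treatment value exceeds a control value:
#' the number of (t, c) pairs with t > c, minus the number with t < c, over
#' `n_t * n_c`, ties contributing zero. Ranges
#' from -1 (all treatment values below all control values) through 0 (the
#' two samples interleave evenly) to +1. Suited to ordinal data such as
#' counts of alcove entries, where a mean-and-SD summary is inappropriate.
#'
#' Computed via midranks in O(n log n); an explicit all-pairs enumeration
#' gives the identical value.
#'
#' @inheritParams mean_difference
#' @return Cliff's delta in `[-1, 1]`.
#' @examples
#' cliffs_delta(c(0, 0, 4), c(1, 2, 3)) # 1/3
#' @export
cliffs_delta <- function(control, treatment) {
  control <- check_sample(control, "control")
  treatment <- check_sample(treatment, "treatment")
  n_c <- length(control)
  n_t <- length(treatment)
  r <- rank(c(treatment, control))
  u_t <- sum(r[seq_len(n_t)]) - n_t * (n_t + 1) / 2 # Mann-Whitney U with midranks
  2 * u_t / (n_c * n_t) - 1
}

#' Percentile bootstrap confidence interval for a two-sample statistic
#'
#' Each group is resampled with replacement at its own size, independently,
#' `B` times; the interval is the percentile (default) or BCa interval of
#' the statistic over the resamples. Fully seeded and reproducible.
#'
#' @inheritParams mean_difference
#' @param statistic `"mean_difference"`, `"hedges_g"`, `"cliffs_delta"`
#'   (fast vectorised paths) or a `function(control, treatment)`.
#' @param B Number of bootstrap resamples (>= 1000).
#' @param level Confidence level, default 0.95.
#' @param seed Integer seed; `NULL` uses the ambient RNG state.
#' @param method `"percentile"` (default) or `"bca"` (bias-corrected and
#'   accelerated, with jackknife acceleration).
#' @return Named numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(control, treatment, statistic = "mean_difference",
                         B = 10000, level = 0.95, seed = NULL,
                         method = c("percentile", "bca")) {
  method <- match.arg(method)
  control <- check_sample(control, "control", min_n = 2L)
  treatment <- check_sample(treatment, "treatment", min_n = 2L)
  B <- check_count(B, "B", min = 1000L)
  check_number(level, "level", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  fun <- resolve_statistic(statistic)
  boot <- with_seed(seed, bootstrap_replicates(control, treatment, statistic, B))
  alpha <- 1 - level
  if (method == "percentile") {
    q <- stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                         type = 7)
  } else {
    q <- bca_interval(boot, fun, control, treatment, alpha)
  }
  c(low = q[1], high = q[2])
}

resolve_statistic <- function(statistic) {
  if (is.function(statistic)) return(statistic)
  switch(statistic,
    mean_difference = mean_difference,
    hedges_g = hedges_g,
    cliffs_delta = cliffs_delta,
    stop_invalid("unknown statistic `", statistic, "`")
  )
}

# Vectorised bootstrap draws. Index matrices are chunked so memory stays
# bounded (~20M cells per chunk) even at large n * B.
bootstrap_replicates <- function(control, treatment, statistic, B) {
  if (is.function(statistic)) {
    n_c <- length(control)
    n_t <- length(treatment)
    return(vapply(seq_len(B), function(i) {
      statistic(control[sample.int(n_c, n_c, replace = TRUE)],
                treatment[sample.int(n_t, n_t, replace = TRUE)])
    }, numeric(1)))
  }
  n_c <- length(control)
  n_t <- length(treatment)
  chunk <- max(1L, min(B, as.integer(2e7 / max(n_c, n_t))))
  out <- numeric(0)
  done <- 0L
  while (done < B) {
    b <- min(chunk, B - done)
    xc <- matrix(control[sample.int(n_c, n_c * b, replace = TRUE)], n_c, b)
    xt <- matrix(treatment[sample.int(n_t, n_t * b, replace = TRUE)], n_t, b)
    out <- c(out, boot_stat_chunk(xc, xt, statistic))
    done <- done + b
  }
  out
}

boot_stat_chunk <- function(xc, xt, statistic) {
  n_c <- nrow(xc)
  n_t <- nrow(xt)
  b <- ncol(xc)
  m_c <- .colMeans(xc, n_c, b)
  m_t <- .colMeans(xt, n_t, b)
  if (statistic == "mean_difference") {
    return(m_t - m_c)
  }
  if (statistic == "hedges_g") {
    v_c <- (.colMeans(xc * xc, n_c, b) - m_c^2) * n_c / (n_c - 1)
    v_t <- (.colMeans(xt * xt, n_t, b) - m_t^2) * n_t / (n_t - 1)
    df <- n_c + n_t - 2
    s_p <- sqrt(((n_c - 1) * v_c + (n_t - 1) * v_t) / df)
    g <- hedges_j(df) * (m_t - m_c) / s_p
    g[s_p == 0] <- 0 # constant resample in both arms: no difference either
    return(g)
  }
  # cliffs_delta: rank-based U per column
  vapply(seq_len(b), function(j) {
    r <- rank(c(xt[, j], xc[, j]))
    u_t <- sum(r[seq_len(n_t)]) - n_t * (n_t + 1) / 2
    2 * u_t / (n_c * n_t) - 1
  }, numeric(1))
}

bca_interval <- function(boot, fun, control, treatment, alpha) {
  theta <- fun(control, treatment)
  prop <- mean(boot < theta)
  if (prop <= 0 || prop >= 1) {
    # degenerate bootstrap distribution; fall back to percentile
    return(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), names = FALSE))
  }
  z0 <- stats::qnorm(prop)
  jack <- c(
    vapply(seq_along(control), function(i) fun(control[-i], treatment), numeric(1)),
    vapply(seq_along(treatment), function(i) fun(control, treatment[-i]), numeric(1))
  )
  d <- mean(jack) - jack
  denom <- 6 * sum(d^2)^1.5
  a <- if (denom == 0) 0 else sum(d^3) / denom
  z <- stats::qnorm(c(alpha / 2, 1 - alpha / 2))
  adj <- stats::pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  stats::quantile(boot, adj, names = FALSE)
}

#' Two-sided Mann-Whitney U P value, for pro-forma reporting
#'
#' Exact enumeration when `n_c * n_t <= 400` and the samples are tie-free;
#' otherwise the tie-corrected normal approximation (no continuity
#' correction). The value is carried for reporting convention only; the
#' package's inferential quantities are effect sizes and their intervals.
#'
#' @inheritParams mean_difference
#' @param exact_max Largest `n_c * n_t` for which exact enumeration is used.
#' @return Two-sided P value.
#' @export
mann_whitney_p <- function(control, treatment, exact_max = 400) {
  control <- check_sample(control, "control")
  treatment <- check_sample(treatment, "treatment")
  has_ties <- anyDuplicated(c(control, treatment)) > 0
  use_exact <- !has_ties && length(control) * length(treatment) <= exact_max
  p <- suppressWarnings(stats::wilcox.test(
    treatment, control,
    exact = use_exact, correct = FALSE
  )$p.value)
  min(p, 1)
}

#' Magnitude label for a standardized effect size
#'
#' Conventional descriptive bins applied to the absolute effect. For
#' Hedges' g: negligible below 0.2, small to 0.5, moderate to 0.8, large
#' beyond. For Cliff's delta: negligible below 0.147, small to 0.33, medium
#' to 0.47, large beyond. Bins are half-open on the left, so the boundary
#' value falls in the higher bin.
#'
#' @param effect Effect size (sign is ignored).
#' @param kind `"g"` or `"delta"`.
#' @return A label string.
#' @examples
#' classify_magnitude(0.53, "g")
#' classify_magnitude(-0.10, "delta")
#' @export
classify_magnitude <- function(effect, kind = c("g", "delta")) {
  kind <- match.arg(kind)
  if (!is.numeric(effect) || length(effect) != 1L || !is.finite(effect)) {
    stop_invalid("`effect` must be a single finite number")
  }
  a <- abs(effect)
  if (kind == "g") {
    cuts <- c(0.2, 0.5, 0.8)
    labs <- c("negligible", "small", "moderate", "large")
  } else {
    cuts <- c(0.147, 0.33, 0.47)
    labs <- c("negligible", "small", "medium", "large")
  }
  labs[findInterval(a, cuts) + 1L]
}

#' Full effect estimate for one two-group contrast
#'
#' Bundles the raw mean difference, the standardized effect (Hedges' g for
#' continuous metrics, Cliff's delta for ordinal ones), its bootstrap 95%
#' confidence interval, a pro-forma Mann-Whitney P value, sample sizes and a
#' magnitude label into one tidy row.
#'
#' @inheritParams mean_difference
#' @param metric Optional metric label carried into the output.
#' @param estimator `"g"` or `"delta"`.
#' @param B,level,seed,ci_method Passed to [bootstrap_ci()].
#' @return A one-row tibble (class `fly_effect`) with columns `metric`,
#'   `estimator`, `delta_raw`, `effect`, `ci_low`, `ci_high`, `p_proforma`,
#'   `n_c`, `n_t`, `magnitude`, `B`, `level`, `seed`.
#' @export
estimate_effect <- function(control, treatment, metric = NA_character_,
                            estimator = c("g", "delta"), B = 10000,
                            level = 0.95, seed = NULL,
                            ci_method = "percentile") {
  estimator <- match.arg(estimator)
  control <- check_sample(control, "control", min_n = 2L)
  treatment <- check_sample(treatment, "treatment", min_n = 2L)
  stat_name <- if (estimator == "g") "hedges_g" else "cliffs_delta"
  effect <- resolve_statistic(stat_name)(control, treatment)
  ci <- bootstrap_ci(control, treatment, stat_name, B = B, level = level,
                     seed = seed, method = ci_method)
  tibble::new_tibble(tibble::tibble(
    metric = as.character(metric),
    estimator = estimator,
    delta_raw = mean_difference(control, treatment),
    effect = effect,
    ci_low = unname(ci[1]),
    ci_high = unname(ci[2]),
    p_proforma = mann_whitney_p(control, treatment),
    n_c = length(control),
    n_t = length(treatment),
    magnitude = classify_magnitude(effect, kind = if (estimator == "g") "g" else "delta"),
    B = as.integer(B),
    level = level,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  ), class = "fly_effect")
}
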