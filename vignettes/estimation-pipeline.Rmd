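---
title: "Estimation statistics for a fly behavioural and metabolic assay panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimation statistics for a fly behavioural and metabolic assay panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyfx)
```

## The problem flyfx addresses

Circuit-silencing experiments in *Drosophila* ask whether switching off a
neuromodulatory system (dopaminergic, serotonergic, octopaminergic/
tyraminergic or NPF-ergic neurons, silenced by warm-induced Kir2.1
expression) changes feeding, locomotion and metabolism in a coordinated
way. The readouts span eleven assays and fourteen metrics: an activity
index and climbing index; single-fly and group capillary feeding (CAFE)
intake; four foraging-chip metrics (alcove entries, latency, path
efficiency, distance travelled); respirometry in fed and starved states;
and lipid content and body weight in fed and starved states. Every
contrast is a two-arm comparison — uninduced control versus induced
silencing — summarised not by significance tests but by estimation
statistics: raw mean differences, standardized effect sizes (Hedges' *g*,
or Cliff's delta for ordinal counts) and bootstrap 95% confidence
intervals, with Mann–Whitney *P* values carried pro forma only.

flyfx implements that full analysis as a tested pipeline. Because raw
recordings are not bundled with the package, it also ships a first-class
synthetic-data layer that generates raw-assay files with *known*
ground-truth effects, so every estimator can be validated by parameter
recovery rather than against an unavailable dataset.

## The estimation engine

For control sample $C$ (size $n_C$) and treatment sample $T$ (size $n_T$),
all effects follow the treatment-minus-control (induced minus uninduced)
sign convention.

**Hedges' g.** With pooled SD
$s_p^2 = \frac{(n_C-1)s_C^2 + (n_T-1)s_T^2}{n_C+n_T-2}$,

$$g = J \cdot \frac{\bar T - \bar C}{s_p}, \qquad
J = 1 - \frac{3}{4(n_C+n_T-2) - 1},$$

the small-sample correction $J$ being applied always. A *g* of 1 means the
groups differ by one pooled standard deviation.

**Cliff's delta.** For ordinal data (alcove-entry counts),
$\delta = \frac{\#\{t > c\} - \#\{t < c\}}{n_T n_C} \in [-1, 1]$, ties
contributing zero. It is computed via midranks in $O(n \log n)$; the
test-suite oracle is the explicit all-pairs enumeration.

**Confidence intervals.** Percentile bootstrap by default: each group is
resampled with replacement at its own size, independently, $B = 10{,}000$
times (configurable, always logged together with the seed), and the
interval is the $\alpha/2$ and $1-\alpha/2$ percentile of the statistic.
BCa is available behind `method = "bca"`. The same engine covers the mean
difference, *g* and delta — including delta, for which some
implementations instead use an analytic variance; we prefer one uniform
resampling scheme and label the method in every output row. Summary-level
literature records (below) are the one exception: with only means, SEMs
and *n* available, `smd_from_summary()` uses the standard large-sample
variance $\mathrm{var}(g) = J^2\!\left[\frac{n_C+n_T}{n_C n_T} +
\frac{d^2}{2(n_C+n_T)}\right]$ with Wald limits, labelled
`ci_method = "wald"`.

**P values.** `mann_whitney_p()` is exact (via `wilcox.test`) when
$n_C n_T \le 400$ and the samples are tie-free, and otherwise uses the
tie-corrected normal approximation without continuity correction. The
output is labelled pro forma; no testing decisions are built on it.

**Magnitude labels.** Conventional descriptive bins on the absolute
effect, half-open on the left: for *g* negligible $<0.2$, small $<0.5$,
moderate $<0.8$, large beyond; for delta negligible $<0.147$, small
$<0.33$, medium $<0.47$, large beyond. The effect-matrix *emphasis* flag
is a separate, stricter rule: $|g| > 0.50$ or $|\delta| > 0.47$, strict
inequalities, so $g = 0.50$ is not emphasised.

## Trajectory and assay metrics

**Activity index**: the proportion of 0.5 s bins, aligned to the
trajectory start (trailing partial bin discarded), in which the fly moved
at least 1 mm. The bin rule's "moved" is ambiguous between summed path
length and net displacement; path length is the default (the stricter
reading) and `method = "net"` provides the alternative. The bin comparison
carries 1 nm of slack so float accumulation cannot flip a boundary bin.

**Exclusion rule**: a fly is excluded for an epoch when total distance
< 200 mm or activity index < 10%, with the reason recorded; the
inequalities are strict, so boundary epochs are kept.

**Foraging sessions**: six food epochs of at most 100 s, separated by
120 s; food is withdrawn at the first alcove entry or at timeout. An entry
is two consecutive samples inside the alcove polygon (point-in-polygon via
`mgcv::in.out`), a debounce against single-frame jitter. Task performance
is successful epochs over total epochs. Path efficiency is the
straight-line distance from the epoch-start position to the entry point
divided by the path length travelled from food-on to entry — defined this
way the invariant "in $(0, 1]$, with equality exactly for straight
monotone runs" holds exactly. Censored (no-entry) epochs count toward task
performance but contribute no latency or path metrics, matching plots that
show successful epochs only. All time windows are half-open `[start, end)`
and steps are indexed by their start sample, which makes travelled
distance exactly additive over adjacent windows.

**Scalar assays**: climbing index scores each fly 1 if it reaches the mark
within 60 s (inclusive) else 0, averaged per trial and then across trials;
CAFE intake is (experimental drop − paired fly-free control drop)/flies,
with non-positive corrected intakes flagged, never clamped; respirometry
rate is displaced volume per fly per hour; body composition takes
lipid = dry − lean-dry and water = wet − dry, reporting lipid as a
percentage of dry mass by default (the denominator is configurable and
always echoed in the output, since published percentage-point changes do
not always state their base).

## What the synthetic generator emulates — and what it does not

`gen_trajectory()` runs a two-state (move/pause) correlated random walk in
a 20 × 22 mm arena with reflective walls: per 0.1 s step the fly pauses
with probability `pause_probability`, otherwise advances
`move_speed_mean`/`sample_rate` mm along a heading with angular noise
scaled by `1 − heading_persistence`. Defaults (10 Hz, 10 mm/s, pause 0.2,
persistence 0.7) give non-degenerate activity indices and path metrics;
source video frame rates are typically unstated, so 10 Hz is a choice, not
a datum. `gen_snac_session()` adds the epoch schedule and, while food is
on, blends the heading toward the alcove with weight `alcove_bias`
(`1` = deterministic beeline, used in tests to force task performance 1).

`gen_assay_bundle()` generates the full driver × metric panel with
configured true standardized effects. Points worth knowing:

* **Evaporation budgeting.** The paired-control CAFE correction *adds*
  evaporation noise ($2 s_e^2 / n_{\text{flies}}^2$) to the corrected
  intake; the generator draws the latent intake with that variance
  removed, so the corrected metric has exactly the configured SD and SMD.
* **Bounded metrics attenuate.** Activity is clamped to [0, 1], climbing
  indices live on a five-fly grid, entry counts are rounded to 0–6 from a
  latent normal shifted by `calibrate_latent_shift(delta)` =
  $\sqrt{2}\,\Phi^{-1}\!\big(\tfrac{\delta+1}{2}\big)$. Clamping and
  discretisation attenuate very large configured effects slightly; a null
  effect is preserved exactly. Estimator-recovery validation therefore
  uses the continuous generator (`gen_two_group()`), and the end-to-end
  null check uses the bundle.
* **Summary-level trajectory metrics.** The bundle emits activity and the
  four foraging metrics per fly at metric level, as tracking software
  would, rather than as raw trajectories: simulating 13,000-step sessions
  for a thousand flies per cell would add hours of compute without
  changing what the effect matrix measures. The raw-trajectory path is
  exercised end to end by `gen_trajectory`/`gen_snac_session` →
  `snac_metrics` at realistic single-fly scale.
* **Seeding.** Every cell draws from a substream derived from the root
  seed and the `driver/metric` key, so identical configs are byte-identical
  and adding one assay never perturbs another. Real data features *not*
  emulated: circadian structure, tracking noise and identity swaps,
  within-arena spatial preferences, and between-day batch effects —
  passing tests say nothing about those.

The default scenario's ground-truth effect matrix is the published
five-driver panel (`published_effects()`), with baseline means and SDs set
to assay-plausible values (e.g. activity 0.50 ± 0.20, reproducing the
printed raw activity difference of −0.25 alongside g = −1.24; distance
250 ± 103 mm consistent with the printed −65 mm at g ≈ −0.6). The
uninduced-baseline elevation seen in some published driver lines relative
to driverless controls is exposed as the per-metric `baseline` knob; the
package takes no position on its mechanism.

## Validation strategy and problem sizes

The test suite validates each layer against independent oracles:
brute-force pair enumeration for Cliff's delta (200 random fixtures);
hand-computed fixtures for *g*, exact Mann–Whitney, intake, respirometry
and lipid arithmetic; `metafor::escalc` as a cross-check of the
summary-level SMD; a 1000-replicate coverage study of the percentile
bootstrap (n = 30/arm, B = 1000, coverage required within 95 ± 2%); and
parameter recovery at the published design points (2000 replicates per
contrast at the printed *n*, mean estimate within ±0.05 for *g*, ±0.03
for delta, ±0.01 for the raw activity difference). The end-to-end null
check runs the full 14 × 5 pipeline at n = 500/arm with B = 2000 and
requires zero emphasis flags. These sizes keep the default suite under
about a minute while leaving Monte-Carlo error well inside each
tolerance; `scripts/acceptance.R` re-runs the recovery targets from
scratch at 2000 replicates each.

## Known limitations

* Cliff's-delta intervals come from the bootstrap, not the analytic
  consistent-variance formula some packages use; for very small ordinal
  samples the percentile interval can be narrow.
* The latent-shift calibration for ordinal entries is exact for the latent
  continuous score; rounding to 0–6 shrinks the realised delta for large
  targets (≈7% at δ = −0.62 with the default latent scale).
* Wald CIs for literature records are symmetric and large-sample; with
  n < 10 per arm they undercover.
* The walk model is not a fit to real fly kinematics; it is the simplest
  process making the trajectory metrics non-degenerate.

## A worked example

```{r example, eval = FALSE}
cfg <- scenario_config(n_per_arm = 50, seed = 2026)
run <- run_pipeline(cfg, B = 2000)
run$matrix
subset(run$estimates, driver == "TH" & metric == "activity")

# literature synthesis from digitized summary statistics
records <- read_extracted_experiments(
  system.file("extdata", "meta_records_synthetic.csv", package = "flyfx")
)
forest_table(records)[, c("study", "neuromodulator", "manipulation",
                          "g", "ci_low", "ci_high")]
```
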