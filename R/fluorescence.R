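#' Summarize a per-cell intensity population
#'
#' One-pass outlier trim followed by a geometric summary: cells with mean
#' intensity outside `mean +/- trim_k * SD` (both computed on the raw
#' values) are removed, then the geometric mean, the SD of the surviving
#' intensities, and the surviving cell count `n` are reported. Cell
#' intensity distributions are right-skewed, hence the geometric center;
#' the trim uses the arithmetic moments of the raw values.
#'
#' If the trim would remove every cell (possible only in pathological
#' inputs), the untrimmed summary is returned with `trimmed_out = TRUE`.
#'
#' @param intensities Numeric vector of positive per-cell mean intensities.
#' @param trim_k Trim window half-width in SDs (default 2).
#' @return One-row tibble: `geo_mean, sd, n, n_raw, trimmed_out`.
#' @examples
#' summarize_cells(c(100, 400)) # geo_mean 200
#' @export
summarize_cells <- function(intensities, trim_k = 2) {
  if (length(intensities) == 0L) abort("`intensities` must be non-empty.")
  if (any(!is.finite(intensities)) || any(intensities <= 0)) {
    abort("`intensities` must be finite and strictly positive.")
  }
  m <- mean(intensities)
  s <- sd(intensities)
  keep <- if (is.na(s) || s == 0) rep(TRUE, length(intensities)) else
    abs(intensities - m) <= trim_k * s
  trimmed_out <- !any(keep)
  x <- if (trimmed_out) intensities else intensities[keep]
  tibble(
    geo_mean = geo_mean(x),
    sd = if (length(x) > 1L) sd(x) else 0,
    n = length(x),
    n_raw = length(intensities),
    trimmed_out = trimmed_out
  )
}

#' Build the autofluorescence band from control strains
#'
#' The background autofluorescence band is the mean of the control-strain
#' geometric means with a confidence interval of two standard deviations
#' (of the control geo-means) in each direction, by default. Strains whose
#' pre-induction signal exceeds the brightest non-fluorescent control are
#' considered fluorescent.
#'
#' @param control_geo_means Numeric vector of control-strain geometric
#'   means (>= 2 controls).
#' @param k Band half-width in SDs (default 2).
#' @return List of class `af_band`: `mean, lower, upper, brightest_control,
#'   n_controls, k`.
#' @examples
#' autofluorescence_band(c(90, 100, 110))
#' @export
autofluorescence_band <- function(control_geo_means, k = 2) {
  x <- control_geo_means[is.finite(control_geo_means)]
  if (length(x) < 2L) abort("at least 2 control strains are required.")
  m <- mean(x)
  s <- sd(x)
  structure(
    list(mean = m, lower = m - k * s, upper = m + k * s,
         brightest_control = max(x), n_controls = length(x), k = k),
    class = "af_band"
  )
}

#' @export
print.af_band <- function(x, ...) {
  cat(sprintf(
    "Autofluorescence band: %.1f [%.1f, %.1f] (+/- %g SD, %d controls); brightest control %.1f\n",
    x$mean, x$lower, x$upper, x$k, x$n_controls, x$brightest_control))
  invisible(x)
}

#' Classify one strain's responsiveness to induced degradation
#'
#' Implements the screen decision tree. A strain is *fluorescent* only if
#' its pre-induction geometric mean exceeds the brightest non-fluorescent
#' control; non-fluorescent strains are `not_visible` (optionally
#' `manual_review` for organellar strains examined visually). A strain is
#' *dead* when fewer than `death_fraction` of the pre-induction cell count
#' remains after induction — induction-provoked lethality makes the
#' fluorescence signal uninformative. A surviving fluorescent strain is
#' *responsive* when its post-induction signal is significantly reduced:
#' a one-sided Welch t-test on log intensities, with the p-value intended
#' for panel-wide Benjamini-Hochberg adjustment (see
#' [adjust_strain_calls()]), plus an effect floor (after/before geometric
#' mean ratio below `min_effect`) excluding trivially significant tiny
#' drops. Otherwise it is *irresponsive*.
#'
#' @param before,after Per-cell tibbles (as from [sim_cell_population()];
#'   any tibble with a `mean_intensity` column) for the pre- and
#'   post-induction acquisitions of one strain.
#' @param band An [autofluorescence_band()] object; required.
#' @param alpha Significance level applied after adjustment.
#' @param min_effect Effect-size ceiling: after/before geometric-mean
#'   ratio must fall below this for a responsive call.
#' @param death_fraction Surviving-cell fraction below which the strain is
#'   called dead.
#' @param trim_k Trim window for [summarize_cells()].
#' @param manual_review Mark non-fluorescent strains `manual_review`
#'   instead of `not_visible` (mirrors visual examination of organellar
#'   strains).
#' @return One-row tibble: `strain_id, fluorescent, status, effect,
#'   p_value, p_adj, geo_before, geo_after, n_before, n_after`. `status`
#'   here is provisional (`p_adj = p_value`); run [adjust_strain_calls()]
#'   on the bound rows of a panel to apply BH adjustment and finalize.
#' @export
classify_strain <- function(before, after, band,
                            alpha = 0.05, min_effect = 0.75,
                            death_fraction = 0.25, trim_k = 2,
                            manual_review = FALSE) {
  if (!inherits(band, "af_band")) {
    abort("`band` must be an `af_band` from autofluorescence_band().")
  }
  strain_id <- if ("strain_id" %in% names(before)) before$strain_id[1] else NA_character_
  sb <- summarize_cells(before$mean_intensity, trim_k = trim_k)
  sa <- summarize_cells(after$mean_intensity, trim_k = trim_k)
  fluorescent <- sb$geo_mean > band$brightest_control
  effect <- sa$geo_mean / sb$geo_mean
  dead <- nrow(after) < death_fraction * nrow(before)

  p_value <- NA_real_
  if (fluorescent && !dead) {
    lb <- log(before$mean_intensity)
    la <- log(after$mean_intensity)
    p_value <- tryCatch(
      t.test(la, lb, alternative = "less", var.equal = FALSE)$p.value,
      error = function(e) NA_real_
    )
  }
  status <- if (!fluorescent) {
    if (manual_review) "manual_review" else "not_visible"
  } else if (dead) {
    "dead"
  } else if (!is.na(p_value) && p_value < alpha && effect < min_effect) {
    "responsive"
  } else {
    "irresponsive"
  }
  tibble(
    strain_id = strain_id, fluorescent = fluorescent,
    status = factor(status, levels = c("not_visible", "responsive",
                                       "irresponsive", "dead",
                                       "manual_review")),
    effect = effect, p_value = p_value, p_adj = p_value,
    geo_before = sb$geo_mean, geo_after = sa$geo_mean,
    n_before = sb$n, n_after = sa$n
  )
}

#' Apply panel-wide multiple-testing adjustment to strain calls
#'
#' Benjamini-Hochberg adjusts the reduction-test p-values across the
#' strain panel and re-resolves each provisional `responsive` /
#' `irresponsive` call at `alpha` on the adjusted p-value (the effect
#' floor from [classify_strain()] is re-applied). `not_visible`, `dead`
#' and `manual_review` calls are untouched.
#'
#' @param calls Row-bound output of [classify_strain()] over a panel.
#' @param alpha Significance level on adjusted p-values.
#' @param min_effect Effect-size ceiling (same meaning as in
#'   [classify_strain()]).
#' @param method Adjustment method passed to [stats::p.adjust()].
#' @return `calls` with `p_adj` recomputed and `status` finalized.
#' @export
adjust_strain_calls <- function(calls, alpha = 0.05, min_effect = 0.75,
                                method = "BH") {
  testable <- calls$status %in% c("responsive", "irresponsive") &
    !is.na(calls$p_value)
  calls$p_adj[testable] <- p.adjust(calls$p_value[testable], method = method)
  new_status <- as.character(calls$status)
  new_status[testable] <- ifelse(
    calls$p_adj[testable] < alpha & calls$effect[testable] < min_effect,
    "responsive", "irresponsive")
  calls$status <- factor(new_status, levels = levels(calls$status))
  calls
}

#' Library-level responsiveness summary
#'
#' Aggregates a panel of strain calls into the screen's headline
#' percentages. Two responsive rates are reported because dead strains are
#' fluorescent but uninformative: `pct_responsive_of_fluorescent` uses
#' live fluorescent strains as the denominator, while
#' `pct_responsive_incl_dead` counts dead strains as responding (their
#' protein depletion killed them) over fluorescent + dead.
#'
#' @param calls Row-bound, adjusted strain calls
#'   (see [adjust_strain_calls()]).
#' @return One-row tibble: `n_strains, n_fluorescent, n_responsive,
#'   n_dead, pct_fluorescent, pct_responsive_of_fluorescent,
#'   pct_responsive_incl_dead`.
#' @export
library_summary <- function(calls) {
  if (nrow(calls) == 0L) abort("`calls` must have at least one strain.")
  n <- nrow(calls)
  n_fluor <- sum(calls$fluorescent)
  n_dead <- sum(calls$status == "dead")
  n_resp <- sum(calls$status == "responsive")
  n_live_fluor <- sum(calls$fluorescent & calls$status != "dead")
  tibble(
    n_strains = n,
    n_fluorescent = n_fluor,
    n_responsive = n_resp,
    n_dead = n_dead,
    pct_fluorescent = 100 * n_fluor / n,
    pct_responsive_of_fluorescent =
      if (n_live_fluor > 0) 100 * n_resp / n_live_fluor else 0,
    pct_responsive_incl_dead =
      if (n_fluor > 0) 100 * (n_resp + n_dead) / n_fluor else 0
  )
}
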