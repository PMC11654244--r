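#' Normalize a degradation time course to its starting signal
#'
#' Divides each replicate series by its own `t = 0` value so all series
#' start at 1 (fraction of initial signal). Idempotent.
#'
#' @param tc Tibble with `replicate, time_min, signal` (extra columns such
#'   as `strain_id`, `modality` pass through).
#' @return Same tibble with `signal` rescaled per replicate.
#' @examples
#' tc <- tibble::tibble(replicate = 1, time_min = c(0, 30, 60),
#'                      signal = c(100, 50, 25))
#' normalize_timecourse(tc)$signal # 1 0.5 0.25
#' @export
normalize_timecourse <- function(tc) {
  if (!all(c("replicate", "time_min", "signal") %in% names(tc))) {
    abort("`tc` needs columns replicate, time_min, signal.")
  }
  t0 <- tc %>%
    filter(.data$time_min == 0) %>%
    group_by(.data$replicate) %>%
    summarise(t0_signal = mean(.data$signal), .groups = "drop")
  missing <- setdiff(unique(tc$replicate), t0$replicate)
  if (length(missing)) {
    abort("every replicate must include a t = 0 observation.")
  }
  if (any(!is.finite(t0$t0_signal)) || any(t0$t0_signal <= 0)) {
    abort("t = 0 signal must be positive for every replicate.")
  }
  tc %>%
    left_join(t0, by = "replicate") %>%
    mutate(signal = .data$signal / .data$t0_signal) %>%
    select(-dplyr::all_of("t0_signal"))
}

#' Normalize immunoblot band volumes by their loading control
#'
#' Divides each band volume by the matching loading-control (Act1) band
#' volume, yielding a raw series ready for [normalize_timecourse()] (which
#' then rescales each replicate to its starting time = 100% signal).
#'
#' @param band_volumes Numeric vector of target-protein band volumes.
#' @param loading_volumes Matching loading-control volumes, all > 0.
#' @return Numeric vector of loading-normalized signals.
#' @examples
#' wb_normalize(c(200, 100), c(100, 100)) # 2 1
#' @export
wb_normalize <- function(band_volumes, loading_volumes) {
  if (length(band_volumes) != length(loading_volumes)) {
    abort("band and loading vectors must match in length.")
  }
  if (any(!is.finite(loading_volumes)) || any(loading_volumes <= 0)) {
    abort("loading volumes must be positive.")
  }
  band_volumes / loading_volumes
}

#' Fit a one-phase decay to a normalized time course
#'
#' Least-squares fit of `y(t) = plateau + (y0 - plateau) * exp(-k t)` with
#' box constraints `y0` in `[0.8, 1.2]` (absorbing normalization noise
#' rather than pinning the intercept to 1), `plateau` in `[0, 1]`, and
#' `k > 0`, via bounded Levenberg-Marquardt ([minpack.lm::nlsLM]).
#' Replicates are pooled into one fit by default.
#'
#' The half-life `t50` is the time at which the fitted curve crosses
#' `(y0 + plateau) / 2`; for this parameterization that is exactly
#' `ln(2) / k`, so the half-distance crossing and the rate-based half-life
#' coincide. The 95% CI on `t50` comes from the delta method applied to
#' the estimated variance of `k` (`t50 = ln2/k`, so
#' `se(t50) = ln2 / k^2 * se(k)`); when the covariance is unavailable and
#' at least 3 replicates exist, a replicate-resampling bootstrap
#' (`n_boot` draws) supplies the interval instead. The method used is
#' recorded in the result.
#'
#' A series with no measurable decay (final fitted drop under
#' `min_decay`) is flagged `non_degrading` with `t50 = Inf`.
#'
#' @param tc Normalized time-course tibble (`replicate, time_min, signal`).
#' @param ci_level Confidence level for the t50 interval.
#' @param n_boot Bootstrap draws for the fallback interval.
#' @param min_decay Minimum fitted fractional drop to call decay.
#' @return An object of class `decay_fit`: a list with `y0, plateau, k,
#'   t50, ci_low, ci_high, rss, converged, non_degrading, ci_method,
#'   n_obs, data`.
#' @examples
#' tc <- sim_timecourse(t50 = 30, plateau = 0, noise_cv = 0, n_rep = 1)
#' fit <- fit_one_phase_decay(tc)
#' glance(fit)
#' @export
fit_one_phase_decay <- function(tc, ci_level = 0.95, n_boot = 1000L,
                                min_decay = 0.05) {
  if (length(unique(tc$time_min)) < 3L) {
    abort("at least 3 distinct timepoints are required.")
  }
  if (any(tc$signal < 0)) abort("normalized signals must be >= 0.")
  dat <- tc[is.finite(tc$signal), c("replicate", "time_min", "signal")]

  fit_once <- function(d) {
    start <- list(y0 = 1,
                  plateau = max(0, min(1, min(d$signal))),
                  k = log(2) / max(stats::weighted.mean(d$time_min, d$time_min > 0), 1))
    tryCatch(
      minpack.lm::nlsLM(
        signal ~ plateau + (y0 - plateau) * exp(-k * time_min),
        data = d, start = start,
        lower = c(y0 = 0.8, plateau = 0, k = 1e-8),
        upper = c(y0 = 1.2, plateau = 1, k = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  }

  fit <- fit_once(dat)
  if (is.null(fit)) {
    return(new_decay_fit(NA, NA, NA, NA, NA, NA, NA, converged = FALSE,
                         non_degrading = FALSE, ci_method = "none",
                         data = dat, ci_level = ci_level))
  }
  p <- coef(fit)
  rss <- sum(resid(fit)^2)
  t50 <- log(2) / p[["k"]]

  # a flat series: bounded k runs to ~0 or fitted drop is negligible
  drop_frac <- (p[["y0"]] - p[["plateau"]])
  tmax <- max(dat$time_min)
  realized_drop <- drop_frac * (1 - exp(-p[["k"]] * tmax))
  if (realized_drop < min_decay) {
    return(new_decay_fit(p[["y0"]], p[["plateau"]], p[["k"]],
                         t50 = Inf, ci_low = NA, ci_high = NA, rss = rss,
                         converged = TRUE, non_degrading = TRUE,
                         ci_method = "none", data = dat,
                         ci_level = ci_level))
  }

  z <- qt(1 - (1 - ci_level) / 2, df = max(nrow(dat) - 3L, 1L))
  ci <- c(NA_real_, NA_real_)
  ci_method <- "none"
  vc <- tryCatch(vcov(fit), error = function(e) NULL)
  if (!is.null(vc) && is.finite(vc["k", "k"]) && vc["k", "k"] >= 0) {
    se_t50 <- log(2) / p[["k"]]^2 * sqrt(vc["k", "k"])
    ci <- c(max(0, t50 - z * se_t50), t50 + z * se_t50)
    ci_method <- "delta"
  } else if (length(unique(dat$replicate)) >= 3L) {
    reps <- unique(dat$replicate)
    boots <- purrr::map_dbl(seq_len(n_boot), function(i) {
      pick <- sample(reps, length(reps), replace = TRUE)
      d <- bind_rows(lapply(pick, function(r) dat[dat$replicate == r, ]))
      f <- fit_once(d)
      if (is.null(f)) return(NA_real_)
      log(2) / coef(f)[["k"]]
    })
    boots <- boots[is.finite(boots)]
    if (length(boots) >= n_boot / 2) {
      ci <- unname(quantile(boots, c((1 - ci_level) / 2,
                                     1 - (1 - ci_level) / 2)))
      ci_method <- "bootstrap"
    }
  }
  new_decay_fit(p[["y0"]], p[["plateau"]], p[["k"]], t50,
                ci[1], ci[2], rss, converged = TRUE,
                non_degrading = FALSE, ci_method = ci_method,
                data = dat, ci_level = ci_level)
}

new_decay_fit <- function(y0, plateau, k, t50, ci_low, ci_high, rss,
                          converged, non_degrading, ci_method, data,
                          ci_level) {
  structure(
    list(y0 = y0, plateau = plateau, k = k, t50 = t50,
         ci_low = ci_low, ci_high = ci_high, rss = rss,
         converged = converged, non_degrading = non_degrading,
         ci_method = ci_method, ci_level = ci_level,
         n_obs = nrow(data), data = data),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  if (!x$converged) {
    cat("One-phase decay fit: did not converge\n")
  } else if (x$non_degrading) {
    cat("One-phase decay fit: non-degrading series (t50 = Inf)\n")
  } else {
    cat(sprintf(
      "One-phase decay fit: t50 = %.2f min [%.2f, %.2f] (%s CI), plateau = %.3f, k = %.4g /min\n",
      x$t50, x$ci_low, x$ci_high, x$ci_method, x$plateau, x$k))
  }
  invisible(x)
}

#' Predicted one-phase decay curve
#'
#' @param object A `decay_fit`.
#' @param newdata Optional tibble with a `time_min` column; defaults to a
#'   fine grid over the fitted range.
#' @param ... Unused.
#' @return Tibble of `time_min, .fitted`.
#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    newdata <- tibble(time_min = seq(0, max(object$data$time_min),
                                     length.out = 101L))
  }
  tibble(
    time_min = newdata$time_min,
    .fitted = object$plateau +
      (object$y0 - object$plateau) * exp(-object$k * newdata$time_min)
  )
}

#' Compare microscopy and immunoblot decay fits
#'
#' Reports the half-life ratio between two modalities and whether their
#' confidence intervals overlap — a simple concordance check between
#' fluorescence-derived and blot-derived degradation kinetics.
#'
#' @param fit_m,fit_w Converged `decay_fit` objects (conventionally
#'   microscopy and western).
#' @return One-row tibble: `t50_m, t50_w, ratio, ci_overlap`.
#' @export
compare_modalities <- function(fit_m, fit_w) {
  ok <- function(f) inherits(f, "decay_fit") && f$converged && !f$non_degrading
  if (!ok(fit_m) || !ok(fit_w)) {
    abort("both fits must be converged, degrading decay_fit objects.")
  }
  overlap <- if (anyNA(c(fit_m$ci_low, fit_m$ci_high,
                         fit_w$ci_low, fit_w$ci_high))) NA else
    fit_m$ci_low <= fit_w$ci_high && fit_w$ci_low <= fit_m$ci_high
  tibble(
    t50_m = fit_m$t50, t50_w = fit_w$t50,
    ratio = fit_m$t50 / fit_w$t50,
    ci_overlap = overlap
  )
}

#' @rdname fit_one_phase_decay
#' @param x A `decay_fit` object.
#' @param ... Unused.
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(
    term = c("y0", "plateau", "k"),
    estimate = c(x$y0, x$plateau, x$k)
  )
}

#' @rdname fit_one_phase_decay
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(
    t50 = x$t50, ci_low = x$ci_low, ci_high = x$ci_high,
    plateau = x$plateau, k = x$k, rss = x$rss,
    converged = x$converged, non_degrading = x$non_degrading,
    ci_method = x$ci_method, n_obs = x$n_obs
  )
}
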