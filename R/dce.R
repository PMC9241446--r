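# DCE-MRI quantification: relative enhancement curves, per-slice Gd influx
# rate (Kp-sc) as the OLS slope of relative enhancement vs time over the
# post-injection window, whole-cord leakage as the sum over slices, and
# longitudinal normalization relative to a baseline day.

#' Relative enhancement curves from a DCE series
#'
#' Per slice i and scan time t, `E_i(t) = (S_i(t) - S_i(pre)) / S_i(pre)`
#' where S is the within-ROI mean intensity and the pre-injection scan is
#' the first.  E at the pre-injection scan is identically 0.
#'
#' @param series a [dce_series()].
#' @return object of class `enhancement_curve`: matrix `E`
#'   (scans x slices), `times`, `baseline` per-slice pre-injection means.
#' @export
relative_enhancement <- function(series) {
  stopifnot(inherits(series, "dce_series"))
  ns <- dim(series$roi)[3]
  roi_mean <- function(vol, s) mean(vol[, , s][series$roi[, , s]])
  means <- vapply(series$scans, function(vol)
    vapply(seq_len(ns), function(s) roi_mean(vol, s), numeric(1)),
    numeric(ns))
  means <- matrix(means, nrow = ns)  # slices x scans
  base <- means[, 1]
  bad <- which(base <= 0)
  if (length(bad))
    stop_bscb("non-positive pre-injection baseline mean in slice %s",
              paste(bad, collapse = ", "))
  E <- t((means - base) / base)  # scans x slices
  structure(list(E = E, times = series$times, baseline = base),
            class = "enhancement_curve")
}

#' Per-slice Gd influx rate (Kp-sc)
#'
#' Kp for slice i is the ordinary least-squares slope of `E_i(t)` against
#' t over the post-injection scans selected by `window` (default: all).
#' The intercept is free by default (the first post-injection scan already
#' carries vascular signal); `through_origin = TRUE` forces the fit
#' through zero.  Negative fitted slopes are retained, keeping the
#' longitudinal normalization unbiased.
#'
#' @param curve an `enhancement_curve` from [relative_enhancement()].
#' @param window indices (into the post-injection scans, in time order) to
#'   include in the fit; default all.
#' @param through_origin logical; fix the intercept at 0.
#' @return numeric vector of per-slice slopes, 1/min.
#' @export
estimate_kp <- function(curve, window = NULL, through_origin = FALSE) {
  stopifnot(inherits(curve, "enhancement_curve"))
  post <- which(seq_along(curve$times) > 1L)
  if (!is.null(window)) post <- post[window]
  if (length(post) < 2L)
    stop_bscb("need >= 2 post-injection time points to fit a slope")
  t <- curve$times[post]
  E <- curve$E[post, , drop = FALSE]
  if (through_origin) {
    drop(crossprod(t, E)) / sum(t^2)
  } else {
    tc <- t - mean(t)
    drop(crossprod(tc, sweep(E, 2, colMeans(E)))) / sum(tc^2)
  }
}

#' Total Gd leakage: sum of per-slice influx rates
#'
#' @param kp_per_slice numeric vector of per-slice Kp values.
#' @return their exact sum.
#' @export
total_leakage <- function(kp_per_slice) {
  if (!length(kp_per_slice)) stop_bscb("need >= 1 slice")
  sum(kp_per_slice)
}

#' Gd leakage relative to a baseline-day value
#'
#' `100 * current / baseline`, the longitudinal %Gd-leakage normalization
#' (later timepoints expressed relative to the acute 7 DPI scan).
#'
#' @param current,baseline total leakage values.
#' @return percent.
#' @export
relative_leakage <- function(current, baseline) {
  if (!is.finite(baseline) || baseline <= 0)
    stop_bscb("undefined normalization: baseline leakage must be > 0")
  100 * current / baseline
}

#' Full DCE scoring of a series
#'
#' Convenience wrapper: enhancement -> per-slice Kp -> summed leakage.
#'
#' @inheritParams estimate_kp
#' @param series a [dce_series()].
#' @return object of class `leakage_result`: `kp_per_slice`, `gd_leakage`.
#' @export
score_dce <- function(series, window = NULL, through_origin = FALSE) {
  kp <- estimate_kp(relative_enhancement(series), window = window,
                    through_origin = through_origin)
  structure(list(kp_per_slice = kp, gd_leakage = total_leakage(kp)),
            class = "leakage_result")
}

#' @export
print.leakage_result <- function(x, ...) {
  cat(sprintf("Gd leakage (sum Kp-sc over %d slices): %.4f /min\n",
              length(x$kp_per_slice), x$gd_leakage))
  invisible(x)
}
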