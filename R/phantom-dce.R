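# DCE-MRI phantom: serial post-contrast volumes whose within-ROI mean
# follows linear relative enhancement S(t) = S0 * (1 + Kp * t) per slice,
# the regime in which the Gd influx rate is the slope of relative
# enhancement over the 10-minute post-bolus window.

#' DCE phantom specification
#'
#' Defaults mirror an axial cord DCE protocol: 11 slices and one baseline
#' scan followed by six post-injection scans spanning 10 minutes.
#'
#' @param n_slices number of axial slices.
#' @param scan_times minutes from injection, strictly increasing; exactly
#'   one pre-injection time point (the first, t <= 0).
#' @param slice_slopes true relative-enhancement slope per slice, 1/min
#'   (recycled to `n_slices`).
#' @param baseline_intensity pre-injection ROI intensity, signal units.
#' @param noise_sigma per-voxel additive Gaussian noise scale.
#' @param image_shape in-plane matrix size c(H, W).
#' @param roi_radius circular ROI radius, pixels.
#' @param seed integer RNG seed.
#' @return object of class `dce_phantom_spec`.
#' @export
dce_phantom_spec <- function(n_slices = 11L,
                             scan_times = c(0, (10 / 6) * (1:6)),
                             slice_slopes = 0.02,
                             baseline_intensity = 100,
                             noise_sigma = 0,
                             image_shape = c(32L, 32L),
                             roi_radius = 8,
                             seed = 1L) {
  if (baseline_intensity < 0) stop_bscb("invalid spec: negative baseline_intensity")
  check_scalar_num(noise_sigma, "noise_sigma", 0)
  if (any(diff(scan_times) <= 0)) stop_bscb("scan_times must be strictly increasing")
  if (sum(scan_times <= 0) != 1L)
    stop_bscb("exactly one pre-injection (t <= 0) time point is required")
  slice_slopes <- rep_len(as.numeric(slice_slopes), n_slices)
  if (any(!is.finite(slice_slopes))) stop_bscb("slice slopes must be finite")
  structure(list(n_slices = as.integer(n_slices),
                 scan_times = as.numeric(scan_times),
                 slice_slopes = slice_slopes,
                 baseline_intensity = baseline_intensity,
                 noise_sigma = noise_sigma,
                 image_shape = as.integer(image_shape),
                 roi_radius = roi_radius,
                 seed = as.integer(seed)),
            class = "dce_phantom_spec")
}

#' Generate a serial post-contrast (DCE) series
#'
#' Within the circular ROI of slice i, the expected intensity at
#' post-injection time t is `baseline_intensity * (1 + slope_i * t)`; the
#' pre-injection scan has zero enhancement in expectation.  Voxel-wise
#' Gaussian noise of scale `noise_sigma` is added everywhere.
#'
#' @param spec a [dce_phantom_spec()].
#' @return list with `series` (a `dce_series`: list of H x W x n_slices
#'   scan arrays, `times`, `roi` mask array) and `true_slopes`.
#' @export
generate_dce_series <- function(spec) {
  stopifnot(inherits(spec, "dce_phantom_spec"))
  h <- spec$image_shape[1]; w <- spec$image_shape[2]
  roi2d <- pixel_grid(c(h, w))$r <= spec$roi_radius
  roi <- array(roi2d, dim = c(h, w, spec$n_slices))
  nt <- length(spec$scan_times)
  scans <- with_seed(spec$seed, {
    lapply(seq_len(nt), function(ti) {
      t_post <- max(spec$scan_times[ti], 0)
      vol <- array(0.2 * spec$baseline_intensity, dim = c(h, w, spec$n_slices))
      for (s in seq_len(spec$n_slices)) {
        plane <- vol[, , s]
        plane[roi2d] <- spec$baseline_intensity *
          (1 + spec$slice_slopes[s] * t_post)
        vol[, , s] <- plane
      }
      if (spec$noise_sigma > 0)
        vol <- vol + array(stats::rnorm(length(vol), 0, spec$noise_sigma), dim = dim(vol))
      vol
    })
  })
  series <- dce_series(scans, spec$scan_times, roi)
  list(series = series, true_slopes = spec$slice_slopes)
}

#' Construct a DCE series container
#'
#' @param scans list of intensity volumes (H x W x S), first scan
#'   pre-injection.
#' @param times minutes from injection, strictly increasing.
#' @param roi logical array (H x W x S) or matrix (H x W, recycled across
#'   slices); must be non-empty in every slice.
#' @return object of class `dce_series`.
#' @export
dce_series <- function(scans, times, roi) {
  if (any(diff(times) <= 0)) stop_bscb("scan times must be strictly increasing")
  if (length(scans) != length(times)) stop_bscb("one time per scan required")
  if (length(scans) < 3L) stop_bscb("need a baseline plus >= 2 post-injection scans")
  d <- dim(scans[[1]])
  if (length(d) == 2L) {
    scans <- lapply(scans, function(x) array(x, dim = c(d, 1L)))
    d <- c(d, 1L)
  }
  if (is.matrix(roi)) roi <- array(roi, dim = d)
  for (s in seq_len(d[3])) if (!any(roi[, , s]))
    stop_bscb("ROI empty in slice %d", s)
  structure(list(scans = scans, times = as.numeric(times), roi = roi),
            class = "dce_series")
}
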