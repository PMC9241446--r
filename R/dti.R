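# Diffusion-tensor quantification: log-linear tensor fit, FA/AD/RD scalar
# maps, white-matter-fraction threshold calibration, and the binarized
# %area scores used as longitudinal white-matter/axon/myelin readouts.

#' Fit diffusion tensors from a DWI stack
#'
#' Per voxel, solves the log-linear system
#' `ln(S_k / S0) = -b * g_k' D g_k` for the six unique tensor elements by
#' (least-squares for K > 6, exact for K = 6) inversion, then
#' eigendecomposes D.  Eigenvalues are returned sorted descending;
#' negative eigenvalues from noisy fits are clamped to 0 (count reported)
#' so that area-score denominators stay stable.  Voxels with non-positive
#' b0 or any non-positive DW signal are flagged invalid and excluded.
#'
#' @param stack a `dwi_stack` (see [generate_dwi_phantom()]): `signals`
#'   H x W x (1+K) with the b0 first, plus a [dti_scheme()].
#' @param mask optional logical matrix restricting the fit (default: all
#'   voxels with positive b0).
#' @return object of class `tensor_map`: arrays `eigenvalues`
#'   (H x W x 3, descending), `valid` mask, `n_clamped`,
#'   and `tensors` (H x W x 6: Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), um^2/ms.
#' @export
fit_tensor <- function(stack, mask = NULL) {
  stopifnot(inherits(stack, "dwi_stack"))
  sig <- stack$signals
  h <- dim(sig)[1]; w <- dim(sig)[2]
  K <- dim(sig)[3] - 1L
  if (K < 6L) stop_bscb("need >= 6 diffusion-weighted volumes")
  B <- tensor_design(stack$scheme$directions)
  if (qr(B)$rank < 6L) stop_bscb("unidentifiable gradient scheme")
  b <- stack$scheme$bval * 1e-3  # pairs with eigenvalues in um^2/ms

  s0 <- sig[, , 1]
  if (is.null(mask)) mask <- s0 > 0
  dw <- matrix(sig[, , -1, drop = FALSE], nrow = h * w, ncol = K)
  valid <- as.vector(mask) & as.vector(s0) > 0 & rowSums(dw <= 0) == 0

  y <- -log(dw[valid, , drop = FALSE] / as.vector(s0)[valid]) / b  # K x 1 per voxel
  # d = (B'B)^-1 B' y' ; exact inverse when K == 6
  d_elems <- t(qr.solve(B, t(y)))  # n_valid x 6

  eig <- array(NA_real_, dim = c(h, w, 3))
  tensors <- array(NA_real_, dim = c(h, w, 6))
  ev_valid <- matrix(NA_real_, nrow(d_elems), 3)
  for (i in seq_len(nrow(d_elems))) {
    d <- d_elems[i, ]
    D <- matrix(c(d[1], d[4], d[5],
                  d[4], d[2], d[6],
                  d[5], d[6], d[3]), 3, 3)
    ev_valid[i, ] <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  }
  n_clamped <- sum(ev_valid < 0)
  ev_valid[ev_valid < 0] <- 0
  vidx <- which(valid)
  for (j in 1:3) {
    plane <- matrix(NA_real_, h, w)
    plane[vidx] <- ev_valid[, j]
    eig[, , j] <- plane
  }
  for (j in 1:6) {
    plane <- matrix(NA_real_, h, w)
    plane[vidx] <- d_elems[, j]
    tensors[, , j] <- plane
  }
  structure(list(eigenvalues = eig, tensors = tensors,
                 valid = matrix(valid, h, w), n_clamped = n_clamped),
            class = "tensor_map")
}

#' Construct a scalar-map set (FA/AD/RD + masks)
#'
#' @param fa_map,ad_map,rd_map numeric matrices (FA dimensionless in
#'   [0, 1]; AD/RD in um^2/ms).
#' @param cord_mask logical cord ROI matrix.
#' @param wm_mask optional white-matter mask (must be a subset of the cord).
#' @return object of class `scalar_map_set`.
#' @export
scalar_map_set <- function(fa_map, ad_map, rd_map, cord_mask, wm_mask = NULL) {
  fin <- is.finite(fa_map)
  if (any(fa_map[fin] < -1e-9 | fa_map[fin] > 1 + 1e-9))
    stop_bscb("FA values must lie in [0, 1]")
  if (!is.null(wm_mask) && any(wm_mask & !cord_mask))
    stop_bscb("wm_mask must be a subset of cord_mask")
  structure(list(fa_map = fa_map, ad_map = ad_map, rd_map = rd_map,
                 cord_mask = cord_mask, wm_mask = wm_mask),
            class = "scalar_map_set")
}

#' Compute FA/AD/RD scalar maps from a tensor fit
#'
#' AD = lambda1, RD = (lambda2 + lambda3) / 2, and
#' FA = sqrt(3/2) * sqrt(sum((lambda_i - mean)^2)) / sqrt(sum(lambda_i^2)),
#' with FA = 0 where all eigenvalues are 0 (degenerate voxels).
#'
#' @param tensors a `tensor_map` from [fit_tensor()].
#' @param cord_mask logical cord ROI matrix.
#' @param wm_mask optional white-matter mask.
#' @return a [scalar_map_set()].
#' @export
compute_scalar_maps <- function(tensors, cord_mask, wm_mask = NULL) {
  stopifnot(inherits(tensors, "tensor_map"))
  d <- dim(tensors$eigenvalues)
  l1 <- matrix(tensors$eigenvalues[, , 1], d[1], d[2])
  l2 <- matrix(tensors$eigenvalues[, , 2], d[1], d[2])
  l3 <- matrix(tensors$eigenvalues[, , 3], d[1], d[2])
  scalar_map_set(fa_map = fa_from_eigenvalues(l1, l2, l3),
                 ad_map = l1, rd_map = (l2 + l3) / 2,
                 cord_mask = cord_mask, wm_mask = wm_mask)
}

#' Calibrate a binarization threshold against a white-matter fraction
#'
#' Returns the threshold t such that the fraction of within-cord voxels
#' passing the comparison (`map >= t`, or `map <= t` for RD-style maps)
#' matches `wm_fraction` as closely as voxel quantization allows --
#' i.e. the appropriate empirical quantile of within-cord values, resolved
#' with the "lower" convention (the most extreme t achieving a passing
#' fraction >= target).  The achieved fraction is reported alongside.
#'
#' @param map scalar map matrix (2-D) or array of slices (3-D, pooled).
#' @param cord_mask logical mask matching `map`.
#' @param wm_fraction target binarized-area fraction, in (0, 1).
#' @param direction `">="` (FA/AD-style positive area) or `"<="`
#'   (RD-style negative area).
#' @return list with `threshold`, `achieved_fraction`, `direction`, `n`.
#' @export
calibrate_threshold <- function(map, cord_mask, wm_fraction,
                                direction = c(">=", "<=")) {
  direction <- match.arg(direction)
  check_scalar_num(wm_fraction, "wm_fraction", 0, 1,
                   strict_lower = TRUE, strict_upper = TRUE)
  all_vals <- map[cord_mask]
  n <- length(all_vals)
  if (!n) stop_bscb("cord mask is empty")
  vals <- all_vals[is.finite(all_vals)]  # invalid voxels never pass
  if (!length(vals) || diff(range(vals)) == 0)
    stop_bscb("degenerate calibration: constant map, no threshold separates any fraction")
  k <- max(1L, round(wm_fraction * n))
  if (k > length(vals))
    stop_bscb("degenerate calibration: only %d of %d cord voxels are valid",
              length(vals), n)
  sorted <- sort(vals, decreasing = (direction == ">="))
  thr <- sorted[k]
  passing <- if (direction == ">=") vals >= thr else vals <= thr
  list(threshold = thr, achieved_fraction = sum(passing) / n,
       direction = direction, n = n)
}

#' Binarization thresholds for the three DTI maps
#'
#' Defaults are the fixed thresholds used for the area scores:
#' FA >= 0.55 (unitless), AD >= 1.4 um^2/ms, RD <= 0.5 um^2/ms, each
#' calibrated so the binarized area matches the white-matter fraction of
#' the injection-site cord (~55%).  Comparisons are inclusive.
#'
#' @param fa_min,ad_min,rd_max threshold values.
#' @return object of class `dti_thresholds`.
#' @export
dti_thresholds <- function(fa_min = 0.55, ad_min = 1.4, rd_max = 0.5) {
  check_scalar_num(fa_min, "fa_min", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  check_scalar_num(ad_min, "ad_min", 0, strict_lower = TRUE)
  check_scalar_num(rd_max, "rd_max", 0, strict_lower = TRUE)
  structure(list(fa_min = fa_min, ad_min = ad_min, rd_max = rd_max),
            class = "dti_thresholds")
}

#' Binarized %area scores of the cord cross-section
#'
#' `pct_fa_positive` = 100 * |cord voxels with FA >= fa_min| / |cord|,
#' analogously `pct_ad_positive` (AD >= ad_min) and `pct_rd_negative`
#' (RD <= rd_max).  Comparisons are inclusive: ties at the threshold count
#' as positive.  For multi-slice maps (3-D arrays) scores are computed per
#' axial slice and averaged (`per_slice = TRUE`, mirroring an 11-slice
#' acquisition block) or pooled over all voxels (`per_slice = FALSE`).
#'
#' @param maps a [scalar_map_set()].
#' @param thresholds a [dti_thresholds()].
#' @param per_slice average per-slice scores for 3-D maps.
#' @return object of class `area_scores`: list with `pct_fa_positive`,
#'   `pct_ad_positive`, `pct_rd_negative` (percent of cord area).
#' @export
area_scores <- function(maps, thresholds = dti_thresholds(),
                        per_slice = TRUE) {
  stopifnot(inherits(maps, "scalar_map_set"), inherits(thresholds, "dti_thresholds"))
  cm <- maps$cord_mask
  if (!any(cm, na.rm = TRUE)) stop_bscb("empty cord mask")
  pct <- function(map, thr, op) {
    score_one <- function(vals, msk) {
      vals <- vals[msk]
      ok <- is.finite(vals)
      pass <- if (op == ">=") vals >= thr else vals <= thr
      100 * sum(pass & ok) / length(vals)
    }
    if (length(dim(map)) == 3L && per_slice) {
      mean(vapply(seq_len(dim(map)[3]), function(s)
        score_one(map[, , s], cm[, , s]), numeric(1)))
    } else score_one(map, cm)
  }
  structure(list(pct_fa_positive = pct(maps$fa_map, thresholds$fa_min, ">="),
                 pct_ad_positive = pct(maps$ad_map, thresholds$ad_min, ">="),
                 pct_rd_negative = pct(maps$rd_map, thresholds$rd_max, "<=")),
            class = "area_scores")
}

#' @export
print.area_scores <- function(x, ...) {
  cat(sprintf("%%FA positive area: %6.2f\n%%AD positive area: %6.2f\n%%RD negative area: %6.2f\n",
              x$pct_fa_positive, x$pct_ad_positive, x$pct_rd_negative))
  invisible(x)
}
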