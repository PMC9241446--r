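# Spinal-cord DWI phantom: an axial thoracic cross-section rendered as a
# disk "cord" whose outer annulus is white matter (WM) occupying a stated
# area fraction, with an optional demyelinating lesion inside the WM.
# Each tissue carries a diagonal diffusion tensor (eigenvalues in um^2/ms)
# and the diffusion-weighted signal follows the mono-exponential model
# S_k = S0 * exp(-b * g_k' D g_k).

#' Cord phantom specification
#'
#' Describes the geometry and tissue diffusivities of a synthetic axial
#' spinal-cord slice.  Defaults give a "naive injection-site" cord: white
#' matter occupying ~55% of the cord cross-section (the calibration anchor
#' used for threshold calibration), WM eigenvalues typical of healthy mouse
#' cord white matter (high FA, AD >= 1.4, RD <= 0.5 um^2/ms) and nearly
#' isotropic gray matter.
#'
#' @param image_shape integer c(H, W) in pixels.
#' @param cord_radius cord disk radius, pixels.
#' @param wm_fraction white-matter area fraction of the cord, in (0, 1).
#' @param wm_values,gm_values,lesion_values tissue eigenvalue triplets
#'   (lambda1 >= lambda2 >= lambda3), um^2/ms.
#' @param lesion_fraction fraction of the WM area that is lesioned, [0, 1).
#'   Lesion voxels show lowered FA/AD and raised RD via `lesion_values`.
#' @param noise_sigma additive Gaussian noise scale, signal units (b0 = 1).
#' @param seed integer RNG seed.
#' @return object of class `cord_phantom_spec`.
#' @export
cord_phantom_spec <- function(image_shape = c(64L, 64L),
                              cord_radius = 24,
                              wm_fraction = 0.55,
                              wm_values = c(1.6, 0.45, 0.35),
                              gm_values = c(0.9, 0.7, 0.6),
                              lesion_fraction = 0,
                              lesion_values = c(1.0, 0.7, 0.6),
                              noise_sigma = 0,
                              seed = 1L) {
  check_scalar_num(wm_fraction, "wm_fraction", 0, 1,
                   strict_lower = TRUE, strict_upper = TRUE)
  check_scalar_num(lesion_fraction, "lesion_fraction", 0, 1, strict_upper = TRUE)
  check_scalar_num(noise_sigma, "noise_sigma", 0)
  check_scalar_num(cord_radius, "cord_radius", 1)
  for (nm in c("wm_values", "gm_values", "lesion_values")) {
    v <- get(nm)
    if (length(v) != 3L || any(!is.finite(v)) || any(v < 0))
      stop_bscb("`%s` must be three finite non-negative eigenvalues", nm)
  }
  structure(list(image_shape = as.integer(image_shape),
                 cord_radius = cord_radius,
                 wm_fraction = wm_fraction,
                 wm_values = sort(wm_values, decreasing = TRUE),
                 gm_values = sort(gm_values, decreasing = TRUE),
                 lesion_fraction = lesion_fraction,
                 lesion_values = sort(lesion_values, decreasing = TRUE),
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "cord_phantom_spec")
}

#' Diffusion gradient scheme
#'
#' Default is the 6-direction dual-gradient scheme (normalized +/-x+/-y,
#' +/-y+/-z, +/-x+/-z) at b = 4900 s/mm^2, matching a single-shot EPI cord
#' protocol with 6 diffusion directions plus one b0.
#'
#' @param bval b-value in s/mm^2.
#' @param directions K x 3 matrix of unit gradient directions.
#' @return object of class `dti_scheme`.
#' @export
dti_scheme <- function(bval = 4900,
                       directions = NULL) {
  if (is.null(directions)) {
    d <- rbind(c(1, 1, 0), c(1, -1, 0),
               c(0, 1, 1), c(0, 1, -1),
               c(1, 0, 1), c(1, 0, -1))
    directions <- d / sqrt(2)
  }
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L) stop_bscb("directions must be K x 3")
  nrm <- sqrt(rowSums(directions^2))
  directions <- directions / nrm
  if (qr(tensor_design(directions))$rank < 6L)
    stop_bscb("gradient scheme is unidentifiable: need >= 6 non-collinear directions spanning tensor space")
  structure(list(bval = bval, directions = directions), class = "dti_scheme")
}

# Design matrix mapping the 6 unique tensor elements
# (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) to g' D g per direction.
tensor_design <- function(directions) {
  g <- directions
  cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
        2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
}

# Tissue label image: 0 background, 1 GM, 2 WM, 3 lesion.  WM membership is
# decided by ranking cord pixels on radius (outermost first) so the WM pixel
# count is exactly round(wm_fraction * |cord|); the lesion is the
# round(lesion_fraction * |WM|) WM pixels closest to a focal point on the
# dorsal cord surface.  This keeps area fractions exact to one pixel.
cord_geometry <- function(spec) {
  grid <- pixel_grid(spec$image_shape)
  cord <- grid$r <= spec$cord_radius
  n_cord <- sum(cord)
  if (n_cord < 16L) stop_bscb("cord mask too small; enlarge image or radius")
  idx <- which(cord)
  # rank by radius, ties broken deterministically by linear index
  ord <- idx[order(grid$r[idx], idx, decreasing = TRUE)]
  n_wm <- round(spec$wm_fraction * n_cord)
  wm_idx <- ord[seq_len(n_wm)]
  wm <- matrix(FALSE, spec$image_shape[1], spec$image_shape[2])
  wm[wm_idx] <- TRUE
  lesion <- matrix(FALSE, spec$image_shape[1], spec$image_shape[2])
  n_les <- round(spec$lesion_fraction * n_wm)
  if (n_les > 0L) {
    # focal point: dorsal-most cord pixel (minimum y)
    cy <- (spec$image_shape[1] + 1) / 2 - spec$cord_radius
    cx <- (spec$image_shape[2] + 1) / 2
    ry <- matrix(seq_len(spec$image_shape[1]), spec$image_shape[1], spec$image_shape[2]) - cy
    rx <- matrix(seq_len(spec$image_shape[2]), spec$image_shape[1], spec$image_shape[2], byrow = TRUE) - cx
    d2 <- ry^2 + rx^2
    les_idx <- wm_idx[order(d2[wm_idx], wm_idx)][seq_len(n_les)]
    lesion[les_idx] <- TRUE
  }
  labels <- matrix(0L, spec$image_shape[1], spec$image_shape[2])
  labels[cord] <- 1L
  labels[wm] <- 2L
  labels[lesion] <- 3L
  list(cord = cord, wm = wm, lesion = lesion, labels = labels)
}

# Closed-form FA from sorted eigenvalues.
fa_from_eigenvalues <- function(l1, l2, l3) {
  ss <- l1^2 + l2^2 + l3^2
  lb <- (l1 + l2 + l3) / 3
  num <- (l1 - lb)^2 + (l2 - lb)^2 + (l3 - lb)^2
  fa <- sqrt(1.5) * sqrt(num) / sqrt(ss)
  fa[ss == 0] <- 0
  fa
}

scalar_maps_from_labels <- function(geom, spec) {
  tissues <- list(spec$gm_values, spec$wm_values, spec$lesion_values)
  fa <- ad <- rd <- matrix(0, nrow(geom$labels), ncol(geom$labels))
  for (lab in 1:3) {
    v <- tissues[[lab]]
    sel <- geom$labels == lab
    ad[sel] <- v[1]
    rd[sel] <- (v[2] + v[3]) / 2
    fa[sel] <- fa_from_eigenvalues(v[1], v[2], v[3])
  }
  scalar_map_set(fa, ad, rd, cord_mask = geom$cord, wm_mask = geom$wm)
}

#' Generate a diffusion-weighted cord phantom
#'
#' Renders the cord geometry of `spec`, assigns each tissue its diagonal
#' diffusion tensor, and simulates one b0 plus K diffusion-weighted images
#' under the mono-exponential signal model with additive Gaussian noise
#' (`noise_sigma`; plain additive rather than Rician -- see the vignette).
#' Ground-truth FA/AD/RD maps and cord/WM/lesion masks are returned
#' alongside and are exact (noise-independent).
#'
#' @param spec a [cord_phantom_spec()].
#' @param scheme a [dti_scheme()]; b-value in s/mm^2 is converted
#'   internally against eigenvalues in um^2/ms (= 1e-3 mm^2/s).
#' @param s0 baseline (b0) signal level.
#' @return list with `stack` (a `dwi_stack`: signals H x W x (1+K), first
#'   plane b0, plus the scheme), `truth` (a `scalar_map_set`), and `masks`
#'   (cord/wm/lesion logical matrices).
#' @export
generate_dwi_phantom <- function(spec, scheme = dti_scheme(), s0 = 1) {
  stopifnot(inherits(spec, "cord_phantom_spec"), inherits(scheme, "dti_scheme"))
  geom <- cord_geometry(spec)
  K <- nrow(scheme$directions)
  h <- spec$image_shape[1]; w <- spec$image_shape[2]
  signals <- array(0, dim = c(h, w, 1L + K))

  # b [s/mm^2] * D [um^2/ms = 1e-3 mm^2/s] -> dimensionless exponent
  bD <- scheme$bval * 1e-3
  tissues <- list(spec$gm_values, spec$wm_values, spec$lesion_values)
  signals[, , 1][geom$labels > 0] <- s0
  for (lab in 1:3) {
    sel <- geom$labels == lab
    if (!any(sel)) next
    ev <- tissues[[lab]]
    # diagonal tensor: g' D g = sum(g_i^2 * lambda_i)
    q <- drop(scheme$directions^2 %*% ev)
    for (k in seq_len(K)) {
      plane <- signals[, , 1L + k]
      plane[sel] <- s0 * exp(-bD * q[k])
      signals[, , 1L + k] <- plane
    }
  }
  if (spec$noise_sigma > 0) {
    signals <- with_seed(spec$seed, {
      signals + array(stats::rnorm(length(signals), 0, spec$noise_sigma),
                      dim = dim(signals))
    })
  }
  stack <- structure(list(signals = signals, scheme = scheme, s0 = s0),
                     class = "dwi_stack")
  list(stack = stack,
       truth = scalar_maps_from_labels(geom, spec),
       masks = list(cord = geom$cord, wm = geom$wm, lesion = geom$lesion))
}
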