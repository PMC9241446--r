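# Image-processing primitives for fluorescence quantification: separable
# Gaussian smoothing, Sobel gradients, Canny edge detection with
# non-maximum suppression and hysteresis, border-connected hole filling,
# connected-component labelling, and disk dilation.  All in base R matrix
# arithmetic (no image-processing package is assumed at run time).

# Shift a matrix by (dy, dx) with edge replication.
shift_mat <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) - dy, 1L), h)
  ci <- pmin(pmax(seq_len(w) - dx, 1L), w)
  m[ri, ci, drop = FALSE]
}

# Separable convolution with a symmetric 1-D kernel (replicate padding).
conv_sep <- function(img, kernel) {
  r <- (length(kernel) - 1L) / 2L
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_along(kernel)) out <- out + kernel[i] * shift_mat(img, i - r - 1L, 0L)
  out2 <- matrix(0, nrow(img), ncol(img))
  for (i in seq_along(kernel)) out2 <- out2 + kernel[i] * shift_mat(out, 0L, i - r - 1L)
  out2
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

sobel_gradients <- function(img) {
  # G_x responds to horizontal (column-wise) intensity change
  sx <- function(m) (shift_mat(m, 0, -1) - shift_mat(m, 0, 1))
  gy_k <- function(m) (shift_mat(m, -1, 0) - shift_mat(m, 1, 0))
  smooth_y <- shift_mat(img, -1, 0) + 2 * img + shift_mat(img, 1, 0)
  smooth_x <- shift_mat(img, 0, -1) + 2 * img + shift_mat(img, 0, 1)
  list(gx = sx(smooth_y), gy = gy_k(smooth_x))
}

dilate8 <- function(mask) {
  out <- mask
  for (dy in -1:1) for (dx in -1:1)
    if (dy || dx) out <- out | shift_mat(mask, dy, dx)
  out
}

dilate4 <- function(mask) {
  mask | shift_mat(mask, 1, 0) | shift_mat(mask, -1, 0) |
    shift_mat(mask, 0, 1) | shift_mat(mask, 0, -1)
}

#' Canny edge detection
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, and hysteresis linking.  By default the
#' high hysteresis threshold is Otsu's split of the gradient-magnitude
#' distribution within `roi` (contrast-adaptive: fixed-percentile
#' thresholds admit a constant fraction of noise pixels however sparse
#' the edges are) and the low threshold is half of it.
#'
#' @param img numeric intensity matrix.
#' @param sigma Gaussian smoothing scale in pixels; should not exceed
#'   about half the thickness of the thinnest structure of interest.
#' @param low,high hysteresis thresholds on gradient magnitude; `NULL`
#'   means the Otsu-based defaults.
#' @param roi logical matrix restricting both the threshold estimation and
#'   the reported edges.
#' @return logical edge mask.
#' @export
canny_edges <- function(img, sigma = 1.5, low = NULL, high = NULL, roi = NULL) {
  if (is.null(roi)) roi <- matrix(TRUE, nrow(img), ncol(img))
  sm <- conv_sep(img, gaussian_kernel(sigma))
  g <- sobel_gradients(sm)
  mag <- sqrt(g$gx^2 + g$gy^2)
  if (is.null(high)) high <- otsu_threshold(mag[roi])
  if (is.null(low)) low <- 0.5 * high
  if (high <= 0) return(matrix(FALSE, nrow(img), ncol(img)))

  # non-maximum suppression: compare with the two neighbors along the
  # gradient direction, quantized to 0/45/90/135 degrees
  ang <- atan2(g$gy, g$gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- floor(((ang + pi / 8) %% pi) / (pi / 4))  # 0..3
  nbr <- list(`0` = c(0L, 1L), `1` = c(1L, 1L), `2` = c(1L, 0L), `3` = c(1L, -1L))
  nms <- matrix(FALSE, nrow(img), ncol(img))
  for (s in 0:3) {
    d <- nbr[[as.character(s)]]
    # strict comparison on one side breaks plateau ties, keeping the
    # ridge line single-pixel wide
    keep <- sector == s & mag > shift_mat(mag, d[1], d[2]) &
      mag >= shift_mat(mag, -d[1], -d[2])
    nms <- nms | keep
  }
  strong <- nms & mag >= high & roi
  weak <- nms & mag >= low & roi
  # grow strong edges through connected weak pixels
  repeat {
    grown <- weak & dilate8(strong)
    newpix <- grown & !strong
    if (!any(newpix)) break
    strong <- strong | newpix
  }
  strong
}

#' Fill holes enclosed by a mask
#'
#' A hole is any off-mask region not connected to the image border.  The
#' background flood uses 4-connectivity (the dual of the 8-connected
#' foreground), so diagonal one-pixel edge chains still enclose holes.
#'
#' @param mask logical matrix.
#' @return logical matrix.
#' @export
fill_holes <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  border <- matrix(FALSE, h, w)
  border[1, ] <- border[h, ] <- TRUE
  border[, 1] <- border[, w] <- TRUE
  bg <- border & !mask
  repeat {
    grown <- dilate4(bg) & !mask
    newpix <- grown & !bg
    if (!any(newpix)) break
    bg <- bg | newpix
  }
  mask | !bg
}

#' Label 8-connected components
#'
#' @param mask logical matrix.
#' @return integer matrix: 0 background, 1..n component labels.
#' @export
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0, h, w)
  lab[mask] <- which(mask)  # provisional: own linear index
  repeat {
    nb <- lab
    for (dy in -1:1) for (dx in -1:1) {
      if (!dy && !dx) next
      sh <- shift_mat(lab, dy, dx)
      upd <- mask & sh > 0 & (nb == 0 | sh < nb)
      nb[upd] <- sh[upd]
    }
    nb[!mask] <- 0
    conv <- mask & nb > 0 & nb < lab
    if (!any(conv)) break
    lab[conv] <- nb[conv]
  }
  # compact labels to 1..n
  ids <- sort(unique(lab[lab > 0]))
  out <- matrix(0L, h, w)
  out[lab > 0] <- match(lab[lab > 0], ids)
  out
}

# Remove components smaller than min_size; returns mask + removal count.
remove_small_components <- function(mask, min_size) {
  lab <- label_components(mask)
  if (!any(lab > 0)) return(list(mask = mask, n_removed = 0L))
  sizes <- tabulate(lab[lab > 0])
  drop_ids <- which(sizes < min_size)
  list(mask = lab > 0 & !(lab %in% drop_ids), n_removed = length(drop_ids))
}

# 2-D FFT convolution (zero padding), used for disk dilation.
conv2d_fft <- function(a, k) {
  pa <- dim(a) + dim(k) - 1L
  A <- matrix(0, pa[1], pa[2]); A[seq_len(nrow(a)), seq_len(ncol(a))] <- a
  Kk <- matrix(0, pa[1], pa[2]); Kk[seq_len(nrow(k)), seq_len(ncol(k))] <- k
  full <- Re(stats::fft(stats::fft(A) * stats::fft(Kk), inverse = TRUE)) / prod(pa)
  r0 <- (nrow(k) - 1L) / 2L; c0 <- (ncol(k) - 1L) / 2L
  full[r0 + seq_len(nrow(a)), c0 + seq_len(ncol(a))]
}

#' Morphological dilation by a disk
#'
#' @param mask logical matrix.
#' @param radius disk radius in pixels.
#' @return logical matrix.
#' @export
dilate_disk <- function(mask, radius) {
  if (radius <= 0) return(mask)
  r <- ceiling(radius)
  g <- pixel_grid(c(2L * r + 1L, 2L * r + 1L))
  disk <- (g$r <= radius) * 1
  conv2d_fft(mask * 1, disk) > 0.5
}

#' Otsu's threshold
#'
#' Maximizes between-class variance over a 256-bin histogram of `values`;
#' bins span the data range, so the threshold is invariant under positive
#' affine rescaling of the input.
#'
#' @param values numeric vector.
#' @return threshold value; pixels strictly above it are "high".
#' @export
otsu_threshold <- function(values) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1])
  nb <- 256L
  br <- seq(rng[1], rng[2], length.out = nb + 1L)
  counts <- tabulate(findInterval(values, br, rightmost.closed = TRUE), nb)
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mids <- (br[-1] + br[-(nb + 1L)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[nb]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  br[which.max(sigma_b) + 1L]
}
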