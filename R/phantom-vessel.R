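# Fluorescence vessel phantom: CD31-bright annular vessel walls (normal
# thin rings or pathologically thickened walls), a marker channel
# (e.g. P-selectin) bright on a stated fraction of the vessel area, and a
# perivascular collagen halo ring outside each vessel.

#' Vessel phantom specification
#'
#' @param image_shape integer c(H, W), pixels.
#' @param vessels list of vessels, each `list(center = c(y, x),
#'   inner_radius, outer_radius)` in pixels; the wall is the annulus
#'   `inner_radius < d <= outer_radius`.  May be empty.
#' @param marker_coverage fraction of the (filled) vessel area that is
#'   marker-high, in [0, 1].
#' @param collagen_halo_width width in pixels of the perivascular collagen
#'   ring outside each vessel's outer radius.
#' @param background_level,foreground_level channel intensities.
#' @param noise_sigma additive Gaussian noise scale, intensity units.
#' @param seed integer RNG seed.
#' @return object of class `vessel_phantom_spec`.
#' @export
vessel_phantom_spec <- function(image_shape = c(128L, 128L),
                                vessels = list(list(center = c(64, 64),
                                                    inner_radius = 12,
                                                    outer_radius = 20)),
                                marker_coverage = 0.5,
                                collagen_halo_width = 5,
                                background_level = 0.1,
                                foreground_level = 1,
                                noise_sigma = 0,
                                seed = 1L) {
  check_scalar_num(marker_coverage, "marker_coverage", 0, 1)
  check_scalar_num(collagen_halo_width, "collagen_halo_width", 0)
  check_scalar_num(noise_sigma, "noise_sigma", 0)
  if (background_level >= foreground_level)
    stop_bscb("foreground_level must exceed background_level")
  for (v in vessels) {
    if (!(v$outer_radius > v$inner_radius) || v$inner_radius < 0)
      stop_bscb("each vessel needs outer_radius > inner_radius >= 0")
    if (any(v$center - v$outer_radius < 1) ||
        v$center[1] + v$outer_radius > image_shape[1] ||
        v$center[2] + v$outer_radius > image_shape[2])
      stop_bscb("vessel extends outside the image")
  }
  structure(list(image_shape = as.integer(image_shape), vessels = vessels,
                 marker_coverage = marker_coverage,
                 collagen_halo_width = collagen_halo_width,
                 background_level = background_level,
                 foreground_level = foreground_level,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "vessel_phantom_spec")
}

#' Generate a two-channel vessel phantom image
#'
#' Channel `cd31` is bright on every vessel wall annulus; the marker
#' channel is bright on `marker_coverage` of the filled vessel area
#' (innermost pixels first, deterministically); the collagen channel is
#' bright on the walls plus a perivascular halo ring of the stated width.
#' Ground-truth masks (filled vessels, walls, marker, halo) are returned.
#' Overlapping vessels raise a warning and are reported as union geometry.
#'
#' @param spec a [vessel_phantom_spec()].
#' @return list with `image` (a [vessel_image()]) and `truth` (logical
#'   masks: `vessel_filled`, `wall`, `marker`, `halo`).
#' @export
generate_vessel_image <- function(spec) {
  stopifnot(inherits(spec, "vessel_phantom_spec"))
  h <- spec$image_shape[1]; w <- spec$image_shape[2]
  blank <- matrix(FALSE, h, w)
  filled <- wall <- halo <- blank
  dist_min <- matrix(Inf, h, w)  # distance to nearest vessel center
  overlap <- FALSE
  for (v in spec$vessels) {
    g <- pixel_grid(c(h, w), center = v$center)
    f <- g$r <= v$outer_radius
    if (any(f & filled)) overlap <- TRUE
    wall <- wall | (g$r <= v$outer_radius & g$r > v$inner_radius)
    halo <- halo | (g$r > v$outer_radius &
                    g$r <= v$outer_radius + spec$collagen_halo_width)
    filled <- filled | f
    dist_min <- pmin(dist_min, g$r)
  }
  if (overlap) warning("overlapping vessels: reporting union geometry")
  halo <- halo & !filled

  marker <- blank
  n_mark <- round(spec$marker_coverage * sum(filled))
  if (n_mark > 0L) {
    idx <- which(filled)
    marker[idx[order(dist_min[idx], idx)][seq_len(n_mark)]] <- TRUE
  }

  render <- function(mask) {
    img <- matrix(spec$background_level, h, w)
    img[mask] <- spec$foreground_level
    img
  }
  channels <- with_seed(spec$seed, {
    ch <- list(cd31 = render(wall),
               p_selectin = render(marker),
               collagen1 = render(wall | halo))
    if (spec$noise_sigma > 0)
      ch <- lapply(ch, function(x)
        x + matrix(stats::rnorm(length(x), 0, spec$noise_sigma), h, w))
    ch
  })
  img <- vessel_image(channels, region_label = "epicenter",
                      tissue_roi = matrix(TRUE, h, w))
  list(image = img,
       truth = list(vessel_filled = filled, wall = wall,
                    marker = marker, halo = halo))
}

#' Construct a multi-channel vessel image
#'
#' @param channels named list of equal-shape intensity matrices; `cd31`
#'   is required for segmentation, marker/collagen channels optional.
#' @param region_label one of "rostral", "epicenter", "caudal".
#' @param tissue_roi logical matrix restricting analysis (e.g. white
#'   matter); defaults to the whole image.
#' @return object of class `vessel_image`.
#' @export
vessel_image <- function(channels, region_label = "epicenter",
                         tissue_roi = NULL) {
  if (is.null(names(channels)) || any(names(channels) == ""))
    stop_bscb("channels must be a named list")
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1L) stop_bscb("all channels must share one shape")
  region_label <- match.arg(region_label, c("rostral", "epicenter", "caudal"))
  if (is.null(tissue_roi)) tissue_roi <- matrix(TRUE, dims[[1]][1], dims[[1]][2])
  if (!identical(dim(tissue_roi), dims[[1]]))
    stop_bscb("tissue_roi must match the channel shape")
  structure(list(channels = channels, region_label = region_label,
                 tissue_roi = tissue_roi),
            class = "vessel_image")
}
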