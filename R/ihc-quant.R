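# Vascular-pathology quantification from two-channel fluorescence images:
# CD31 vessel segmentation (Canny edges + hole filling), marker area
# within vessels, perivascular collagen area, and per-animal triplicate
# aggregation.

#' Segment vessels from the CD31 channel
#'
#' Canny edge detection on the CD31 channel followed by hole filling of
#' the edge map yields filled vessel lumina+walls.  The single-pixel Canny
#' contour straddles the true vessel boundary, so naively keeping it
#' dilates the mask by about half a pixel; contour pixels with two or more
#' exterior 4-neighbors (convex corners of the outline) are therefore
#' trimmed, which centers the mask boundary on the gradient ridge.  The
#' result is intersected with `tissue_roi` and components below `min_size`
#' pixels are removed (speckle suppression).
#'
#' @param image a [vessel_image()] with a `cd31` channel.
#' @param sigma Canny Gaussian scale, pixels.
#' @param low,high hysteresis thresholds (`NULL`: Otsu-based defaults,
#'   see [canny_edges()]).
#' @param min_size minimum connected-component size in pixels.
#' @return logical vessel mask, with attribute `n_removed` (small
#'   components dropped).
#' @export
segment_vessels <- function(image, sigma = 1.5, low = NULL, high = NULL,
                            min_size = 20L) {
  stopifnot(inherits(image, "vessel_image"))
  if (is.null(image$channels$cd31)) stop_bscb("cd31 channel is required")
  if (!any(image$tissue_roi)) stop_bscb("tissue_roi is empty")
  edges <- canny_edges(image$channels$cd31, sigma = sigma, low = low,
                       high = high, roi = image$tissue_roi)
  filled <- fill_holes(edges)
  ext <- !filled
  n_ext <- shift_mat(ext, 1, 0) + shift_mat(ext, -1, 0) +
    shift_mat(ext, 0, 1) + shift_mat(ext, 0, -1)
  trimmed <- filled & !(edges & n_ext >= 2)
  res <- remove_small_components(trimmed & image$tissue_roi, min_size)
  structure(res$mask, n_removed = res$n_removed)
}

# Marker positivity within a mask: Otsu's threshold computed from the
# within-mask intensities (relative thresholding; scale-invariant).  A
# constant channel is positive everywhere iff its level exceeds 0.
marker_positive <- function(channel, mask) {
  vals <- channel[mask]
  if (diff(range(vals)) == 0) return(mask & (channel > 0))
  mask & channel > otsu_threshold(vals)
}

#' Marker-high area within the segmented vessels
#'
#' Pixels inside `vessel_mask` whose marker intensity exceeds the
#' high-intensity threshold (Otsu within the vessel mask by default).
#'
#' @param image a [vessel_image()].
#' @param vessel_mask logical mask from [segment_vessels()].
#' @param marker channel name (e.g. `"p_selectin"`).
#' @return area in pixels.
#' @export
marker_area_within_vessels <- function(image, vessel_mask, marker = "p_selectin") {
  stopifnot(inherits(image, "vessel_image"))
  ch <- image$channels[[marker]]
  if (is.null(ch)) stop_bscb("missing channel: %s", marker)
  sum(marker_positive(ch, vessel_mask))
}

#' Perivascular collagen area
#'
#' Collagen-positive pixels within the perivascular neighborhood of the
#' vessels (a disk dilation of `vessel_mask` by `neighborhood_radius`)
#' minus the collagen-positive pixels inside the vessels themselves,
#' floored at 0.  Collagen positivity uses the same within-mask Otsu rule
#' as markers, computed over the perivascular neighborhood.
#'
#' @param image a [vessel_image()].
#' @param vessel_mask logical mask from [segment_vessels()].
#' @param collagen channel name (e.g. `"collagen1"`, `"collagen4"`).
#' @param neighborhood_radius dilation radius in pixels.
#' @return area in pixels.
#' @export
perivascular_collagen_area <- function(image, vessel_mask,
                                       collagen = "collagen1",
                                       neighborhood_radius = 10) {
  stopifnot(inherits(image, "vessel_image"))
  ch <- image$channels[[collagen]]
  if (is.null(ch)) stop_bscb("missing channel: %s", collagen)
  neigh <- dilate_disk(vessel_mask, neighborhood_radius)
  pos <- marker_positive(ch, neigh)
  max(0L, sum(pos) - sum(pos & vessel_mask))
}

#' Quantify one vessel image
#'
#' @param image a [vessel_image()].
#' @param marker,collagen channel names (NULL to skip).
#' @param ... passed to [segment_vessels()].
#' @return object of class `vessel_quant`: `cd31_area` (pixels),
#'   `cd31_pct_roi` (percent of tissue_roi), `marker_area`,
#'   `perivascular_collagen_area`, `region_label`.
#' @export
quantify_vessel_image <- function(image, marker = "p_selectin",
                                  collagen = "collagen1", ...) {
  vm <- segment_vessels(image, ...)
  res <- list(cd31_area = sum(vm),
              cd31_pct_roi = 100 * sum(vm) / sum(image$tissue_roi),
              marker_area = if (!is.null(marker) && !is.null(image$channels[[marker]]))
                marker_area_within_vessels(image, vm, marker) else NA_integer_,
              perivascular_collagen_area =
                if (!is.null(collagen) && !is.null(image$channels[[collagen]]))
                  perivascular_collagen_area(image, vm, collagen) else NA_integer_,
              region_label = image$region_label)
  class(res) <- "vessel_quant"
  res
}

#' Aggregate triplicate image quantifications per animal
#'
#' The mean of (nominally three) per-image quantifications of one spinal
#' cord region is the per-animal value.  Fewer than three images raises a
#' warning and averages what is available.
#'
#' @param quants list of `vessel_quant` objects (or numeric vectors of
#'   identical names) from one region of one animal.
#' @return named numeric vector of per-metric means.
#' @export
aggregate_animal <- function(quants) {
  if (!length(quants)) stop_bscb("no images to aggregate")
  if (length(quants) < 3L)
    warning(sprintf("only %d image(s) supplied; averaging available images",
                    length(quants)))
  nums <- lapply(quants, function(q) {
    v <- if (is.numeric(q)) q
         else unlist(q[vapply(q, is.numeric, logical(1))])
    if (is.null(names(v))) names(v) <- paste0("value", seq_along(v))
    v
  })
  metrics <- names(nums[[1]])
  vapply(metrics, function(m)
    mean(vapply(nums, `[[`, numeric(1), m), na.rm = TRUE), numeric(1))
}
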