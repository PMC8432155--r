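#' Disc median filter
#'
#' Noise reduction used on the nuclear channel before thresholding: a median
#' filter over a disc structuring element (all offsets with
#' `dx^2 + dy^2 <= radius^2`), with reflecting border handling.
#'
#' @param img numeric matrix.
#' @param radius disc radius in pixels (default 3, the value used throughout
#'   the nuclear pipeline).
#' @return filtered numeric matrix of the same shape.
#' @export
median_filter_disc <- function(img, radius = 3) {
  stopifnot(is.matrix(img), radius > 0)
  cpp_median_filter_disc(img, radius)
}

#' Label connected components
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix; 0 = background, components numbered from 1 in
#'   raster-scan order of their first pixel.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  cpp_label_components(mask, as.integer(connectivity))
}

#' Fill holes in a binary mask
#'
#' Background regions (4-connected) not reachable from the image border are
#' converted to foreground.
#'
#' @param mask logical matrix.
#' @return logical matrix.
#' @export
fill_holes <- function(mask) {
  stopifnot(is.matrix(mask))
  cpp_fill_holes(mask)
}

#' Exact Euclidean distance transform
#'
#' @param mask logical matrix; distance from each `TRUE` pixel to the nearest
#'   `FALSE` pixel (0 on background).
#' @return numeric matrix of distances in pixels.
#' @export
distance_transform <- function(mask) {
  stopifnot(is.matrix(mask))
  cpp_distance_transform(mask)
}

#' Prominence-based local maxima (ImageJ-style "Find Maxima")
#'
#' A local maximum is accepted iff its prominence -- its height above the
#' highest saddle connecting it to any higher region -- strictly exceeds
#' `noise_tolerance`. The highest maximum of each masked region is measured
#' against the region minimum, so a constant image yields no calls. Plateaus
#' produce one representative pixel (topmost, then leftmost). Only pixels
#' inside `region_mask` take part: connecting paths may not leave the mask.
#'
#' @param img numeric matrix (raw channel-2 intensities; no smoothing is
#'   applied).
#' @param region_mask logical matrix restricting the search, or `NULL` for
#'   the whole image.
#' @param noise_tolerance strictly positive prominence threshold in DN.
#' @return data.frame with columns `row`, `col` (1-based pixel coordinates),
#'   `value` (peak DN) and `prominence`, ordered by (row, col).
#' @export
find_maxima <- function(img, region_mask = NULL, noise_tolerance) {
  stopifnot(is.matrix(img), noise_tolerance > 0)
  if (is.null(region_mask)) {
    region_mask <- matrix(TRUE, nrow(img), ncol(img))
  }
  stopifnot(identical(dim(region_mask), dim(img)))
  m <- cpp_find_maxima(img, region_mask, noise_tolerance)
  data.frame(row = m[, 1] + 1, col = m[, 2] + 1,
             value = m[, 3], prominence = m[, 4])
}

# Separable Gaussian smoothing with replicate padding; used to regularize
# the distance map before marker detection.
gauss_smooth <- function(m, sigma) {
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, 0, sigma)
  k <- k / sum(k)
  nr <- nrow(m); nc <- ncol(m)
  padm <- m[c(rep(1, r), 1:nr, rep(nr, r)),
            c(rep(1, r), 1:nc, rep(nc, r))]
  a <- apply(padm, 2, function(v) stats::filter(v, k)[(r + 1):(r + nr)])
  t(apply(a, 1, function(v) stats::filter(v, k)[(r + 1):(r + nc)]))
}

# Watershed seed markers: prominence-filtered local maxima of the smoothed
# distance map. Discretization ripples on the distance transform vanish
# under Gaussian smoothing, while the second peak of a fused nucleus pair
# (centres >= 1.2 x radius apart) retains positive prominence; a small floor
# in smoothed-distance pixels separates the two. A greedy minimum-separation
# suppression (highest peak first, raster-order ties) then removes duplicate
# plateau survivors.
distance_peaks <- function(dist, mask, min_sep, min_prominence = 0.05,
                           smooth_sigma = 1.5) {
  sm <- if (smooth_sigma > 0) gauss_smooth(dist, smooth_sigma) else dist
  calls <- find_maxima(sm, mask, min_prominence)
  if (nrow(calls) == 0) return(cbind(row = integer(0), col = integer(0)))
  ord <- order(-calls$value, calls$row, calls$col)
  r <- calls$row[ord]; c <- calls$col[ord]
  keep_r <- integer(0); keep_c <- integer(0)
  for (i in seq_along(r)) {
    if (length(keep_r) == 0 ||
        all((keep_r - r[i])^2 + (keep_c - c[i])^2 >= min_sep^2)) {
      keep_r <- c(keep_r, r[i]); keep_c <- c(keep_c, c[i])
    }
  }
  cbind(row = keep_r, col = keep_c)
}
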