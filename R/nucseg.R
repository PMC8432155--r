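#' Otsu threshold from a pooled batch histogram
#'
#' Calibrates one global nuclear-channel threshold for a whole batch of
#' fields: every field's nuclear channel is median-filtered (disc radius
#' `median_radius`), the integer histograms are pooled, and the exhaustive
#' Otsu criterion is applied -- the cut `t` splitting pixels into
#' `{< t}` / `{>= t}` that maximizes the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2`. Ties are resolved to the lowest cut, which
#' is conservative (larger foreground) and deterministic. Foreground is
#' subsequently defined as `value >= threshold`.
#'
#' @param fields a list of `field_image` objects (or a single one).
#' @param median_radius disc radius for the pre-filter, pixels.
#' @return the threshold DN (integer-valued numeric).
#' @export
batch_otsu_threshold <- function(fields, median_radius = 3) {
  if (inherits(fields, "field_image")) fields <- list(fields)
  stopifnot(length(fields) >= 1)
  counts <- numeric(65536)
  for (f in fields) {
    stopifnot(inherits(f, "field_image"))
    filt <- median_filter_disc(f$channels[[1]], median_radius)
    v <- pmin(pmax(round(filt), 0), 65535)
    tb <- tabulate(as.integer(v) + 1L, nbins = 65536L)
    counts <- counts + tb
  }
  otsu_from_counts(counts)
}

# Exhaustive Otsu on a histogram of counts over values 0..(length - 1).
# Returns the smallest threshold t maximizing the between-class variance of
# the split {< t} / {>= t}.
otsu_from_counts <- function(counts) {
  n <- sum(counts)
  vals <- seq_along(counts) - 1
  w0 <- cumsum(counts) / n
  mu_cum <- cumsum(counts * vals) / n
  mu_tot <- mu_cum[length(mu_cum)]
  w1 <- 1 - w0
  # sb[i]: variance for class0 = {<= vals[i]}, i.e. threshold t = vals[i]+1
  sb <- (mu_tot * w0 - mu_cum)^2 / (w0 * w1)
  sb[!is.finite(sb)] <- -Inf
  sb <- sb[-length(sb)]                # cut above the top value is no cut
  if (max(sb) <= 0)
    stop("degenerate histogram: no between-class variance ",
         "(constant-intensity batch)")
  # lowest-tie rule: the smallest threshold realizing the best partition is
  # one above the last value of its lower class
  best <- which(sb == max(sb))[1]
  lower_top <- max(vals[seq_len(best)][counts[seq_len(best)] > 0])
  lower_top + 1
}

#' Segment nuclei in one field
#'
#' The nuclear-channel pipeline: disc median filter (radius 3 px) ->
#' binarize at the supplied threshold (foreground = `>= threshold`) ->
#' fill holes ->
#' split touching nuclei by marker-controlled watershed on the Euclidean
#' distance transform (markers: distance-map local maxima at least
#' `marker_min_sep` px apart) -> discard components smaller than `min_area`
#' -> label consecutively. Per-nucleus geometry and the channel-2 intensity
#' maximum under each footprint are recorded.
#'
#' The threshold may be the frozen batch constant (the default analysis
#' uses a calibrated global value; see [batch_otsu_threshold()]).
#'
#' @param field a `field_image`.
#' @param threshold nuclear-channel DN in (0, 65535).
#' @param min_area minimum nucleus area, pixels.
#' @param median_radius median pre-filter radius, pixels.
#' @param marker_min_sep minimum separation of watershed seed markers,
#'   pixels; of the order of the smallest expected nucleus radius.
#' @param marker_prominence minimum prominence (in smoothed-distance-map
#'   pixels) for a distance peak to seed a basin; suppresses spurious
#'   discretization bumps without losing genuine pair peaks.
#' @param dist_smooth_sigma Gaussian sigma (px) applied to the distance map
#'   before marker detection and flooding; 0 disables smoothing.
#' @return a `nuclear_mask`: list with `labels` (integer matrix, 0 =
#'   background), `threshold_used`, and `nuclei` -- one row per label with
#'   `label`, `area`, `centroid_row`, `centroid_col`, `perimeter`,
#'   `roundness` (`4 pi area / perimeter^2`, clamped to 1),
#'   `mean_nuclear_intensity`, `i_max_ch2`, and placeholders `is_acn`,
#'   `na_count`, `na_area` filled by the inclusion-quantification step.
#' @export
segment_nuclei <- function(field, threshold, min_area = 50,
                           median_radius = 3, marker_min_sep = 8,
                           marker_prominence = 0.05,
                           dist_smooth_sigma = 1.5) {
  stopifnot(inherits(field, "field_image"),
            threshold > 0, threshold < 65535)
  ch1 <- field$channels[[1]]
  ch2 <- if (length(field$channels) >= 2) field$channels[[2]] else NULL
  filt <- median_filter_disc(ch1, median_radius)
  bin <- filt >= threshold
  bin <- fill_holes(bin)
  dist <- distance_transform(bin)
  sm <- if (dist_smooth_sigma > 0) gauss_smooth(dist, dist_smooth_sigma)
        else dist
  peaks <- distance_peaks(dist, bin, marker_min_sep, marker_prominence,
                          dist_smooth_sigma)
  markers <- matrix(0L, nrow(bin), ncol(bin))
  if (nrow(peaks) > 0)
    markers[cbind(peaks[, "row"], peaks[, "col"])] <- seq_len(nrow(peaks))
  lab <- cpp_marker_watershed(sm, markers, bin)
  lab <- absorb_small_basins(lab, min_area)
  # size filter (isolated specks), then consecutive relabeling
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area)
  remap <- integer(length(areas))
  remap[keep] <- seq_along(keep)
  lab[lab > 0] <- remap[lab[lab > 0]]
  nuclei <- nucleus_records(lab, ch1, ch2)
  structure(list(labels = lab, threshold_used = threshold, nuclei = nuclei),
            class = "nuclear_mask")
}

# Merge watershed basins smaller than min_area into the adjacent basin with
# the longest shared boundary; basins with no labeled neighbour (isolated
# specks) are left for the size filter. Iterates smallest-first so chains of
# small fragments coalesce deterministically.
absorb_small_basins <- function(lab, min_area) {
  repeat {
    areas <- tabulate(lab[lab > 0])
    small <- which(areas > 0 & areas < min_area)
    if (length(small) == 0) return(lab)
    small <- small[order(areas[small])]
    changed <- FALSE
    nr <- nrow(lab); nc <- ncol(lab)
    for (s in small) {
      idx <- which(lab == s)
      r <- (idx - 1) %% nr + 1
      c <- (idx - 1) %/% nr + 1
      nb <- integer(0)
      for (sh in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                      c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))) {
        rr <- r + sh[1]; cc <- c + sh[2]
        ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
        v <- lab[cbind(rr[ok], cc[ok])]
        nb <- c(nb, v[v > 0 & v != s])
      }
      if (length(nb) == 0) next
      tb <- table(nb)
      target <- as.integer(names(tb)[which.max(tb)])
      lab[idx] <- target
      changed <- TRUE
    }
    if (!changed) return(lab)
  }
}

# Per-label geometry + intensity table.
nucleus_records <- function(lab, ch1, ch2 = NULL) {
  nlab <- max(lab, 0L)
  empty <- data.frame(label = integer(0), area = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      perimeter = numeric(0), roundness = numeric(0),
                      mean_nuclear_intensity = numeric(0),
                      i_max_ch2 = numeric(0), is_acn = logical(0),
                      na_count = numeric(0), na_area = numeric(0))
  if (nlab == 0) return(empty)
  idx <- which(lab > 0)
  l <- lab[idx]
  nr <- nrow(lab)
  r <- (idx - 1) %% nr + 1
  c <- (idx - 1) %/% nr + 1
  area <- tabulate(l, nbins = nlab)
  crow <- rowsum(r, l)[, 1] / area
  ccol <- rowsum(c, l)[, 1] / area
  meanint <- rowsum(ch1[idx], l)[, 1] / area
  # perimeter: count of 4-neighbour pixel edges between a label and anything
  # else (other label, background, or image border)
  perim <- numeric(nlab)
  pad <- function(m) {
    out <- matrix(0L, nrow(m) + 2, ncol(m) + 2)
    out[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
    out
  }
  lp <- pad(lab)
  nrp <- nrow(lp)
  core <- 2:(nrp - 1)
  ccore <- 2:(ncol(lp) - 1)
  for (sh in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    nb <- lp[core + sh[1], ccore + sh[2]]
    mism <- lab > 0 & nb != lab
    perim <- perim + tabulate(lab[mism], nbins = nlab)
  }
  imax <- if (is.null(ch2)) rep(NA_real_, nlab) else
    vapply(split(ch2[idx], l), max, 0)
  data.frame(label = seq_len(nlab), area = as.numeric(area),
             centroid_row = crow, centroid_col = ccol,
             perimeter = perim,
             roundness = pmin(1, 4 * pi * area / perim^2),
             mean_nuclear_intensity = meanint,
             i_max_ch2 = as.numeric(imax),
             is_acn = NA, na_count = NA_real_, na_area = NA_real_)
}

#' @export
print.nuclear_mask <- function(x, ...) {
  cat(sprintf("<nuclear_mask> %d nuclei (threshold %s), %d x %d px\n",
              nrow(x$nuclei), format(x$threshold_used), nrow(x$labels),
              ncol(x$labels)))
  invisible(x)
}
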