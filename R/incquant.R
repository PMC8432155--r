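#' Classify aggregate-containing nuclei (ACN)
#'
#' A nucleus is aggregate-containing iff its channel-2 intensity maximum is
#' strictly greater than `acn_threshold` (a nucleus at exactly the
#' threshold is not an ACN).
#'
#' @param mask a `nuclear_mask` from [segment_nuclei()].
#' @param acn_threshold channel-2 DN (default 2000, the frozen analysis
#'   constant).
#' @return the mask with `nuclei$is_acn` filled, plus attribute-free list
#'   fields: `pct_acn` = 100 x #ACN / total cells, `NA` when the field has
#'   no nuclei (missing, not zero).
#' @export
classify_acn <- function(mask, acn_threshold = 2000) {
  stopifnot(inherits(mask, "nuclear_mask"), acn_threshold > 0)
  mask$nuclei$is_acn <- mask$nuclei$i_max_ch2 > acn_threshold
  tot <- nrow(mask$nuclei)
  mask$pct_acn <- if (tot == 0) metric_missing() else
    100 * sum(mask$nuclei$is_acn) / tot
  mask
}

# find_maxima restricted to one label's bounding box (identical result,
# much faster than scanning the full field per nucleus).
maxima_in_label <- function(ch2, labels, lab, noise_tolerance) {
  idx <- which(labels == lab)
  nr <- nrow(labels)
  r <- (idx - 1) %% nr + 1
  c <- (idx - 1) %/% nr + 1
  rr <- range(r); cc <- range(c)
  sub <- ch2[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  subm <- labels[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE] == lab
  calls <- find_maxima(sub, subm, noise_tolerance)
  if (nrow(calls) > 0) {
    calls$row <- calls$row + rr[1] - 1
    calls$col <- calls$col + cc[1] - 1
  }
  calls
}

#' Count nuclear aggregates per aggregate-containing nucleus
#'
#' Runs prominence-based maxima detection (tolerance `noise_tolerance`,
#' default 150) restricted to each ACN's footprint. Non-ACN nuclei
#' contribute nothing (count 0). The per-field summary `nas_per_acn` is the
#' mean count over ACNs, missing when the field has no ACN.
#'
#' @param mask a `nuclear_mask` with `is_acn` set (see [classify_acn()]).
#' @param ch2 the raw channel-2 matrix.
#' @param noise_tolerance prominence threshold, DN.
#' @return the mask with `nuclei$na_count` filled and fields `nas_per_acn`
#'   and `nuclear_spot_calls` (data.frame of calls with `parent_label`).
#' @export
count_nuclear_aggregates <- function(mask, ch2, noise_tolerance = 150) {
  stopifnot(inherits(mask, "nuclear_mask"))
  if (any(is.na(mask$nuclei$is_acn)))
    stop("run classify_acn() before counting nuclear aggregates")
  n <- nrow(mask$nuclei)
  mask$nuclei$na_count <- 0
  calls_all <- list()
  for (i in seq_len(n)) {
    if (!mask$nuclei$is_acn[i]) next
    calls <- maxima_in_label(ch2, mask$labels, mask$nuclei$label[i],
                             noise_tolerance)
    mask$nuclei$na_count[i] <- nrow(calls)
    if (nrow(calls) > 0) {
      calls$parent_label <- mask$nuclei$label[i]
      calls_all[[length(calls_all) + 1]] <- calls
    }
  }
  acn <- mask$nuclei$is_acn
  mask$nas_per_acn <- if (!any(acn)) metric_missing() else
    mean(mask$nuclei$na_count[acn])
  mask$nuclear_spot_calls <- if (length(calls_all) > 0)
    do.call(rbind, calls_all) else
    data.frame(row = numeric(0), col = numeric(0), value = numeric(0),
               prominence = numeric(0), parent_label = integer(0))
  mask
}

#' Count extra-nuclear aggregates
#'
#' Maxima detection applied outside the nuclear mask (label 0 pixels only),
#' tolerance 150 by default; the count is expressed per total cell count of
#' the same field.
#'
#' @inheritParams count_nuclear_aggregates
#' @return list with `count`, `enas_per_cell` (missing when the field has
#'   no cells), and `calls`.
#' @export
extra_nuclear_aggregates <- function(mask, ch2, noise_tolerance = 150) {
  stopifnot(inherits(mask, "nuclear_mask"))
  calls <- find_maxima(ch2, mask$labels == 0L, noise_tolerance)
  tot <- nrow(mask$nuclei)
  list(count = nrow(calls),
       enas_per_cell = if (tot == 0) metric_missing() else nrow(calls) / tot,
       calls = calls)
}

#' Count total aggregates over the whole field
#'
#' Maxima detection over the entire channel-2 image (no mask restriction),
#' with the higher tolerance 1000, expressed per total cell count.
#'
#' @param ch2 raw channel-2 matrix.
#' @param tot_cells total cell count of the field.
#' @param noise_tolerance prominence threshold, DN.
#' @return list with `count` and `tot_aggs_per_cell` (missing when
#'   `tot_cells` is 0).
#' @export
total_aggregates <- function(ch2, tot_cells, noise_tolerance = 1000) {
  calls <- find_maxima(ch2, NULL, noise_tolerance)
  list(count = nrow(calls),
       tot_aggs_per_cell = if (tot_cells == 0) metric_missing() else
         nrow(calls) / tot_cells,
       calls = calls)
}

#' Nuclear aggregate area
#'
#' Within the footprints of aggregate-containing nuclei only, channel-2
#' pixels strictly above `area_threshold` (default 969) count as aggregate
#' area. The field ratio `na_area_frac` divides the summed aggregate area
#' by the summed area of all nuclei in the field (not only ACNs).
#'
#' @inheritParams count_nuclear_aggregates
#' @param area_threshold channel-2 DN defining aggregate pixels.
#' @param denominator `"all_nuclei"` (literal reading, default) or
#'   `"acn_only"`.
#' @return the mask with `nuclei$na_area` filled and field `na_area_frac`
#'   (missing when there are no nuclei).
#' @export
aggregate_area <- function(mask, ch2, area_threshold = 969,
                           denominator = c("all_nuclei", "acn_only")) {
  stopifnot(inherits(mask, "nuclear_mask"), area_threshold > 0)
  denominator <- match.arg(denominator)
  if (any(is.na(mask$nuclei$is_acn)))
    stop("run classify_acn() before measuring aggregate area")
  mask$nuclei$na_area <- 0
  for (i in seq_len(nrow(mask$nuclei))) {
    if (!mask$nuclei$is_acn[i]) next
    foot <- mask$labels == mask$nuclei$label[i]
    mask$nuclei$na_area[i] <- sum(ch2[foot] > area_threshold)
  }
  denom <- if (denominator == "all_nuclei") sum(mask$nuclei$area) else
    sum(mask$nuclei$area[mask$nuclei$is_acn])
  mask$na_area_frac <- if (nrow(mask$nuclei) == 0 || denom == 0)
    metric_missing() else sum(mask$nuclei$na_area) / denom
  mask
}

#' Mean background intensity
#'
#' Mean of all channel-2 pixels strictly below `cutoff` (default 2000),
#' over the whole field: the diffuse signal remaining after all aggregates
#' are excluded.
#'
#' @param ch2 raw channel-2 matrix.
#' @param cutoff DN.
#' @return list with `mean` plus pooling helpers `sum` and `n`.
#' @export
mean_background <- function(ch2, cutoff = 2000) {
  v <- ch2[ch2 < cutoff]
  list(mean = if (length(v) == 0) metric_missing() else mean(v),
       sum = sum(v), n = length(v))
}

#' Median per-nucleus channel-2 maximum
#'
#' @param i_max vector of per-nucleus channel-2 maxima (pooled over all
#'   fields of a well).
#' @return the median, or missing for an empty input.
#' @export
median_imax <- function(i_max) {
  if (length(i_max) == 0) metric_missing() else median(i_max)
}

#' Perinuclear ring intensity
#'
#' Simplified cytoplasmic readout standing in for a proprietary
#' find-cytoplasm implementation: each nucleus footprint is dilated by
#' `ring_width` pixels into the background, contested pixels going to the
#' geodesically nearest nucleus; the per-nucleus ring mean of the marker
#' channel is reported. Rings at the image border are clipped to available
#' pixels.
#'
#' @param mask a `nuclear_mask`.
#' @param marker_channel raster of the neuronal-marker channel.
#' @param ring_width ring thickness, pixels.
#' @return the mask with `nuclei$ring_mean` added, plus
#'   `ring_acn_ratio` = mean ring intensity of ACNs / mean of non-ACNs
#'   (NA unless `is_acn` is set and both groups are non-empty).
#' @export
perinuclear_intensity <- function(mask, marker_channel, ring_width = 3) {
  stopifnot(inherits(mask, "nuclear_mask"), ring_width > 0)
  lab <- mask$labels
  inside <- lab > 0L
  d_out <- distance_transform(!inside)   # distance from bg to nearest nucleus
  ring_zone <- !inside & d_out <= ring_width & d_out > 0
  grow_mask <- inside | ring_zone
  # flood outwards: nearer pixels claimed first
  ext <- cpp_marker_watershed(-d_out, lab, grow_mask)
  n <- nrow(mask$nuclei)
  rm <- rep(NA_real_, n)
  ridx <- which(ring_zone)
  if (length(ridx) > 0) {
    rl <- ext[ridx]
    sums <- rowsum(marker_channel[ridx], rl)
    cnts <- rowsum(rep(1, length(ridx)), rl)
    got <- as.integer(rownames(sums))
    means <- sums[, 1] / cnts[, 1]
    rm[match(got, mask$nuclei$label)] <- means
  }
  mask$nuclei$ring_mean <- rm
  acn <- mask$nuclei$is_acn
  mask$ring_acn_ratio <- if (!any(is.na(acn)) && any(acn) && any(!acn))
    mean(rm[acn], na.rm = TRUE) / mean(rm[!acn], na.rm = TRUE) else NA_real_
  mask
}

#' Marker-positive fraction
#'
#' Percentage of nuclei whose perinuclear ring mean of the marker channel
#' strictly exceeds `marker_threshold` -- the simplified
#' neuronal-population readout.
#'
#' @inheritParams perinuclear_intensity
#' @param marker_threshold DN; `NULL` asks for an Otsu threshold over the
#'   ring means.
#' @return percentage in \[0, 100\], missing for a field without nuclei.
#' @export
marker_positive_fraction <- function(mask, marker_channel,
                                     marker_threshold = NULL,
                                     ring_width = 3) {
  if (is.null(mask$nuclei$ring_mean))
    mask <- perinuclear_intensity(mask, marker_channel, ring_width)
  rm <- mask$nuclei$ring_mean
  if (length(rm) == 0) return(metric_missing())
  if (is.null(marker_threshold)) {
    counts <- tabulate(as.integer(pmin(pmax(round(rm), 0), 65535)) + 1L,
                       nbins = 65536L)
    marker_threshold <- otsu_from_counts(counts)
  }
  100 * sum(rm > marker_threshold, na.rm = TRUE) / length(rm)
}

#' Quantify one field end to end
#'
#' Convenience wrapper chaining ACN classification, nuclear/extra-nuclear/
#' total spot calling, aggregate area and background for a single field.
#'
#' @param field a `field_image` (channel 2 = anti-HTT stain).
#' @param mask its `nuclear_mask`.
#' @param acn_threshold,na_tolerance,ena_tolerance,tot_tolerance,
#'   area_threshold,background_cutoff the frozen analysis constants.
#' @return a `field_quant` list: updated `mask`, per-field tallies used for
#'   per-well pooling, and the metric values for this field alone.
#' @export
quantify_field <- function(field, mask, acn_threshold = 2000,
                           na_tolerance = 150, ena_tolerance = 150,
                           tot_tolerance = 1000, area_threshold = 969,
                           background_cutoff = 2000) {
  ch2 <- field$channels[[2]]
  mask <- classify_acn(mask, acn_threshold)
  mask <- count_nuclear_aggregates(mask, ch2, na_tolerance)
  mask <- aggregate_area(mask, ch2, area_threshold)
  ena <- extra_nuclear_aggregates(mask, ch2, ena_tolerance)
  tot <- total_aggregates(ch2, nrow(mask$nuclei), tot_tolerance)
  bg <- mean_background(ch2, background_cutoff)
  structure(list(
    well_id = field$well_id, field_id = field$field_id,
    line_label = field$line_label, day = field$day,
    mask = mask,
    tot_cells = nrow(mask$nuclei),
    n_acn = sum(mask$nuclei$is_acn),
    sum_na_count = sum(mask$nuclei$na_count),
    n_ena = ena$count,
    n_tot_aggs = tot$count,
    sum_na_area = sum(mask$nuclei$na_area),
    sum_nuclear_area = sum(mask$nuclei$area),
    i_max = mask$nuclei$i_max_ch2,
    bg_sum = bg$sum, bg_n = bg$n,
    pct_acn = mask$pct_acn, nas_per_acn = mask$nas_per_acn,
    enas_per_cell = ena$enas_per_cell,
    tot_aggs_per_cell = tot$tot_aggs_per_cell,
    na_area_frac = mask$na_area_frac,
    mean_background = bg$mean), class = "field_quant")
}

#' Pool field quantifications into well-level metrics
#'
#' Counts are summed across the fields of a well before ratios are formed
#' (ratios of sums, not means of ratios), and the per-nucleus channel-2
#' maxima of all fields are pooled for the well median. Ratios with zero
#' denominators are missing, not 0.
#'
#' @param quants list of `field_quant` objects belonging to one well.
#' @return one-row data.frame with columns `tot_cells`, `median_imax`,
#'   `pct_acn`, `nas_per_acn`, `mean_background`, `enas_per_cell`,
#'   `tot_aggs_per_cell`, `nas_per_cell`, `na_area_frac`.
#' @export
well_metrics <- function(quants) {
  stopifnot(length(quants) >= 1)
  g <- function(f) sum(vapply(quants, function(q) q[[f]], 0))
  tot <- g("tot_cells"); nacn <- g("n_acn"); nna <- g("sum_na_count")
  rat <- function(num, den) if (den == 0) metric_missing() else num / den
  data.frame(
    well_id = quants[[1]]$well_id,
    line_label = quants[[1]]$line_label,
    day = quants[[1]]$day,
    tot_cells = tot,
    median_imax = median_imax(unlist(lapply(quants, `[[`, "i_max"))),
    pct_acn = if (tot == 0) metric_missing() else 100 * nacn / tot,
    nas_per_acn = rat(nna, nacn),
    mean_background = rat(g("bg_sum"), g("bg_n")),
    enas_per_cell = rat(g("n_ena"), tot),
    tot_aggs_per_cell = rat(g("n_tot_aggs"), tot),
    nas_per_cell = rat(nna, tot),
    na_area_frac = rat(g("sum_na_area"), g("sum_nuclear_area")))
}
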