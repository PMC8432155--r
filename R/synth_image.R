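#' Specification for one synthetic high-content field
#'
#' Describes the stated world of one simulated two-channel fluorescence
#' field: channel 1 carries nuclei (smooth discs on a dark background),
#' channel 2 carries diffuse cytoplasmic signal, bright intra-nuclear
#' inclusion puncta in a configurable fraction of nuclei, and sparse dimmer
#' extra-nuclear puncta. Gaussian read noise is added to both channels and
#' clipped to the 16-bit range; Poisson shot noise is deliberately omitted.
#'
#' Defaults are chosen so that the frozen analysis constants of the imaging
#' pipeline apply directly: nuclei (1250+ DN at their rendered edge) clear
#' the nuclear threshold, planted nuclear peaks exceed the 2000 DN
#' inclusion-nucleus threshold while cytoplasm plus noise stays far below
#' it, and extra-nuclear puncta are dimmer (below 2000 DN) but prominent
#' enough (> 150 DN over cytoplasm) for spot calling.
#'
#' @param field_shape integer (rows, cols) of the field in pixels.
#' @param n_nuclei number of nuclei to plant.
#' @param touching_pair_fraction fraction of nuclei that belong to touching
#'   pairs (placed at centre distance 1.2-1.6 x radius so thresholding fuses
#'   them into one blob with a detectable neck).
#' @param nucleus_radius_range (min, max) nucleus radius in pixels.
#' @param nucleus_intensity_range (min, max) nuclear-channel plateau DN.
#' @param acn_fraction fraction of nuclei carrying inclusions.
#' @param spots_per_acn_range (min, max) inclusion count per carrying
#'   nucleus.
#' @param spot_peak_range (min, max) absolute channel-2 peak DN of nuclear
#'   inclusions (before noise); must exceed `cytoplasm_level`.
#' @param spot_sigma Gaussian sigma of puncta, pixels.
#' @param ena_density number of extra-nuclear puncta per field.
#' @param ena_peak_range (min, max) absolute peak DN of extra-nuclear
#'   puncta.
#' @param cytoplasm_level diffuse channel-2 background DN.
#' @param noise_sd Gaussian read-noise standard deviation, DN.
#' @param seed integer seed; identical spec (including seed) gives
#'   bit-identical output.
#' @return an object of class `synth_image_spec`.
#' @export
synth_image_spec <- function(field_shape = c(512L, 512L),
                             n_nuclei = 50L,
                             touching_pair_fraction = 0.2,
                             nucleus_radius_range = c(8, 14),
                             nucleus_intensity_range = c(2500, 6000),
                             acn_fraction = 0.2,
                             spots_per_acn_range = c(1L, 4L),
                             spot_peak_range = c(2500, 6000),
                             spot_sigma = 1.5,
                             ena_density = 5L,
                             ena_peak_range = c(1200, 1800),
                             cytoplasm_level = 500,
                             noise_sd = 20,
                             seed = 1L) {
  spec <- list(field_shape = as.integer(field_shape),
               n_nuclei = as.integer(n_nuclei),
               touching_pair_fraction = touching_pair_fraction,
               nucleus_radius_range = nucleus_radius_range,
               nucleus_intensity_range = nucleus_intensity_range,
               acn_fraction = acn_fraction,
               spots_per_acn_range = as.integer(spots_per_acn_range),
               spot_peak_range = spot_peak_range,
               spot_sigma = spot_sigma,
               ena_density = as.integer(ena_density),
               ena_peak_range = ena_peak_range,
               cytoplasm_level = cytoplasm_level,
               noise_sd = noise_sd,
               seed = as.integer(seed))
  validate_synth_image_spec(spec)
  structure(spec, class = "synth_image_spec")
}

validate_synth_image_spec <- function(s) {
  stopifnot(length(s$field_shape) == 2, all(s$field_shape >= 32),
            s$n_nuclei >= 0,
            s$touching_pair_fraction >= 0, s$touching_pair_fraction <= 1,
            s$acn_fraction >= 0, s$acn_fraction <= 1,
            all(s$nucleus_radius_range > 0),
            diff(s$nucleus_radius_range) >= 0,
            s$spot_sigma > 0,
            all(s$spots_per_acn_range >= 1),
            all(s$spot_peak_range > s$cytoplasm_level),
            s$ena_density >= 0,
            all(s$ena_peak_range > s$cytoplasm_level),
            s$cytoplasm_level >= 0, s$noise_sd >= 0)
  invisible(s)
}

# Evaluate fn with the RNG seeded at `seed`, restoring global RNG state.
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  fn()
}

new_field_image <- function(channels, well_id = "A01", field_id = 1L,
                            line_label = NA_character_, day = NA_integer_) {
  stopifnot(length(channels) >= 2)
  structure(list(channels = channels, well_id = well_id,
                 field_id = as.integer(field_id), line_label = line_label,
                 day = as.integer(day)),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf("<field_image> well %s field %d: %d channel(s), %d x %d px\n",
              x$well_id, x$field_id, length(x$channels),
              nrow(x$channels[[1]]), ncol(x$channels[[1]])))
  invisible(x)
}

# Deterministic spot-count assignment: n counts whose mean is as close to m
# as integer granularity allows, each within [lo, hi].
quota_counts <- function(n, m, lo, hi) {
  m <- min(max(m, lo), hi)
  base <- floor(m)
  n_hi <- round((m - base) * n)
  k <- c(rep(base + 1, n_hi), rep(base, n - n_hi))
  pmin(pmax(k, lo), hi)
}

#' Generate one synthetic field with ground truth
#'
#' Renders the world described by a [synth_image_spec()]: channel 1 nuclei
#' as radially smoothed discs (logistic edge profile, width 0.5 px), channel
#' 2 as diffuse cytoplasm plus isotropic Gaussian puncta, then i.i.d.
#' Gaussian noise clipped to \[0, 65535\] and rounded to integer DN.
#' Touching pairs share one radius and are placed at centre distance
#' 1.2-1.6 x radius; all other nuclei keep a clearance of at least 8 px
#' between footprints. Nuclear puncta sit at least 3 sigma inside their
#' parent's footprint and at least 4 sigma apart; extra-nuclear puncta stay
#' at least 4 sigma clear of every nucleus footprint.
#'
#' @param spec a [synth_image_spec()].
#' @param well_id,field_id,line_label,day metadata carried on the result.
#' @param spot_counts optional integer vector overriding the per-nucleus
#'   inclusion counts (one entry per carrying nucleus, recycled); when
#'   `NULL`, counts are drawn uniformly from `spots_per_acn_range`.
#' @return a list with elements `field` (a `field_image`) and `truth`
#'   (a `ground_truth`: data frames `nuclei`, `nuclear_spots`,
#'   `extra_nuclear_spots`; planted peaks are amplitudes before noise).
#' @export
make_field <- function(spec, well_id = "A01", field_id = 1L,
                       line_label = NA_character_, day = NA_integer_,
                       spot_counts = NULL) {
  validate_synth_image_spec(spec)
  with_seed(spec$seed, function() {
    nr <- spec$field_shape[1]; nc <- spec$field_shape[2]
    n_pairs <- round(spec$touching_pair_fraction * spec$n_nuclei / 2)
    n_single <- spec$n_nuclei - 2 * n_pairs

    nuc <- data.frame(id = integer(0), row = numeric(0), col = numeric(0),
                      radius = numeric(0), intensity = numeric(0),
                      pair_id = integer(0))
    place_one <- function(radius, partner = NULL) {
      for (try in 1:500) {
        if (is.null(partner)) {
          m <- radius + 6
          r0 <- runif(1, m, nr - m); c0 <- runif(1, m, nc - m)
        } else {
          d <- runif(1, 1.2, 1.6) * radius
          th <- runif(1, 0, 2 * pi)
          r0 <- partner[1] + d * sin(th); c0 <- partner[2] + d * cos(th)
          m <- radius + 6
          if (r0 < m || r0 > nr - m || c0 < m || c0 > nc - m) next
        }
        ok <- TRUE
        if (nrow(nuc) > 0) {
          dd <- sqrt((nuc$row - r0)^2 + (nuc$col - c0)^2)
          lim <- nuc$radius + radius + 8
          if (!is.null(partner)) {
            skip <- abs(nuc$row - partner[1]) < 1e-9 &
              abs(nuc$col - partner[2]) < 1e-9
            ok <- all(dd[!skip] >= lim[!skip])
          } else {
            ok <- all(dd >= lim)
          }
        }
        if (ok) return(c(r0, c0))
      }
      stop("nucleus placement failed after bounded retries; ",
           "reduce n_nuclei or enlarge field_shape")
    }
    pid <- 0L
    for (p in seq_len(n_pairs)) {
      rad <- runif(1, spec$nucleus_radius_range[1], spec$nucleus_radius_range[2])
      a <- place_one(rad)
      b <- place_one(rad, partner = a)
      pid <- pid + 1L
      for (ctr in list(a, b)) {
        nuc <- rbind(nuc, data.frame(
          id = nrow(nuc) + 1L, row = ctr[1], col = ctr[2], radius = rad,
          intensity = runif(1, spec$nucleus_intensity_range[1],
                            spec$nucleus_intensity_range[2]),
          pair_id = pid))
      }
    }
    for (s in seq_len(n_single)) {
      rad <- runif(1, spec$nucleus_radius_range[1], spec$nucleus_radius_range[2])
      ctr <- place_one(rad)
      nuc <- rbind(nuc, data.frame(
        id = nrow(nuc) + 1L, row = ctr[1], col = ctr[2], radius = rad,
        intensity = runif(1, spec$nucleus_intensity_range[1],
                          spec$nucleus_intensity_range[2]),
        pair_id = NA_integer_))
    }

    ch1 <- matrix(0, nr, nc)
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    for (i in seq_len(nrow(nuc))) {
      w <- ceiling(nuc$radius[i] + 5)
      rr <- max(1, floor(nuc$row[i] - w)):min(nr, ceiling(nuc$row[i] + w))
      cc <- max(1, floor(nuc$col[i] - w)):min(nc, ceiling(nuc$col[i] + w))
      d <- sqrt(outer((rr - nuc$row[i])^2, (cc - nuc$col[i])^2, "+"))
      # overlapping nuclei composite by maximum, not sum: the rendered
      # footprint of a touching pair is then the union of the two discs,
      # keeping the neck between them detectable
      ch1[rr, cc] <- pmax(ch1[rr, cc],
                          nuc$intensity[i] / (1 + exp((d - nuc$radius[i]) / 0.5)))
    }

    ch2 <- matrix(spec$cytoplasm_level, nr, nc)
    sig <- spec$spot_sigma
    add_spot <- function(img, r0, c0, amp) {
      w <- ceiling(4 * sig)
      rr <- max(1, r0 - w):min(nr, r0 + w)
      cc <- max(1, c0 - w):min(nc, c0 + w)
      d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
      img[rr, cc] <- img[rr, cc] + amp * exp(-d2 / (2 * sig^2))
      img
    }

    n_acn <- round(spec$acn_fraction * spec$n_nuclei)
    acn_ids <- if (n_acn > 0) sort(sample(nuc$id, n_acn)) else integer(0)
    nspots <- data.frame(nucleus = integer(0), row = integer(0),
                         col = integer(0), peak = numeric(0))
    for (iacn in seq_along(acn_ids)) {
      id <- acn_ids[iacn]
      k <- if (is.null(spot_counts)) {
        sample(seq(spec$spots_per_acn_range[1],
                   spec$spots_per_acn_range[2]), 1)
      } else {
        spot_counts[(iacn - 1) %% length(spot_counts) + 1]
      }
      rad <- nuc$radius[id]
      placed <- matrix(numeric(0), 0, 2)
      inner <- max(rad - 3 * sig, 1)
      for (j in seq_len(k)) {
        for (try in 1:100) {
          a <- runif(1, 0, 2 * pi); d <- sqrt(runif(1)) * inner
          r0 <- round(nuc$row[id] + d * sin(a))
          c0 <- round(nuc$col[id] + d * cos(a))
          if ((r0 - nuc$row[id])^2 + (c0 - nuc$col[id])^2 > inner^2) next
          if (nrow(placed) == 0 ||
              all((placed[, 1] - r0)^2 + (placed[, 2] - c0)^2 >=
                  (4 * sig)^2)) {
            placed <- rbind(placed, c(r0, c0))
            break
          }
        }
      }
      for (j in seq_len(nrow(placed))) {
        peak <- runif(1, spec$spot_peak_range[1], spec$spot_peak_range[2])
        ch2 <- add_spot(ch2, placed[j, 1], placed[j, 2],
                        peak - spec$cytoplasm_level)
        nspots <- rbind(nspots, data.frame(
          nucleus = id, row = placed[j, 1], col = placed[j, 2], peak = peak))
      }
    }

    espots <- data.frame(row = integer(0), col = integer(0),
                         peak = numeric(0))
    w_edge <- ceiling(4 * sig)
    for (j in seq_len(spec$ena_density)) {
      for (try in 1:500) {
        r0 <- round(runif(1, 1 + w_edge, nr - w_edge))
        c0 <- round(runif(1, 1 + w_edge, nc - w_edge))
        dd <- if (nrow(nuc) > 0)
          sqrt((nuc$row - r0)^2 + (nuc$col - c0)^2) - nuc$radius else Inf
        clear_nuc <- all(dd >= 4 * sig)
        clear_ena <- nrow(espots) == 0 ||
          all((espots$row - r0)^2 + (espots$col - c0)^2 >= (6 * sig)^2)
        if (clear_nuc && clear_ena) {
          peak <- runif(1, spec$ena_peak_range[1], spec$ena_peak_range[2])
          ch2 <- add_spot(ch2, r0, c0, peak - spec$cytoplasm_level)
          espots <- rbind(espots,
                          data.frame(row = r0, col = c0, peak = peak))
          break
        }
      }
    }

    clipr <- function(m) {
      m <- m + rnorm(length(m), 0, spec$noise_sd)
      matrix(as.integer(pmin(pmax(round(m), 0), 65535)), nr, nc)
    }
    field <- new_field_image(list(clipr(ch1), clipr(ch2)),
                             well_id = well_id, field_id = field_id,
                             line_label = line_label, day = day)
    truth <- structure(list(nuclei = nuc, nuclear_spots = nspots,
                            extra_nuclear_spots = espots),
                       class = "ground_truth")
    list(field = field, truth = truth)
  })
}

#' Generate an allelic-series plate
#'
#' Builds a plate of synthetic fields over a grid of cell lines and days of
#' differentiation, emulating a CAG-length allelic series: the planted
#' fraction of inclusion-carrying nuclei and the planted inclusions per
#' carrying nucleus are non-decreasing in an assigned per-line severity and
#' in day, and are exactly zero for severity-0 (control) lines and before
#' day 7 (inclusions appear only after differentiation is under way).
#'
#' Planted burdens follow
#' `acn_fraction(s, d) = min(0.9, s * (0.06 + 0.03 * (d - 7)))` and
#' `spots_per_acn_mean(s, d) = 1 + min(3, s * (0.3 + 0.5 * (d - 7)/7))`
#' for `d >= 7`, both zero-inclusion for `d < 7`. Spot counts are assigned
#' by deterministic quota so the planted per-cell mean equals the target up
#' to integer granularity.
#'
#' @param template a [synth_image_spec()] supplying geometry, intensities
#'   and noise; its `acn_fraction` and `spots_per_acn_range` are overridden
#'   per line/day. Its `seed` seeds the whole plate.
#' @param lines character vector of line labels.
#' @param days integer vector of days of differentiation.
#' @param severity named numeric vector (>= 0) mapping each line label to a
#'   severity; defaults to 0, 1, 2, ... in order of `lines`.
#' @param wells_per_line number of wells per line at each day.
#' @return list with `plate` (list of per-well entries: `well_id`,
#'   `line_label`, `day`, `field`, `truth`, `planted_acn_fraction`,
#'   `planted_spots_mean`) and `layout` (data.frame).
#' @export
make_allelic_series <- function(template, lines, days,
                                severity = setNames(seq_along(lines) - 1,
                                                    lines),
                                wells_per_line = 16L) {
  if (length(lines) == 0 || length(days) == 0)
    stop("lines and days must be non-empty")
  stopifnot(all(lines %in% names(severity)), all(severity >= 0))
  plate <- list()
  layout <- data.frame(well_id = character(0), line_label = character(0),
                       day = integer(0))
  widx <- 0L
  for (li in seq_along(lines)) {
    s <- severity[[lines[li]]]
    for (d in days) {
      ramp <- if (d < 7) 0 else 0.06 + 0.03 * (d - 7)
      acn <- min(0.9, s * ramp)
      spot_mean <- if (d < 7) 1 else 1 + min(3, s * (0.3 + 0.5 * (d - 7) / 7))
      for (w in seq_len(wells_per_line)) {
        widx <- widx + 1L
        spec_w <- template
        spec_w$acn_fraction <- acn
        spec_w$seed <- (template$seed * 7919L + widx * 104729L) %% 2147483647L
        class(spec_w) <- "synth_image_spec"
        well_id <- sprintf("W%03d", widx)
        fg <- make_field_quota(spec_w, spot_mean, well_id = well_id,
                               line_label = lines[li], day = d)
        fg$planted_acn_fraction <-
          round(acn * template$n_nuclei) / template$n_nuclei
        fg$planted_spots_mean <- spot_mean
        plate[[widx]] <- fg
        layout <- rbind(layout, data.frame(well_id = well_id,
                                           line_label = lines[li],
                                           day = d))
      }
    }
  }
  list(plate = plate, layout = layout)
}

# make_field with quota-assigned spot counts targeting a given per-ACN mean.
make_field_quota <- function(spec, spot_mean, ...) {
  n_acn <- round(spec$acn_fraction * spec$n_nuclei)
  if (n_acn > 0) {
    ks <- quota_counts(n_acn, spot_mean, spec$spots_per_acn_range[1],
                       spec$spots_per_acn_range[2])
    make_field(spec, spot_counts = ks, ...)
  } else {
    make_field(spec, ...)
  }
}
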