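# Build a hand-crafted mask + channel-2 pair for exact arithmetic checks:
# three 10x10 square "nuclei" on a 40x40 field.
toy_mask <- function(ch2_vals = c(1999, 2001, 500)) {
  lab <- matrix(0L, 40, 40)
  lab[3:12, 3:12] <- 1L
  lab[3:12, 20:29] <- 2L
  lab[25:34, 3:12] <- 3L
  ch2 <- matrix(100, 40, 40)
  ch2[6, 6] <- ch2_vals[1]
  ch2[6, 24] <- ch2_vals[2]
  ch2[29, 6] <- ch2_vals[3]
  ch1 <- matrix(0, 40, 40)
  ch1[lab > 0] <- 5000
  mask <- structure(list(labels = lab, threshold_used = 144,
                         nuclei = polyQscreen:::nucleus_records(lab, ch1, ch2)),
                    class = "nuclear_mask")
  list(mask = mask, ch2 = ch2)
}

test_that("ACN classification is strictly greater-than", {
  t <- toy_mask(c(1999, 2000, 2001))
  m <- classify_acn(t$mask, 2000)
  expect_identical(m$nuclei$is_acn, c(FALSE, FALSE, TRUE))
  expect_equal(m$pct_acn, 100 / 3)
  # one ACN of 10 nuclei -> 10%
  t2 <- toy_mask(c(2001, 100, 100))
  m2 <- classify_acn(t2$mask, 2000)
  expect_equal(m2$pct_acn, 100 * 1 / 3)
  # empty mask: missing, not zero
  blank <- segment_nuclei(polyQscreen:::new_field_image(
    list(matrix(0, 32, 32), matrix(0, 32, 32))), 144)
  expect_true(is.na(classify_acn(blank)$pct_acn))
})

test_that("nuclear aggregate counting is restricted to ACN footprints", {
  t <- toy_mask(c(3000, 100, 100))
  m <- classify_acn(t$mask, 2000)
  m <- count_nuclear_aggregates(m, t$ch2, 150)
  expect_equal(m$nuclei$na_count, c(1, 0, 0))
  expect_equal(m$nas_per_acn, 1)
  expect_equal(m$nuclear_spot_calls$parent_label, 1L)
  # no ACNs: metric missing, not 0
  t0 <- toy_mask(c(100, 100, 100))
  m0 <- count_nuclear_aggregates(classify_acn(t0$mask, 2000), t0$ch2, 150)
  expect_true(is.na(m0$nas_per_acn))
  # requires classification first
  expect_error(count_nuclear_aggregates(t0$mask, t0$ch2), "classify_acn")
})

test_that("spot calls partition into nuclear xor extra-nuclear", {
  sp <- synth_image_spec(seed = 23)
  e <- make_field(sp)
  mk <- segment_nuclei(e$field, 144)
  ch2 <- e$field$channels[[2]]
  mk <- classify_acn(mk, 2000)
  mk <- count_nuclear_aggregates(mk, ch2, 150)
  ena <- extra_nuclear_aggregates(mk, ch2, 150)
  # nuclear calls on label > 0; extra-nuclear on label 0
  nsc <- mk$nuclear_spot_calls
  if (nrow(nsc) > 0)
    expect_true(all(mk$labels[cbind(nsc$row, nsc$col)] > 0))
  if (nrow(ena$calls) > 0)
    expect_true(all(mk$labels[cbind(ena$calls$row, ena$calls$col)] == 0))
  # a punctum centred on a nuclear pixel is counted as nuclear, never as
  # extra-nuclear: no overlap between the two call sets
  k1 <- paste(nsc$row, nsc$col)
  k2 <- paste(ena$calls$row, ena$calls$col)
  expect_length(intersect(k1, k2), 0)
})

test_that("total aggregates follow the prominence rule at tolerance 1000", {
  ch2 <- matrix(500, 64, 64)
  expect_equal(total_aggregates(ch2, 10)$count, 0)
  add_peak <- function(m, r0, c0, amp) {
    for (r in 1:64) for (c in 1:64)
      m[r, c] <- m[r, c] + amp * exp(-((r - r0)^2 + (c - c0)^2) / 8)
    m
  }
  ch2 <- add_peak(ch2, 20, 20, 1500)   # prominence ~1500: counted
  ch2 <- add_peak(ch2, 45, 45, 500)    # prominence ~500: not counted
  res <- total_aggregates(ch2, 10, 1000)
  expect_equal(res$count, 1)
  expect_equal(res$tot_aggs_per_cell, 0.1)
})

test_that("aggregate area uses the 969 cut inside ACNs over all-nuclei area", {
  t <- toy_mask(c(3000, 100, 100))
  ch2 <- t$ch2
  # paint 20 pixels of nucleus 1 above 969
  ch2[3:4, 3:12] <- 1200
  ch2[6, 6] <- 3000
  m <- classify_acn(t$mask, 2000)
  m$nuclei$i_max_ch2 <- c(3000, 100, 100)  # keep classification explicit
  m <- classify_acn(m, 2000)
  m <- aggregate_area(m, ch2, 969)
  expect_equal(m$nuclei$na_area, c(21, 0, 0))
  expect_equal(m$na_area_frac, 21 / 300)
  # acn-only denominator switch
  m2 <- aggregate_area(m, ch2, 969, denominator = "acn_only")
  expect_equal(m2$na_area_frac, 21 / 100)
  # no ACNs: zero area everywhere, frac 0
  t0 <- toy_mask(c(100, 100, 100))
  m0 <- aggregate_area(classify_acn(t0$mask, 2000), t0$ch2, 969)
  expect_equal(m0$na_area_frac, 0)
})

test_that("mean background and median i-max follow their definitions", {
  expect_equal(mean_background(matrix(500, 10, 10))$mean, 500)
  half <- matrix(c(1000, 3000), 10, 10)
  expect_equal(mean_background(half, 2000)$mean, 1000)
  expect_equal(median_imax(c(1, 2, 3)), 2)
  expect_true(is.na(median_imax(numeric(0))))
})

test_that("perinuclear rings and marker positivity behave", {
  sp <- synth_image_spec(field_shape = c(128, 128), n_nuclei = 5,
                         nucleus_radius_range = c(6, 9),
                         touching_pair_fraction = 0, ena_density = 0,
                         seed = 6)
  e <- make_field(sp)
  mk <- segment_nuclei(e$field, 144)
  mk <- classify_acn(mk, 2000)
  # uniform marker channel: all ring means equal the constant
  uni <- matrix(700, 128, 128)
  mku <- perinuclear_intensity(mk, uni, 3)
  expect_true(all(abs(mku$nuclei$ring_mean - 700) < 1e-9))
  expect_equal(marker_positive_fraction(mku, uni, marker_threshold = 0), 100)
  expect_equal(marker_positive_fraction(mku, uni, marker_threshold = 70000), 0)
  # marker suppressed around ACN-like nuclei shows up in the ring ratio
  mk$nuclei$is_acn <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  supp <- matrix(1000, 128, 128)
  for (i in 1:2) {
    r0 <- mk$nuclei$centroid_row[i]; c0 <- mk$nuclei$centroid_col[i]
    rr <- pmax(1, round(r0) - 15):pmin(128, round(r0) + 15)
    cc <- pmax(1, round(c0) - 15):pmin(128, round(c0) + 15)
    supp[rr, cc] <- 500
  }
  mks <- perinuclear_intensity(mk, supp, 3)
  expect_lt(abs(mks$ring_acn_ratio - 0.5), 0.05)
})

test_that("well pooling sums counts and keeps the metric identities", {
  sp <- synth_image_spec(seed = 25)
  e1 <- make_field(sp, field_id = 1L)
  sp2 <- sp; sp2$seed <- 26L; class(sp2) <- "synth_image_spec"
  e2 <- make_field(sp2, field_id = 2L)
  quants <- lapply(list(e1, e2), function(e)
    quantify_field(e$field, segment_nuclei(e$field, 144)))
  wm <- well_metrics(quants)
  expect_named(wm, c("well_id", "line_label", "day", "tot_cells",
                     "median_imax", "pct_acn", "nas_per_acn",
                     "mean_background", "enas_per_cell",
                     "tot_aggs_per_cell", "nas_per_cell", "na_area_frac"))
  tot <- sum(vapply(quants, `[[`, 0, "tot_cells"))
  expect_equal(wm$tot_cells, tot)
  # identity: nas_per_cell = nas_per_acn x (#ACN) / tot_cells
  nacn <- sum(vapply(quants, `[[`, 0, "n_acn"))
  expect_equal(wm$nas_per_cell, wm$nas_per_acn * nacn / tot)
  # pooled median over all nuclei, not median of medians
  expect_equal(wm$median_imax,
               median(unlist(lapply(quants, `[[`, "i_max"))))
  expect_true(wm$pct_acn >= 0 && wm$pct_acn <= 100)
  expect_lt(wm$mean_background, 2000)
  expect_true(wm$na_area_frac >= 0 && wm$na_area_frac <= 1)
})
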