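test_that("make_field is deterministic and honors empty cases", {
  sp <- synth_image_spec(field_shape = c(160, 160), n_nuclei = 8,
                         nucleus_radius_range = c(6, 9),
                         ena_density = 2, seed = 5)
  a <- make_field(sp)
  b <- make_field(sp)
  expect_identical(a$field$channels, b$field$channels)
  expect_identical(a$truth, b$truth)

  # no nuclei, no puncta: noise-only image, empty ground truth
  sp0 <- synth_image_spec(field_shape = c(64, 64), n_nuclei = 0,
                          ena_density = 0, seed = 2)
  e0 <- make_field(sp0)
  expect_equal(nrow(e0$truth$nuclei), 0)
  expect_equal(nrow(e0$truth$nuclear_spots), 0)
  expect_equal(nrow(e0$truth$extra_nuclear_spots), 0)
  expect_lt(max(e0$field$channels[[1]]), 5 * sp0$noise_sd + 1)

  # acn_fraction 0: no planted nuclear spots; channel 2 stays near the
  # cytoplasm level except for planted extra-nuclear puncta
  spA <- synth_image_spec(field_shape = c(128, 128), n_nuclei = 6,
                          nucleus_radius_range = c(6, 9),
                          acn_fraction = 0, ena_density = 0, seed = 3)
  eA <- make_field(spA)
  expect_equal(nrow(eA$truth$nuclear_spots), 0)
  expect_lt(max(eA$field$channels[[2]]),
            spA$cytoplasm_level + 5 * spA$noise_sd + 1)
})

test_that("planted objects respect the stated geometry", {
  sp <- synth_image_spec(seed = 9)
  e <- make_field(sp)
  tr <- e$truth
  # every nuclear spot centre lies inside its parent nucleus footprint
  for (i in seq_len(nrow(tr$nuclear_spots))) {
    par <- tr$nuclei[tr$nuclei$id == tr$nuclear_spots$nucleus[i], ]
    d <- sqrt((tr$nuclear_spots$row[i] - par$row)^2 +
              (tr$nuclear_spots$col[i] - par$col)^2)
    expect_lte(d, par$radius)
  }
  # touching pairs at centre distance 1.2-1.6 x radius
  for (pid in unique(stats::na.omit(tr$nuclei$pair_id))) {
    mem <- tr$nuclei[which(tr$nuclei$pair_id == pid), ]
    d <- sqrt(diff(mem$row)^2 + diff(mem$col)^2)
    expect_gte(d / mem$radius[1], 1.2 - 1e-9)
    expect_lte(d / mem$radius[1], 1.6 + 1e-9)
  }
  # spots within one nucleus are >= 4 sigma apart
  for (id in unique(tr$nuclear_spots$nucleus)) {
    s <- tr$nuclear_spots[tr$nuclear_spots$nucleus == id, ]
    if (nrow(s) >= 2) {
      dd <- as.matrix(dist(s[, c("row", "col")]))
      expect_gte(min(dd[upper.tri(dd)]), 4 * sp$spot_sigma - 1e-9)
    }
  }
  # planted peaks are the pre-noise channel-2 amplitudes at spot centres
  expect_true(all(tr$nuclear_spots$peak >= sp$spot_peak_range[1] &
                  tr$nuclear_spots$peak <= sp$spot_peak_range[2]))
})

test_that("placement failure raises an explicit error", {
  sp <- synth_image_spec(field_shape = c(64, 64), n_nuclei = 60, seed = 1)
  expect_error(make_field(sp), "placement")
})

test_that("allelic series burden is monotone in severity and day", {
  tmpl <- synth_image_spec(field_shape = c(128, 128), n_nuclei = 5,
                           nucleus_radius_range = c(6, 9),
                           ena_density = 0, seed = 4)
  days <- c(0, 7, 14)
  res <- make_allelic_series(tmpl, c("ctrl", "mid", "high"), days,
                             severity = c(ctrl = 0, mid = 1, high = 2),
                             wells_per_line = 2)
  lay <- res$layout
  planted_frac <- vapply(res$plate, `[[`, 0, "planted_acn_fraction")
  spots_mean <- vapply(res$plate, `[[`, 0, "planted_spots_mean")
  # control line: zero planted inclusions at every day
  ctrl_idx <- lay$line_label == "ctrl"
  expect_true(all(planted_frac[ctrl_idx] == 0))
  expect_true(all(vapply(res$plate[ctrl_idx],
                         function(e) nrow(e$truth$nuclear_spots), 0L) == 0))
  # monotone in severity at fixed day, and in day at fixed line
  for (d in days) {
    f <- function(l) planted_frac[lay$line_label == l & lay$day == d][1]
    expect_true(f("ctrl") <= f("mid") && f("mid") <= f("high"))
  }
  for (l in c("mid", "high")) {
    fr <- vapply(days, function(d)
      planted_frac[lay$line_label == l & lay$day == d][1], 0)
    sm <- vapply(days, function(d)
      spots_mean[lay$line_label == l & lay$day == d][1], 0)
    expect_true(all(diff(fr) >= 0))
    expect_true(all(diff(sm) >= 0))
  }
  expect_error(make_allelic_series(tmpl, character(0), days), "non-empty")
})

test_that("make_ocr_trace reproduces plateau levels from the rate formulas", {
  # derived by inverting the parameter definitions: baseline = non-mito +
  # basal; post-oligomycin = baseline - ATP; post-FCCP = non-mito +
  # maximal; post-rot/AA = non-mito
  tp <- list(non_mito = 20, basal = 80, atp_production = 60,
             proton_leak = 20, maximal = 160)
  tr <- make_ocr_trace(tp, n_cycles_per_phase = 3, noise_sd = 0)
  m <- tr$measurements
  lev <- function(p) unique(m$ocr[m$phase == p])
  expect_equal(lev("baseline"), 100)
  expect_equal(lev("oligomycin"), 40)
  expect_equal(lev("fccp"), 180)
  expect_equal(lev("rot_aa"), 20)

  # all-zero parameters: flat zero trace
  z <- make_ocr_trace(list(non_mito = 0, basal = 0, atp_production = 0,
                           proton_leak = 0, maximal = 0), noise_sd = 0)
  expect_true(all(z$measurements$ocr == 0))

  # determinism
  t1 <- make_ocr_trace(tp, noise_sd = 5, seed = 12)
  t2 <- make_ocr_trace(tp, noise_sd = 5, seed = 12)
  expect_identical(t1$measurements, t2$measurements)

  # the identity basal = ATP + leak is enforced by name
  expect_error(make_ocr_trace(list(non_mito = 20, basal = 70,
                                   atp_production = 60, proton_leak = 20,
                                   maximal = 160)),
               "atp_production \\+ proton_leak")
})

test_that("make_absorbance_trace produces the stated kinetics", {
  lin <- make_absorbance_trace("linear", list(a0 = 1, slope = 0),
                               noise_sd = 0)
  expect_true(all(lin$absorbance == 1))
  fo <- make_absorbance_trace("first_order",
                              list(a0 = 0, a_inf = 1, k = 0.1),
                              times = seq(0, 20, 0.5), noise_sd = 0)
  # log-linear residual of the plateau-relative decay is ~0 by construction
  resid <- log(1 - fo$absorbance) + 0.1 * fo$time
  expect_lt(max(abs(resid)), 1e-9)
  expect_error(make_absorbance_trace("first_order", list(k = -1)),
               "positive")
  t1 <- make_absorbance_trace("linear", list(slope = 0.02), noise_sd = 0.01,
                              seed = 3)
  t2 <- make_absorbance_trace("linear", list(slope = 0.02), noise_sd = 0.01,
                              seed = 3)
  expect_identical(t1$absorbance, t2$absorbance)
})
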