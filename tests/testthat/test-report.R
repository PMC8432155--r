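test_that("compare_groups: Bonferroni plumbing behaves at the edges", {
  df <- data.frame(y = c(1, 1.1, 0.9, 1, 1.05, 0.95),
                   g = rep(c("a", "b"), each = 3))
  res <- compare_groups(df, "y", "g")
  # two groups: a single comparison, Bonferroni equals the unadjusted p
  expect_equal(res$pairwise$p_adjusted, res$pairwise$p_raw)
  # identical groups: adjusted p = 1
  df2 <- data.frame(y = rep(c(1, 2, 3), 3), g = rep(c("a", "b", "c"), each = 3))
  res2 <- compare_groups(df2, "y", "g")
  expect_true(all(res2$pairwise$p_adjusted == 1))
  expect_true(all(res2$pairwise$p_adjusted <= 1))
  # degenerate designs error out explicitly
  expect_error(compare_groups(data.frame(y = 1:3, g = rep("a", 3)),
                              "y", "g"), "degenerate")
  expect_error(compare_groups(data.frame(y = 1:3, g = c("a", "b", "b")),
                              "y", "g"), "degenerate")
})

test_that("compare_groups two-way design and null type-I control", {
  set.seed(77)
  df <- data.frame(y = rnorm(24), g = rep(c("a", "b"), 12),
                   d = rep(c("d1", "d2"), each = 12))
  res <- compare_groups(df, "y", "g", group2 = "d")
  expect_s3_class(res$anova[[1]], "data.frame")
  # simulated null: pairwise rejection rate stays at or below nominal
  # (Bonferroni is conservative); 300 reps keep the test fast -- the rate
  # estimate then has SE ~ 0.7% at the 5% level
  rej <- 0; total <- 0
  for (i in 1:300) {
    dfn <- data.frame(y = rnorm(15), g = rep(c("a", "b", "c"), each = 5))
    pw <- compare_groups(dfn, "y", "g")$pairwise
    rej <- rej + sum(pw$significant)
    total <- total + nrow(pw)
  }
  expect_lte(rej / total, 0.05 + 2 * sqrt(0.05 * 0.95 / total))
})

test_that("study_config validates and loads from YAML", {
  cfg <- study_config()
  expect_equal(cfg$nuclear_threshold, 144)
  expect_equal(cfg$acn_threshold, 2000)
  expect_equal(cfg$area_threshold, 969)
  expect_equal(cfg$na_tolerance, 150)
  expect_equal(cfg$tot_tolerance, 1000)
  expect_equal(cfg$volume_bounds, c(100, 1000))
  expect_error(study_config(control_label = "nope"), "control")
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("acn_threshold: 1800",
               "control_label: GFP",
               "template:",
               "  n_nuclei: 7",
               "  seed: 3"), yml)
  cfg2 <- read_study_config(yml)
  expect_equal(cfg2$acn_threshold, 1800)
  expect_equal(cfg2$template$n_nuclei, 7L)
  expect_equal(cfg2$template$spot_sigma, cfg$template$spot_sigma)
})

test_that("run_pipeline is reproducible byte for byte", {
  tmpl <- synth_image_spec(field_shape = c(128, 128), n_nuclei = 5,
                           nucleus_radius_range = c(6, 9), ena_density = 1)
  cfg1 <- study_config(lines = c("GFP", "CAG122"),
                       severity = c(GFP = 0, CAG122 = 2),
                       days = c(7, 14), wells_per_line = 2,
                       template = tmpl, seed = 11,
                       output_dir = tempfile("runA_"))
  cfg2 <- cfg1
  cfg2$output_dir <- tempfile("runB_")
  r1 <- run_pipeline(cfg1)
  r2 <- run_pipeline(cfg2)
  for (f in c("per_nucleus.csv", "per_well.csv", "per_line.csv")) {
    expect_identical(readLines(file.path(cfg1$output_dir, f)),
                     readLines(file.path(cfg2$output_dir, f)),
                     info = f)
  }
  expect_true(file.exists(file.path(cfg1$output_dir, "run_log.yaml")))
  # pct_acn structure: control zero, severe line higher at day 14
  pw <- r1$per_well
  expect_true(all(pw$pct_acn[pw$line_label == "GFP"] == 0))
  expect_gt(mean(pw$pct_acn[pw$line_label == "CAG122" & pw$day == 14]), 0)
  # empty plate errors before any computation
  expect_error(run_pipeline(study_config(wells_per_line = 0)), "empty")
})

test_that("field/ground-truth/OCR round trips through disk formats", {
  sp <- synth_image_spec(field_shape = c(96, 96), n_nuclei = 3,
                         nucleus_radius_range = c(6, 9), ena_density = 1,
                         seed = 19)
  e <- make_field(sp)
  tif <- tempfile(fileext = ".tif"); csv <- tempfile(fileext = ".csv")
  write_field(e, tif, csv)
  back <- read_field(tif)
  expect_identical(back$channels[[1]], e$field$channels[[1]])
  expect_identical(back$channels[[2]], e$field$channels[[2]])
  gt <- read.csv(csv)
  expect_equal(sum(gt$object_type == "nucleus"), nrow(e$truth$nuclei))
  traces <- list(make_ocr_trace(list(non_mito = 20, basal = 80,
                                     atp_production = 60, proton_leak = 20,
                                     maximal = 160),
                                noise_sd = 2, seed = 4, well_id = "A01"),
                 make_ocr_trace(list(non_mito = 10, basal = 40,
                                     atp_production = 30, proton_leak = 10,
                                     maximal = 90),
                                noise_sd = 2, seed = 5, well_id = "A02",
                                cell_density = 20000))
  ocsv <- tempfile(fileext = ".csv")
  write_ocr_csv(traces, ocsv)
  back_tr <- read_ocr_csv(ocsv)
  expect_equal(back_tr[["A02"]]$cell_density, 20000)
  expect_equal(back_tr[["A01"]]$measurements$ocr,
               traces[[1]]$measurements$ocr)
})
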