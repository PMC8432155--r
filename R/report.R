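#' Study configuration
#'
#' Collects every tunable constant of the analysis in one place: the
#' frozen imaging thresholds (nuclear threshold 144 DN or per-batch Otsu,
#' ACN threshold 2000, aggregate-area threshold 969, maxima tolerances 150
#' and 1000), segmentation settings, the mitochondrial volume bin bounds
#' (100, 1000 um^3), the control line label, and the simulation layout.
#' No analysis code path carries its own magic numbers.
#'
#' @param nuclear_threshold fixed DN (default 144, the frozen batch
#'   calibration) or the string `"batch-otsu"` to recalibrate on the
#'   current batch.
#' @param acn_threshold,area_threshold,na_tolerance,ena_tolerance,
#'   tot_tolerance,background_cutoff channel-2 constants, DN.
#' @param min_area,median_radius,marker_min_sep,ring_width segmentation
#'   settings, pixels.
#' @param volume_bounds mitochondrial size-bin edges, um^3.
#' @param control_label experimental control line.
#' @param lines,severity,days,wells_per_line simulated plate layout.
#' @param template a [synth_image_spec()] for simulation.
#' @param output_dir where [run_pipeline()] writes its tables.
#' @param seed master seed.
#' @return a `study_config` list.
#' @export
study_config <- function(nuclear_threshold = 144,
                         acn_threshold = 2000,
                         area_threshold = 969,
                         na_tolerance = 150,
                         ena_tolerance = 150,
                         tot_tolerance = 1000,
                         background_cutoff = 2000,
                         min_area = 50,
                         median_radius = 3,
                         marker_min_sep = 8,
                         ring_width = 3,
                         volume_bounds = c(100, 1000),
                         control_label = "GFP",
                         lines = c("GFP", "CAG71", "CAG122"),
                         severity = c(GFP = 0, CAG71 = 1, CAG122 = 2),
                         days = c(0, 7, 11, 14),
                         wells_per_line = 4L,
                         template = synth_image_spec(),
                         output_dir = tempfile("polyQscreen_run_"),
                         seed = 1L) {
  cfg <- list(nuclear_threshold = nuclear_threshold,
              acn_threshold = acn_threshold,
              area_threshold = area_threshold,
              na_tolerance = na_tolerance,
              ena_tolerance = ena_tolerance,
              tot_tolerance = tot_tolerance,
              background_cutoff = background_cutoff,
              min_area = min_area, median_radius = median_radius,
              marker_min_sep = marker_min_sep, ring_width = ring_width,
              volume_bounds = volume_bounds,
              control_label = control_label,
              lines = lines, severity = severity, days = days,
              wells_per_line = as.integer(wells_per_line),
              template = template, output_dir = output_dir,
              seed = as.integer(seed))
  stopifnot(cfg$acn_threshold > 0, cfg$area_threshold > 0,
            cfg$na_tolerance > 0, cfg$ena_tolerance > 0,
            cfg$tot_tolerance > 0, cfg$min_area > 0,
            cfg$control_label %in% cfg$lines)
  structure(cfg, class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Fields absent from the file keep their [study_config()] defaults;
#' `template` sub-fields override the default [synth_image_spec()].
#'
#' @param path YAML file.
#' @return a `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  tmpl_over <- raw$template
  raw$template <- NULL
  if (!is.null(raw$severity)) raw$severity <- unlist(raw$severity)
  cfg <- do.call(study_config, raw)
  if (!is.null(tmpl_over)) {
    tm <- unclass(cfg$template)
    for (n in names(tmpl_over)) tm[[n]] <- tmpl_over[[n]]
    cfg$template <- do.call(synth_image_spec, tm)
  }
  cfg
}

#' Group comparisons with Bonferroni correction
#'
#' Reporting plumbing: one- or two-way ANOVA followed by Bonferroni-
#' adjusted pairwise t tests between the levels of the primary factor,
#' significance flagged at adjusted p < 0.05.
#'
#' @param df data.frame.
#' @param value name of the response column.
#' @param group name of the primary factor column.
#' @param group2 optional second factor (two-way design).
#' @param design `"one_way"` or `"two_way"` (inferred from `group2` when
#'   omitted).
#' @return list with `anova` (the summary table), `pairwise` (data.frame:
#'   `group1`, `group2`, `p_adjusted`, `significant`).
#' @export
compare_groups <- function(df, value, group, group2 = NULL,
                           design = if (is.null(group2)) "one_way"
                                    else "two_way") {
  design <- match.arg(design, c("one_way", "two_way"))
  y <- df[[value]]
  g <- factor(df[[group]])
  if (nlevels(g) < 2) stop("degenerate design: need >= 2 groups")
  if (any(table(g) < 2))
    stop("degenerate design: need >= 2 replicates per group")
  fit <- if (design == "one_way") {
    aov(y ~ g)
  } else {
    g2 <- factor(df[[group2]])
    if (nlevels(g2) < 2) stop("degenerate design: second factor has 1 level")
    aov(y ~ g * g2)
  }
  combs <- utils::combn(levels(g), 2)
  praw <- apply(combs, 2, function(pr) {
    a <- y[g == pr[1]]; b <- y[g == pr[2]]
    if (sd(a) == 0 && sd(b) == 0) {
      if (mean(a) == mean(b)) 1 else 0
    } else {
      stats::t.test(a, b)$p.value
    }
  })
  padj <- p.adjust(praw, method = "bonferroni")
  list(anova = summary(fit),
       pairwise = data.frame(group1 = combs[1, ], group2 = combs[2, ],
                             p_raw = praw, p_adjusted = padj,
                             significant = padj < 0.05))
}

#' Run the imaging pipeline end to end
#'
#' Simulates (or loads) a plate, calibrates or applies the nuclear
#' threshold, segments every field, quantifies inclusion metrics, pools
#' per well and per line, runs the group comparison on the percentage of
#' aggregate-containing nuclei, and writes `per_nucleus.csv`,
#' `per_well.csv`, `per_line.csv` and `run_log.yaml` to
#' `config$output_dir`. Identical config (including seed) gives
#' byte-identical outputs.
#'
#' @param config a [study_config()].
#' @param plate optionally a pre-built plate (as from
#'   [make_allelic_series()]); when `NULL` one is simulated from the
#'   config.
#' @return list with `per_nucleus`, `per_well`, `per_line`, `comparison`,
#'   `threshold`, and `output_dir`, invisibly also written to disk.
#' @export
run_pipeline <- function(config, plate = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(plate)) {
    if (length(config$lines) == 0 || config$wells_per_line < 1)
      stop("input error: empty plate layout")
    tmpl <- config$template
    tmpl$seed <- config$seed
    class(tmpl) <- "synth_image_spec"
    plate <- make_allelic_series(tmpl, config$lines, config$days,
                                 severity = config$severity,
                                 wells_per_line = config$wells_per_line)
  }
  entries <- plate$plate
  if (length(entries) == 0) stop("input error: empty plate")
  threshold <- if (identical(config$nuclear_threshold, "batch-otsu")) {
    batch_otsu_threshold(lapply(entries, function(e) e$field),
                         config$median_radius)
  } else {
    config$nuclear_threshold
  }
  quants <- lapply(entries, function(e) {
    mask <- segment_nuclei(e$field, threshold,
                           min_area = config$min_area,
                           median_radius = config$median_radius,
                           marker_min_sep = config$marker_min_sep)
    quantify_field(e$field, mask,
                   acn_threshold = config$acn_threshold,
                   na_tolerance = config$na_tolerance,
                   ena_tolerance = config$ena_tolerance,
                   tot_tolerance = config$tot_tolerance,
                   area_threshold = config$area_threshold,
                   background_cutoff = config$background_cutoff)
  })
  per_nucleus <- do.call(rbind, lapply(quants, function(q) {
    if (nrow(q$mask$nuclei) == 0) return(NULL)
    cbind(data.frame(well_id = q$well_id, field_id = q$field_id,
                     line_label = q$line_label, day = q$day),
          q$mask$nuclei)
  }))
  by_well <- split(quants, vapply(quants, `[[`, "", "well_id"))
  per_well <- do.call(rbind, lapply(by_well, well_metrics))
  per_well <- per_well[order(per_well$well_id), , drop = FALSE]
  rownames(per_well) <- NULL
  per_line <- do.call(rbind, lapply(
    split(per_well, list(per_well$line_label, per_well$day), drop = TRUE),
    function(d) {
      row <- data.frame(line_label = d$line_label[1], day = d$day[1],
                        n_wells = nrow(d))
      for (v in c("tot_cells", "median_imax", "pct_acn", "nas_per_acn",
                  "mean_background", "enas_per_cell", "tot_aggs_per_cell",
                  "nas_per_cell", "na_area_frac")) {
        row[[paste0(v, "_mean")]] <- mean(d[[v]], na.rm = TRUE)
        row[[paste0(v, "_sem")]] <- sd(d[[v]], na.rm = TRUE) /
          sqrt(sum(!is.na(d[[v]])))
      }
      row
    }))
  per_line <- per_line[order(per_line$line_label, per_line$day), ,
                       drop = FALSE]
  rownames(per_line) <- NULL
  comparison <- tryCatch(
    compare_groups(per_well, "pct_acn", "line_label"),
    error = function(e) NULL)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(d, f) write.csv(d, file.path(config$output_dir, f),
                                 row.names = FALSE)
  wr(per_nucleus, "per_nucleus.csv")
  wr(per_well, "per_well.csv")
  wr(per_line, "per_line.csv")
  log <- list(package = "polyQscreen",
              version = as.character(utils::packageVersion("polyQscreen")),
              threshold_used = threshold,
              n_fields = length(entries),
              config = config_as_list(config))
  yaml::write_yaml(log, file.path(config$output_dir, "run_log.yaml"))
  invisible(list(per_nucleus = per_nucleus, per_well = per_well,
                 per_line = per_line, comparison = comparison,
                 threshold = threshold, output_dir = config$output_dir))
}

config_as_list <- function(cfg) {
  out <- unclass(cfg)
  out$template <- unclass(out$template)
  out$severity <- as.list(out$severity)
  out
}
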