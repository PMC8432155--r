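#' Construct an OCR trace
#'
#' An injection-annotated oxygen-consumption-rate time series for one well
#' of an extracellular-flux (Mito Stress Test) assay. Phases must appear in
#' the order baseline, oligomycin, fccp, rot_aa, each with at least one
#' measurement cycle.
#'
#' @param measurements data.frame with columns `phase` (one of `baseline`,
#'   `oligomycin`, `fccp`, `rot_aa`), `cycle`, `time` (min), `ocr`
#'   (pmol O2/min).
#' @param well_id,line_label identifiers.
#' @param cell_density cells per well (> 0), used for density
#'   normalization.
#' @return an `ocr_trace` object.
#' @export
ocr_trace <- function(measurements, well_id, line_label,
                      cell_density) {
  phases <- c("baseline", "oligomycin", "fccp", "rot_aa")
  stopifnot(all(c("phase", "cycle", "time", "ocr") %in% names(measurements)),
            all(measurements$phase %in% phases),
            all(is.finite(measurements$ocr)),
            cell_density > 0)
  present <- unique(measurements$phase)
  if (!identical(present, phases[phases %in% present]) ||
      is.unsorted(match(measurements$phase, phases)))
    stop("phases must appear in the order baseline, oligomycin, fccp, rot_aa")
  missing_ph <- setdiff(phases, present)
  if (length(missing_ph) > 0)
    stop("missing phase(s): ", paste(missing_ph, collapse = ", "))
  structure(list(measurements = measurements, well_id = well_id,
                 line_label = line_label, cell_density = cell_density),
            class = "ocr_trace")
}

#' @export
print.ocr_trace <- function(x, ...) {
  cat(sprintf("<ocr_trace> well %s (%s), %d measurements, density %g\n",
              x$well_id, x$line_label, nrow(x$measurements),
              x$cell_density))
  invisible(x)
}

#' Normalize OCR traces by cell density
#'
#' Each well's density is expressed relative to the lowest density in the
#' batch (`factor = density / min(density)`), and every OCR measurement of
#' that well is divided by its factor. The minimum-density well is
#' unchanged. Within-well rate ratios (hence coupling efficiency) are
#' invariant under this operation.
#'
#' @param traces list of `ocr_trace` objects.
#' @return list of normalized `ocr_trace` objects (with
#'   `density_factor` recorded on each).
#' @export
density_normalize <- function(traces) {
  stopifnot(length(traces) >= 1)
  dens <- vapply(traces, function(t) t$cell_density, 0)
  if (any(dens <= 0)) stop("cell densities must be > 0")
  dmin <- min(dens)
  lapply(traces, function(t) {
    f <- t$cell_density / dmin
    t$measurements$ocr <- t$measurements$ocr / f
    t$density_factor <- f
    t
  })
}

#' Derive Mito Stress Test respiratory parameters
#'
#' Computes, phase-scoped and verbatim from the defining formulas:
#' non-mitochondrial respiration = minimum rate after rotenone/antimycin A;
#' basal respiration = last rate before the first injection minus
#' non-mitochondrial; maximal respiration = maximum rate after FCCP minus
#' non-mitochondrial; proton leak = minimum rate after oligomycin minus
#' non-mitochondrial; ATP production = last rate before oligomycin minus
#' minimum rate after oligomycin; coupling efficiency = ATP production /
#' basal x 100. The identity `basal = atp_production + proton_leak` is an
#' algebraic consequence and holds for every input. Negative derived rates
#' (possible with noise) are reported as computed and flagged, never
#' clipped. Ties in min/max go to the earliest cycle.
#'
#' @param trace an `ocr_trace`.
#' @return a `resp_profile`: list with `non_mito`, `basal`, `maximal`,
#'   `proton_leak`, `atp_production` (pmol O2/min), `coupling_efficiency`
#'   (%, missing when basal is 0), `negative_rates` (character vector of
#'   flagged parameters), and the trace metadata.
#' @export
derive_parameters <- function(trace) {
  stopifnot(inherits(trace, "ocr_trace"))
  m <- trace$measurements
  ph <- function(p) m$ocr[m$phase == p]
  base <- ph("baseline"); olig <- ph("oligomycin")
  fccp <- ph("fccp"); rot <- ph("rot_aa")
  non_mito <- min(rot)
  last_base <- base[length(base)]
  basal <- last_base - non_mito
  maximal <- max(fccp) - non_mito
  leak <- min(olig) - non_mito
  atp <- last_base - min(olig)
  coupling <- if (basal == 0) metric_missing() else 100 * atp / basal
  rates <- c(non_mito = non_mito, basal = basal, maximal = maximal,
             proton_leak = leak, atp_production = atp)
  structure(list(well_id = trace$well_id, line_label = trace$line_label,
                 non_mito = non_mito, basal = basal, maximal = maximal,
                 proton_leak = leak, atp_production = atp,
                 coupling_efficiency = coupling,
                 negative_rates = names(rates)[rates < 0]),
            class = "resp_profile")
}

#' @export
print.resp_profile <- function(x, ...) {
  cat(sprintf(
    paste0("<resp_profile> %s (%s): basal %.2f, ATP %.2f, leak %.2f, ",
           "maximal %.2f, non-mito %.2f, coupling %.1f%%\n"),
    x$well_id, x$line_label, x$basal, x$atp_production, x$proton_leak,
    x$maximal, x$non_mito, x$coupling_efficiency))
  if (length(x$negative_rates) > 0)
    cat("  flagged negative:", paste(x$negative_rates, collapse = ", "), "\n")
  invisible(x)
}

#' Express respiratory parameters as percentage of a control line
#'
#' Each rate is divided by the control-line mean of that rate and scaled to
#' percent, so the control line's mean of itself is exactly 100. Rates
#' whose control mean is 0 are reported missing.
#'
#' @param profiles list of `resp_profile` objects.
#' @param control_label line label of the experimental control.
#' @return data.frame: one row per well with raw rates and
#'   `<rate>_pct_control` columns.
#' @export
normalize_to_control <- function(profiles, control_label) {
  stopifnot(length(profiles) >= 1)
  rates <- c("non_mito", "basal", "maximal", "proton_leak",
             "atp_production", "coupling_efficiency")
  df <- do.call(rbind, lapply(profiles, function(p)
    data.frame(well_id = p$well_id, line_label = p$line_label,
               t(vapply(rates, function(r) p[[r]], 0)))))
  ctrl <- df[df$line_label == control_label, , drop = FALSE]
  if (nrow(ctrl) == 0)
    stop("no profile carries the control label '", control_label, "'")
  for (r in rates) {
    cm <- mean(ctrl[[r]], na.rm = TRUE)
    df[[paste0(r, "_pct_control")]] <-
      if (!is.finite(cm) || cm == 0) metric_missing() else 100 * df[[r]] / cm
  }
  df
}

#' Per-line summary of respiratory parameters
#'
#' @param df output of [normalize_to_control()].
#' @return data.frame of per-line mean and SEM (across wells) for each raw
#'   and control-normalized rate.
#' @export
summarize_respiration <- function(df) {
  num <- names(df)[vapply(df, is.numeric, TRUE)]
  out <- do.call(rbind, lapply(split(df, df$line_label), function(d) {
    row <- data.frame(line_label = d$line_label[1], n_wells = nrow(d))
    for (v in num) {
      row[[paste0(v, "_mean")]] <- mean(d[[v]], na.rm = TRUE)
      row[[paste0(v, "_sem")]] <- sd(d[[v]], na.rm = TRUE) /
        sqrt(sum(!is.na(d[[v]])))
    }
    row
  }))
  rownames(out) <- NULL
  out
}
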