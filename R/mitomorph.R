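#' Volume-weighted mitochondrial size-category fractions
#'
#' Classifies per-organelle mitochondrial volumes as small, medium, or
#' large and reports the summed volume within each category as a
#' percentage of total mitochondrial volume (volume-weighted, not
#' count-weighted). With the default bounds (100, 1000) in um^3 the bins
#' are: small `< 100`, medium `[100, 1000]` (closed on both ends), large
#' `> 1000`. The three percentages sum to 100.
#'
#' @param volumes numeric vector of per-organelle volumes, um^3 (> 0).
#' @param bounds length-2 numeric: (small/medium, medium/large) edges.
#' @return named numeric `c(pct_small, pct_medium, pct_large)`, or all-`NA`
#'   for an empty set (missing, not 0).
#' @export
volume_fractions <- function(volumes, bounds = c(100, 1000)) {
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  if (length(volumes) == 0)
    return(c(pct_small = NA_real_, pct_medium = NA_real_,
             pct_large = NA_real_))
  stopifnot(all(volumes > 0))
  tot <- sum(volumes)
  small <- sum(volumes[volumes < bounds[1]])
  large <- sum(volumes[volumes > bounds[2]])
  medium <- tot - small - large
  100 * c(pct_small = small, pct_medium = medium, pct_large = large) / tot
}

#' Express per-line values as percentage of a control line
#'
#' @param values numeric vector (e.g. TMRM mean intensity per volume, one
#'   entry per replicate).
#' @param line_labels line label per entry.
#' @param control_label which line is the control.
#' @return data.frame with per-entry `pct_of_control` (100 x value /
#'   control-line mean); the control line's mean of itself is 100.
#' @export
pct_of_control <- function(values, line_labels, control_label) {
  stopifnot(length(values) == length(line_labels))
  ctrl <- values[line_labels == control_label]
  if (length(ctrl) == 0)
    stop("no entry carries the control label '", control_label, "'")
  cm <- mean(ctrl, na.rm = TRUE)
  if (!is.finite(cm) || cm == 0)
    stop("control-line mean is zero or undefined")
  data.frame(line_label = line_labels, value = values,
             pct_of_control = 100 * values / cm)
}

#' Summarize a table of mitochondrial volumes
#'
#' @param df data.frame with columns `line_label`, `replicate`,
#'   `volume_um3`.
#' @param bounds passed to [volume_fractions()].
#' @return per-(line, replicate) size-category percentages plus per-line
#'   mean and SEM of each category.
#' @export
mito_volume_summary <- function(df, bounds = c(100, 1000)) {
  stopifnot(all(c("line_label", "replicate", "volume_um3") %in% names(df)))
  per_rep <- do.call(rbind, lapply(
    split(df, list(df$line_label, df$replicate), drop = TRUE),
    function(d) {
      fr <- volume_fractions(d$volume_um3, bounds)
      data.frame(line_label = d$line_label[1], replicate = d$replicate[1],
                 t(fr))
    }))
  rownames(per_rep) <- NULL
  per_line <- do.call(rbind, lapply(split(per_rep, per_rep$line_label),
    function(d) {
      row <- data.frame(line_label = d$line_label[1], n_reps = nrow(d))
      for (v in c("pct_small", "pct_medium", "pct_large")) {
        row[[paste0(v, "_mean")]] <- mean(d[[v]])
        row[[paste0(v, "_sem")]] <- sd(d[[v]]) / sqrt(nrow(d))
      }
      row
    }))
  rownames(per_line) <- NULL
  list(per_replicate = per_rep, per_line = per_line)
}
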