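#' Least-squares slope of an absorbance segment
#'
#' @param time minutes.
#' @param absorbance AU.
#' @return slope in AU/min (signed; the assay direction decides the
#'   expected sign).
#' @export
linear_rate <- function(time, absorbance) {
  stopifnot(length(time) == length(absorbance), length(time) >= 2)
  unname(coef(lm(absorbance ~ time))[2])
}

#' Beer-Lambert specific activity
#'
#' Converts an absorbance rate to a specific activity. With slope in
#' AU/min, molar extinction coefficient in 1/M/cm, path length in cm and
#' protein concentration in mg/mL:
#' `|slope| / (epsilon * path)` is the reaction rate in M/min;
#' `x 1e9` gives nmol/L/min; dividing by `protein * 1000` (mg/L) yields
#' nmol/min/mg. Equivalently `activity = 1e6 * |slope| / (epsilon * path *
#' protein_mg_per_ml)`.
#'
#' @param slope AU/min.
#' @param extinction_coeff molar extinction coefficient, 1/M/cm.
#' @param path_length cm.
#' @param protein_mg_per_ml protein concentration in the reaction, mg/mL.
#' @return specific activity, nmol/min/mg protein.
#' @export
beer_lambert_activity <- function(slope, extinction_coeff, path_length = 1,
                                  protein_mg_per_ml) {
  stopifnot(extinction_coeff > 0, path_length > 0, protein_mg_per_ml > 0)
  abs(slope) / (extinction_coeff * path_length) * 1e9 /
    (protein_mg_per_ml * 1000)
}

#' Inhibitor-sensitive rate
#'
#' Difference of the fitted linear rates before and after inhibitor
#' addition (e.g. the TTFA-sensitive DCPIP reduction, or the antimycin
#' A-sensitive cytochrome c reduction). A negative sensitivity (post faster
#' than pre) is flagged, not clipped.
#'
#' @param pre,post data.frames with `time` and `absorbance` for the two
#'   segments.
#' @return list with `rate` = `rate_pre - rate_post` (AU/min, signed),
#'   `sensitive_magnitude` = `|rate_pre| - |rate_post|`, and `flagged`
#'   (TRUE when the post-inhibitor rate is the faster one).
#' @export
inhibitor_sensitive_rate <- function(pre, post) {
  r_pre <- linear_rate(pre$time, pre$absorbance)
  r_post <- linear_rate(post$time, post$absorbance)
  list(rate = r_pre - r_post,
       sensitive_magnitude = abs(r_pre) - abs(r_post),
       flagged = abs(r_pre) < abs(r_post))
}

#' Pseudo first-order rate constant
#'
#' For assays whose progress curve approaches a plateau (cytochrome c
#' reduction by complex III), the non-enzymatic linear rate -- fitted on a
#' dedicated segment recorded before homogenate addition -- is subtracted,
#' and `A(t) = a_inf - (a_inf - a0) * exp(-k t)` is fitted to the corrected
#' enzymatic segment with `a_inf`, `a0` and `k` free (joint fit rather than
#' taking the last point as the plateau, for robustness to truncated
#' traces). The rate constant is expressed per mg protein.
#'
#' @param enzymatic data.frame `time`, `absorbance` of the enzymatic
#'   segment (time may restart at 0).
#' @param non_enzymatic optional data.frame of the pre-homogenate segment;
#'   its fitted linear slope is removed from the enzymatic segment.
#' @param protein_mg protein mass in the reaction, mg.
#' @return list with `k` (/min/mg), `k_raw` (/min), `background_slope`
#'   (AU/min) and `flagged` (TRUE when the corrected trace shows no
#'   resolvable exponential rise).
#' @export
first_order_k <- function(enzymatic, non_enzymatic = NULL, protein_mg = 1) {
  stopifnot(protein_mg > 0, nrow(enzymatic) >= 4)
  bg <- if (is.null(non_enzymatic)) 0 else
    linear_rate(non_enzymatic$time, non_enzymatic$absorbance)
  t <- enzymatic$time - enzymatic$time[1]
  a <- enzymatic$absorbance - bg * t
  span <- diff(range(a))
  if (span <= .Machine$double.eps^0.5 * max(1, abs(mean(a))))
    return(list(k = 0, k_raw = 0, background_slope = bg, flagged = TRUE))
  fit <- tryCatch(
    nls(a ~ ainf - (ainf - a0) * exp(-k * t),
        start = list(ainf = max(a) + 0.05 * span, a0 = a[1],
                     k = 1 / max(t[t > 0])),
        control = nls.control(maxiter = 500, tol = 1e-10,
                              minFactor = 1e-12, scaleOffset = 1)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(k = NA_real_, k_raw = NA_real_, background_slope = bg,
                flagged = TRUE))
  k_raw <- unname(coef(fit)["k"])
  list(k = k_raw / protein_mg, k_raw = k_raw, background_slope = bg,
       flagged = k_raw <= 0)
}

#' Normalize activities to citrate synthase
#'
#' Divides each complex activity by the citrate-synthase activity of the
#' same sample (and CoQ10 level by CS when given), removing a common
#' mitochondrial-content factor: scaling every activity and CS by the same
#' constant leaves all ratios unchanged.
#'
#' @param activities named numeric vector (or list) of activities.
#' @param cs_activity citrate synthase activity (same units).
#' @param coq10_level optional CoQ10 level, pmol/mg protein.
#' @return data.frame with `assay`, `activity`, `cs_ratio` (NA with an
#'   error record when CS is not positive), plus a `coq10_cs_ratio` row
#'   when CoQ10 is supplied.
#' @export
cs_normalize <- function(activities, cs_activity, coq10_level = NULL) {
  a <- unlist(activities)
  bad_cs <- !is.finite(cs_activity) || cs_activity <= 0
  out <- data.frame(assay = names(a), activity = unname(a),
                    cs_ratio = if (bad_cs) NA_real_ else unname(a) / cs_activity)
  if (!is.null(coq10_level)) {
    out <- rbind(out, data.frame(
      assay = "coq10", activity = coq10_level,
      cs_ratio = if (bad_cs) NA_real_ else coq10_level / cs_activity))
  }
  attr(out, "error") <- if (bad_cs)
    "citrate synthase activity not positive; ratios undefined" else NULL
  out
}
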