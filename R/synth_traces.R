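#' Simulate a Mito Stress Test OCR trace
#'
#' Builds a four-phase oxygen-consumption-rate trace (baseline, after
#' oligomycin, after FCCP, after rotenone/antimycin A) whose noiseless
#' plateau levels follow from the true respiratory parameters:
#' \deqn{baseline = non\_mito + basal}
#' \deqn{oligomycin = non\_mito + proton\_leak}
#' \deqn{fccp = non\_mito + maximal}
#' \deqn{rot\_aa = non\_mito}
#' The identity `basal = atp_production + proton_leak` must hold by
#' construction and is enforced.
#'
#' @param true_params list/vector with `non_mito`, `basal`, `atp_production`,
#'   `proton_leak`, `maximal` (pmol O2/min; all >= 0).
#' @param n_cycles_per_phase measurement cycles per phase.
#' @param noise_sd i.i.d. Gaussian noise SD added to every measurement.
#' @param seed integer seed.
#' @param well_id,line_label,cell_density metadata (density: cells/well).
#' @return an `ocr_trace` (see [ocr_trace()]).
#' @export
make_ocr_trace <- function(true_params, n_cycles_per_phase = 3L,
                           noise_sd = 0, seed = 1L, well_id = "A01",
                           line_label = "30CAG", cell_density = 30000) {
  p <- as.list(true_params)
  need <- c("non_mito", "basal", "atp_production", "proton_leak", "maximal")
  if (!all(need %in% names(p)))
    stop("true_params must name: ", paste(need, collapse = ", "))
  if (any(unlist(p[need]) < 0)) stop("all true rates must be >= 0")
  if (abs(p$basal - (p$atp_production + p$proton_leak)) > 1e-9)
    stop("inconsistent parameters: basal must equal ",
         "atp_production + proton_leak")
  levels <- c(baseline = p$non_mito + p$basal,
              oligomycin = p$non_mito + p$proton_leak,
              fccp = p$non_mito + p$maximal,
              rot_aa = p$non_mito)
  with_seed(seed, function() {
    phases <- rep(names(levels), each = n_cycles_per_phase)
    ocr <- rep(unname(levels), each = n_cycles_per_phase) +
      rnorm(length(phases), 0, noise_sd)
    ocr_trace(data.frame(phase = phases,
                         cycle = seq_along(phases),
                         time = seq_along(phases) * 6.5,
                         ocr = ocr),
              well_id = well_id, line_label = line_label,
              cell_density = cell_density)
  })
}

#' Simulate an absorbance kinetic trace
#'
#' Two kinds of enzyme-assay time course are emulated: `"linear"` (constant
#' rate, e.g. DCPIP reduction followed at 600 nm) and `"first_order"`
#' (exponential approach to a plateau, e.g. cytochrome c reduction whose
#' activity is expressed as a pseudo first-order rate constant k), with an
#' optional additive linear non-enzymatic component.
#'
#' @param kind `"linear"` or `"first_order"`.
#' @param params for `"linear"`: `a0` (starting AU), `slope` (AU/min; sign
#'   carries the assay direction). For `"first_order"`: `a0`, `a_inf`
#'   (plateau AU), `k` (/min, > 0), optional `background_slope` (AU/min).
#' @param times minutes at which absorbance is sampled.
#' @param noise_sd AU noise SD.
#' @param seed integer seed.
#' @return data.frame with `time` (min) and `absorbance` (AU), plus the
#'   noiseless generating parameters as attribute `"params"`.
#' @export
make_absorbance_trace <- function(kind = c("linear", "first_order"), params,
                                  times = seq(0, 5, by = 0.1), noise_sd = 0,
                                  seed = 1L) {
  kind <- match.arg(kind)
  p <- as.list(params)
  a <- switch(kind,
    linear = {
      if (is.null(p$slope)) stop("linear kind needs `slope`")
      a0 <- if (is.null(p$a0)) 1 else p$a0
      a0 + p$slope * times
    },
    first_order = {
      if (is.null(p$k) || p$k <= 0)
        stop("first_order kind needs a strictly positive rate constant `k`")
      a0 <- if (is.null(p$a0)) 0 else p$a0
      a_inf <- if (is.null(p$a_inf)) a0 + 1 else p$a_inf
      bg <- if (is.null(p$background_slope)) 0 else p$background_slope
      a_inf - (a_inf - a0) * exp(-p$k * times) + bg * times
    })
  with_seed(seed, function() {
    structure(data.frame(time = times,
                         absorbance = a + rnorm(length(times), 0, noise_sd)),
              params = c(list(kind = kind), p))
  })
}
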