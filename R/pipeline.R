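## End-to-end convenience pipeline ---------------------------------------------

#' Run the full trace-to-events pipeline
#'
#' Chains the analysis steps on a raw trace set: photobleach-step detection,
#' ALEX frame pairing, spectral corrections, FRET computation (with bleach
#' validity flags), and event extraction.
#'
#' @param traces a \linkS4class{TraceSet}.
#' @param params a \linkS4class{CorrectionParams}; if \code{NULL}, parameters
#'   are estimated from the detected bleach segments via
#'   \code{\link{estimateCorrections}}.
#' @param detection a \linkS4class{DetectionParams}.
#' @param denominator_floor passed to \code{\link{computeFret}}.
#' @return A list with elements \code{bleach} (data.frame), \code{fret}
#'   (\linkS4class{FretTraceSet}), \code{events} (\linkS4class{EventTable})
#'   and \code{params} (the \linkS4class{CorrectionParams} used).
#' @examples
#' sim <- simulateDataset(kineticConfig(n_molecules = 3, duration = 60,
#'                                      seed = 11))
#' res <- analyzeTraces(sim$traces, correctionParams(
#'     d_cy5_532 = 0.05, d_a750_638 = 0.05, b_cy3_cy5 = 0.1,
#'     b_cy5_a750 = 0.1, s_cy3 = 1 / 1.3, s_a750 = 1 / 0.8))
#' res$events
#' @export
analyzeTraces <- function(traces, params = NULL,
                          detection = detectionParams(),
                          denominator_floor = 3 * 5 * sqrt(3)) {
    stopifnot(is(traces, "TraceSet"))
    bleach <- detectBleachSteps(traces)
    if (is.null(params))
        params <- estimateCorrections(traces, bleach)
    aligned <- pairAlexFrames(traces)
    corrected <- applyCorrections(aligned, params)
    fret <- computeFret(corrected, bleach = bleach,
                        denominator_floor = denominator_floor)
    events <- extractEvents(fret, detection, bleach = bleach)
    list(bleach = bleach, fret = fret, events = events, params = params)
}

#' Correction parameters matching a PhotoConfig
#'
#' The exact inverse of the rendering model of \code{\link{renderTraces}}:
#' same fractions, scale factors the reciprocals of the detection g factors.
#' Useful for round-trip validation of synthetic data.
#'
#' @param photo a \linkS4class{PhotoConfig}.
#' @return A \linkS4class{CorrectionParams}.
#' @export
correctionParamsFromPhoto <- function(photo) {
    stopifnot(is(photo, "PhotoConfig"))
    correctionParams(d_cy5_532 = photo@d_cy5_532,
                     d_a750_638 = photo@d_a750_638,
                     b_cy3_cy5 = photo@b_cy3_cy5,
                     b_cy5_a750 = photo@b_cy5_a750,
                     s_cy3 = 1 / photo@g_cy3, s_a750 = 1 / photo@g_a750)
}
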