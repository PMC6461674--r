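#' @import methods
NULL

## Channel / column conventions used throughout the package --------------------
##
## Trace tables are column-oriented TSV with one row per molecule-frame and
## columns (exact order): molecule_id, frame, time_s, excitation, I_cy3,
## I_cy5, I_a750, with excitation coded as 532 or 638.  Frames are 0-based,
## times in seconds, intervals half-open [start, end).

.TRACE_COLUMNS <- c("molecule_id", "frame", "time_s", "excitation",
                    "I_cy3", "I_cy5", "I_a750")

.EVENT_FLAGS <- c("complete", "entry_only", "censored_by_bleach",
                  "no_event", "multi_step_bleach")

#' Experiment manifest
#'
#' Acquisition metadata shared by all molecules of a data set: the camera frame
#' interval, the alternation period of the two excitation lasers (in frames per
#' excitation block), the ATP concentration, the remodeller used, and (for
#' synthetic data sets) the RNG seed the traces were generated with.
#'
#' @slot frame_interval numeric(1), seconds per camera frame (> 0).
#' @slot alternation_period integer(1), frames per excitation block (>= 1).
#' @slot atp_uM numeric(1), ATP concentration in micromolar.
#' @slot remodeller character(1), free-text remodeller description.
#' @slot seed integer(1) or NA, RNG seed recorded for synthetic sets.
#'
#' @name Manifest-class
#' @rdname Manifest
#' @exportClass Manifest
setClass("Manifest",
         representation(frame_interval = "numeric",
                        alternation_period = "integer",
                        atp_uM = "numeric",
                        remodeller = "character",
                        seed = "integer"),
         prototype(frame_interval = 0.1,
                   alternation_period = 1L,
                   atp_uM = 500,
                   remodeller = "Chd1",
                   seed = NA_integer_))

setValidity("Manifest", function(object) {
    msg <- character()
    if (length(object@frame_interval) != 1L || !is.finite(object@frame_interval) ||
        object@frame_interval <= 0)
        msg <- c(msg, "frame_interval must be a single positive number")
    if (length(object@alternation_period) != 1L || is.na(object@alternation_period) ||
        object@alternation_period < 1L)
        msg <- c(msg, "alternation_period must be >= 1")
    if (length(object@atp_uM) != 1L || is.na(object@atp_uM) || object@atp_uM < 0)
        msg <- c(msg, "atp_uM must be a single non-negative number")
    if (length(msg)) msg else TRUE
})

#' Construct a Manifest
#'
#' @param frame_interval seconds per camera frame; the default 0.1 s gives a
#'   0.2 s ALEX cycle with strict 532/638 alternation.
#' @param alternation_period frames per excitation block.
#' @param atp_uM ATP concentration (micromolar).
#' @param remodeller free-text remodeller label.
#' @param seed optional integer RNG seed recorded for synthetic data.
#' @return A \linkS4class{Manifest}.
#' @examples
#' manifest(atp_uM = 100)
#' @export
manifest <- function(frame_interval = 0.1, alternation_period = 1L,
                     atp_uM = 500, remodeller = "Chd1", seed = NA) {
    new("Manifest", frame_interval = as.numeric(frame_interval),
        alternation_period = as.integer(alternation_period),
        atp_uM = as.numeric(atp_uM), remodeller = as.character(remodeller),
        seed = as.integer(seed))
}

setMethod("show", "Manifest", function(object) {
    cat("Manifest: frame_interval =", object@frame_interval,
        "s, alternation_period =", object@alternation_period,
        "frame(s), ATP =", object@atp_uM, "uM, remodeller =",
        object@remodeller,
        if (!is.na(object@seed)) paste0(", seed = ", object@seed) else "", "\n")
})

#' Raw three-channel ALEX trace set
#'
#' Per-frame detected intensities in the Cy3, Cy5 and Alexa750 channels under
#' alternating 532/638 nm excitation, for a set of surface-immobilised
#' molecules.  Intensities are in arbitrary detector units and may be negative
#' after background subtraction.  Within each molecule, frames strictly
#' increase, the excitation alternates in blocks of
#' \code{alternationPeriod(manifest)} frames starting with 532 nm, and
#' consecutive frame times differ by the manifest frame interval (within
#' 1e-6 s).
#'
#' @slot data data.frame with columns molecule_id, frame, time_s, excitation,
#'   I_cy3, I_cy5, I_a750.
#' @slot manifest the acquisition \linkS4class{Manifest}.
#'
#' @name TraceSet-class
#' @rdname TraceSet
#' @exportClass TraceSet
setClass("TraceSet",
         representation(data = "data.frame", manifest = "Manifest"))

.validate_trace_data <- function(df, man) {
    if (!is.data.frame(df))
        return("data must be a data.frame")
    missing_cols <- setdiff(.TRACE_COLUMNS, names(df))
    if (length(missing_cols))
        return(paste0("format error: missing column(s): ",
                      paste(missing_cols, collapse = ", ")))
    if (nrow(df) == 0L)
        return(TRUE)
    if (!all(df$excitation %in% c(532L, 638L)))
        return("excitation values must be 532 or 638")
    p <- man@alternation_period
    dt <- man@frame_interval
    for (id in unique(df$molecule_id)) {
        m <- df[df$molecule_id == id, , drop = FALSE]
        fr <- m$frame
        if (anyDuplicated(fr))
            return(paste0("validation error: duplicated frame index in molecule ",
                          id, " (frame ", fr[anyDuplicated(fr)], ")"))
        if (is.unsorted(fr, strictly = TRUE))
            return(paste0("validation error: frames not strictly increasing in molecule ", id))
        if (any(abs(diff(m$time_s) - dt * diff(fr)) > 1e-6))
            return(paste0("validation error: frame times of molecule ", id,
                          " do not follow the manifest frame interval"))
        expected <- ifelse((fr %/% p) %% 2L == 0L, 532L, 638L)
        bad <- which(m$excitation != expected)
        if (length(bad))
            return(paste0("validation error: non-alternating excitation pattern in molecule ",
                          id, " at frame ", fr[bad[1L]]))
    }
    TRUE
}

setValidity("TraceSet", function(object) {
    .validate_trace_data(object@data, object@manifest)
})

#' Construct a TraceSet from a frame table
#'
#' @param data data.frame with the trace table columns (see
#'   \linkS4class{TraceSet}).
#' @param manifest a \linkS4class{Manifest}.
#' @return A validated \linkS4class{TraceSet}.
#' @export
traceSet <- function(data, manifest = slideFRET::manifest()) {
    data <- as.data.frame(data)
    missing_cols <- setdiff(.TRACE_COLUMNS, names(data))
    if (length(missing_cols))
        stop("format error: missing column(s): ",
             paste(missing_cols, collapse = ", "))
    data <- data[, .TRACE_COLUMNS]
    data$molecule_id <- as.integer(data$molecule_id)
    data$frame <- as.integer(data$frame)
    data$excitation <- as.integer(data$excitation)
    new("TraceSet", data = data, manifest = manifest)
}

setMethod("show", "TraceSet", function(object) {
    ids <- unique(object@data$molecule_id)
    cat("TraceSet with", length(ids), "molecule(s),",
        nrow(object@data), "frames total\n")
    show(object@manifest)
})

#' Time-aligned ALEX record series
#'
#' Per molecule, time-aligned tuples of the five channel intensities that enter
#' the FRET observables: (I532_cy3, I532_cy5, I532_a750) from a 532 nm block
#' and (I638_cy5, I638_a750) from the nearest-in-time 638 nm block.  Each
#' record carries the midpoint timestamp of the two blocks as well as the
#' individual block timestamps.
#'
#' @slot data data.frame with columns molecule_id, time_s, t532_s, t638_s,
#'   I532_cy3, I532_cy5, I532_a750, I638_cy5, I638_a750.
#' @slot dropped named integer, per-molecule count of unpaired trailing blocks.
#' @slot manifest the acquisition \linkS4class{Manifest}.
#'
#' @name AlexSeries-class
#' @rdname AlexSeries
#' @exportClass AlexSeries
setClass("AlexSeries",
         representation(data = "data.frame", dropped = "integer",
                        manifest = "Manifest"))

setMethod("show", "AlexSeries", function(object) {
    cat("AlexSeries with", length(unique(object@data$molecule_id)),
        "molecule(s),", nrow(object@data), "aligned records,",
        sum(object@dropped), "dropped block(s)\n")
})

#' Spectral correction parameters
#'
#' Coefficients of the ALEX crosstalk model: direct-excitation fractions,
#' bleedthrough fractions, and multiplicative scale factors that normalise the
#' Cy3 and Alexa750 signals to Cy5-equivalent units (compensating quantum-yield
#' and detection-efficiency differences).  Direct excitation of Alexa750 by the
#' 532 nm laser is taken as negligible and has no coefficient.
#'
#' @slot d_cy5_532 direct-excitation fraction of Cy5 under 532 nm.
#' @slot d_a750_638 direct-excitation fraction of Alexa750 under 638 nm.
#' @slot b_cy3_cy5 bleedthrough fraction of Cy3 emission into the Cy5 channel.
#' @slot b_cy5_a750 bleedthrough fraction of Cy5 emission into the A750 channel.
#' @slot s_cy3,s_a750 multiplicative scale factors (> 0).
#' @slot estimated named logical, TRUE where the value came from data rather
#'   than a prior/default.
#' @slot n_segments named integer, per-parameter count of bleach segments used.
#'
#' @name CorrectionParams-class
#' @rdname CorrectionParams
#' @exportClass CorrectionParams
setClass("CorrectionParams",
         representation(d_cy5_532 = "numeric", d_a750_638 = "numeric",
                        b_cy3_cy5 = "numeric", b_cy5_a750 = "numeric",
                        s_cy3 = "numeric", s_a750 = "numeric",
                        estimated = "logical", n_segments = "integer"))

setValidity("CorrectionParams", function(object) {
    msg <- character()
    fr <- c(object@d_cy5_532, object@d_a750_638, object@b_cy3_cy5,
            object@b_cy5_a750)
    if (any(!is.finite(fr)) || any(fr < 0) || any(fr >= 1))
        msg <- c(msg, "direct-excitation and bleedthrough fractions must lie in [0, 1)")
    if (!is.finite(object@s_cy3) || object@s_cy3 <= 0 ||
        !is.finite(object@s_a750) || object@s_a750 <= 0)
        msg <- c(msg, "scale factors must be > 0")
    if (length(msg)) msg else TRUE
})

#' Construct CorrectionParams
#'
#' @param d_cy5_532,d_a750_638 direct-excitation fractions in [0, 1).
#' @param b_cy3_cy5,b_cy5_a750 bleedthrough fractions in [0, 1).
#' @param s_cy3,s_a750 positive scale factors to Cy5-equivalent units.
#' @param estimated named logical flags (set by \code{\link{estimateCorrections}}).
#' @param n_segments named integer segment counts per parameter.
#' @return A \linkS4class{CorrectionParams}.
#' @examples
#' correctionParams()                       # identity (no crosstalk)
#' correctionParams(b_cy3_cy5 = 0.1, d_cy5_532 = 0.05)
#' @export
correctionParams <- function(d_cy5_532 = 0, d_a750_638 = 0,
                             b_cy3_cy5 = 0, b_cy5_a750 = 0,
                             s_cy3 = 1, s_a750 = 1,
                             estimated = NULL, n_segments = NULL) {
    fields <- c("d_cy5_532", "d_a750_638", "b_cy3_cy5", "b_cy5_a750",
                "s_cy3", "s_a750")
    if (is.null(estimated))
        estimated <- stats::setNames(rep(FALSE, 6L), fields)
    if (is.null(n_segments))
        n_segments <- stats::setNames(rep(0L, 6L), fields)
    new("CorrectionParams",
        d_cy5_532 = d_cy5_532, d_a750_638 = d_a750_638,
        b_cy3_cy5 = b_cy3_cy5, b_cy5_a750 = b_cy5_a750,
        s_cy3 = s_cy3, s_a750 = s_a750,
        estimated = estimated, n_segments = as.integer(n_segments))
}

setMethod("show", "CorrectionParams", function(object) {
    cat("CorrectionParams:\n")
    cat(sprintf("  direct excitation : d_cy5_532 = %.4g, d_a750_638 = %.4g\n",
                object@d_cy5_532, object@d_a750_638))
    cat(sprintf("  bleedthrough      : b_cy3_cy5 = %.4g, b_cy5_a750 = %.4g\n",
                object@b_cy3_cy5, object@b_cy5_a750))
    cat(sprintf("  channel scaling   : s_cy3 = %.4g, s_a750 = %.4g\n",
                object@s_cy3, object@s_a750))
    if (any(object@estimated))
        cat("  estimated from data:",
            paste(names(object@estimated)[object@estimated], collapse = ", "), "\n")
})

#' Entry-/exit-side FRET trace set
#'
#' Per molecule, per aligned time point: the exit-side FRET observable (all
#' FRET originating from Cy3 under 532 nm excitation) and the entry-side FRET
#' observable (Cy5-to-A750 transfer under 638 nm excitation), together with the
#' corrected intensities and validity flags.  A record is invalid for a given
#' observable when its denominator falls below the configured floor or when a
#' dye required by that observable has photobleached.
#'
#' @slot data data.frame with columns molecule_id, time_s, t532_s, t638_s,
#'   E_exit, E_entry, valid_exit, valid_entry plus the corrected intensities.
#' @slot manifest the acquisition \linkS4class{Manifest}.
#'
#' @name FretTraceSet-class
#' @rdname FretTraceSet
#' @exportClass FretTraceSet
setClass("FretTraceSet",
         representation(data = "data.frame", manifest = "Manifest"))

setValidity("FretTraceSet", function(object) {
    d <- object@data
    bad_exit <- d$valid_exit & (d$E_exit < -0.2 | d$E_exit > 1.2)
    bad_entry <- d$valid_entry & (d$E_entry < -0.2 | d$E_entry > 1.2)
    if (any(bad_exit, na.rm = TRUE) || any(bad_entry, na.rm = TRUE))
        return("valid FRET values must lie in [-0.2, 1.2]")
    TRUE
})

setMethod("show", "FretTraceSet", function(object) {
    d <- object@data
    cat("FretTraceSet with", length(unique(d$molecule_id)), "molecule(s),",
        nrow(d), "records (", sum(d$valid_exit), "valid exit,",
        sum(d$valid_entry), "valid entry )\n")
})

#' Per-molecule event table
#'
#' One row per molecule with the detected (or ground-truth) onset of the
#' entry-side FRET change, the onset of the exit-side change, the lag time
#' between them, per-dye photobleach times (Inf if the dye survived the
#' trace), the censoring time for molecules whose exit onset was not observed,
#' and a semicolon-separated flag drawn from \code{complete}, \code{entry_only},
#' \code{censored_by_bleach}, \code{no_event}, \code{multi_step_bleach}.
#'
#' @slot data data.frame with columns molecule_id, t_entry_s, t_exit_s,
#'   t_lag_s, bleach_cy3_s, bleach_cy5_s, bleach_a750_s, t_censor_s, flag.
#'
#' @name EventTable-class
#' @rdname EventTable
#' @exportClass EventTable
setClass("EventTable", representation(data = "data.frame"))

setValidity("EventTable", function(object) {
    d <- object@data
    need <- c("molecule_id", "t_entry_s", "t_exit_s", "t_lag_s", "flag")
    missing_cols <- setdiff(need, names(d))
    if (length(missing_cols))
        return(paste("missing column(s):", paste(missing_cols, collapse = ", ")))
    both <- !is.na(d$t_entry_s) & !is.na(d$t_exit_s)
    if (!all(is.na(d$t_lag_s) != both))
        return("t_lag_s must be present iff both onsets are present")
    if (any(both & abs(d$t_lag_s - (d$t_exit_s - d$t_entry_s)) > 1e-9))
        return("t_lag_s must equal t_exit_s - t_entry_s")
    TRUE
})

#' Construct an EventTable
#'
#' @param data data.frame of per-molecule events (see \linkS4class{EventTable}).
#' @return An \linkS4class{EventTable}.
#' @export
eventTable <- function(data) {
    data <- as.data.frame(data)
    for (col in c("bleach_cy3_s", "bleach_cy5_s", "bleach_a750_s"))
        if (is.null(data[[col]])) data[[col]] <- Inf
    if (is.null(data$t_censor_s)) data$t_censor_s <- NA_real_
    if (is.null(data$flag)) data$flag <- "complete"
    new("EventTable", data = data)
}

setMethod("show", "EventTable", function(object) {
    d <- object@data
    cat("EventTable with", nrow(d), "molecule(s)\n")
    if (nrow(d)) {
        tab <- table(d$flag)
        for (fl in names(tab)) cat("  ", fl, ":", tab[[fl]], "\n")
    }
})

#' Kinetic configuration of the synthetic-data generator
#'
#' Ground-truth kinetics of a simulated remodelling experiment.  Each molecule
#' waits an exponentially distributed time (rate \code{k_init}) before the
#' entry-side FRET change begins, then an exponentially distributed lag before
#' the exit-side change, whose mean follows a Michaelis-Menten dependence on
#' ATP: \code{1/tau = k_max * atp / (K_app + atp)}.  The entry-side
#' (Cy5 to A750) efficiency is non-monotonic (baseline, peak as the A750 dye
#' approaches the central Cy5, final level after it passes); the exit-side
#' (Cy3 to Cy5) efficiency decreases monotonically.  All FRET trajectories are
#' piecewise linear with the configured ramp durations.
#'
#' @slot atp_uM ATP concentration (micromolar, > 0).
#' @slot k_max saturating lag rate (1/s).
#' @slot K_app half-saturation constant of the lag rate (micromolar).
#' @slot k_init rate of leaving the initial waiting state (1/s).
#' @slot d_rise,d_fall,d_exit ramp durations (s) of the entry rise, entry fall
#'   and exit decrease.
#' @slot E_exit0,E_exit1 exit-side efficiencies before/after sliding
#'   (E_exit1 < E_exit0).
#' @slot E_entry0,E_entry_peak,E_entry1 entry-side baseline, peak and final
#'   efficiencies (peak above both).
#' @slot bleach_rate_cy3,bleach_rate_cy5,bleach_rate_a750 per-dye photobleach
#'   rates (1/s of exposure to the laser(s) exciting the dye).
#' @slot duration trace duration (s).
#' @slot n_molecules number of molecules.
#' @slot seed integer RNG seed.
#'
#' @name KineticConfig-class
#' @rdname KineticConfig
#' @exportClass KineticConfig
setClass("KineticConfig",
         representation(atp_uM = "numeric", k_max = "numeric",
                        K_app = "numeric", k_init = "numeric",
                        d_rise = "numeric", d_fall = "numeric",
                        d_exit = "numeric",
                        E_exit0 = "numeric", E_exit1 = "numeric",
                        E_entry0 = "numeric", E_entry_peak = "numeric",
                        E_entry1 = "numeric",
                        bleach_rate_cy3 = "numeric",
                        bleach_rate_cy5 = "numeric",
                        bleach_rate_a750 = "numeric",
                        duration = "numeric",
                        n_molecules = "integer", seed = "integer"))

setValidity("KineticConfig", function(object) {
    msg <- character()
    rates <- c(object@k_max, object@K_app, object@k_init,
               object@d_rise, object@d_fall, object@d_exit, object@duration)
    if (any(!is.finite(rates)) || any(rates <= 0))
        msg <- c(msg, "all rates and durations must be finite and > 0")
    if (!is.finite(object@atp_uM) || object@atp_uM <= 0)
        msg <- c(msg, paste("atp_uM must be > 0: a zero ATP concentration gives",
                            "an infinite mean lag (non-finite rate)"))
    ef <- c(object@E_exit0, object@E_exit1, object@E_entry0,
            object@E_entry_peak, object@E_entry1)
    if (any(ef < 0) || any(ef > 1))
        msg <- c(msg, "all FRET efficiencies must lie in [0, 1]")
    if (object@E_entry_peak <= max(object@E_entry0, object@E_entry1))
        msg <- c(msg, "E_entry_peak must exceed both E_entry0 and E_entry1 (non-monotonic entry)")
    if (object@E_exit1 >= object@E_exit0)
        msg <- c(msg, "E_exit1 must be below E_exit0 (exit FRET decreases)")
    if (any(c(object@bleach_rate_cy3, object@bleach_rate_cy5,
              object@bleach_rate_a750) < 0))
        msg <- c(msg, "bleach rates must be >= 0")
    if (object@n_molecules < 1L)
        msg <- c(msg, "n_molecules must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Construct a KineticConfig
#'
#' Defaults describe a Chd1 experiment at 500 uM ATP on the original 601
#' orientation: with \code{K_app = 60} uM and \code{k_max = 560/(500*4.9)} the
#' mean lag at 500 uM ATP is 4.9 s.
#'
#' @param atp_uM,k_max,K_app,k_init,d_rise,d_fall,d_exit see
#'   \linkS4class{KineticConfig}.
#' @param E_exit0,E_exit1,E_entry0,E_entry_peak,E_entry1 FRET levels.
#' @param bleach_rate_cy3,bleach_rate_cy5,bleach_rate_a750 per-dye bleach rates
#'   (1/s of exposure).
#' @param duration trace duration in seconds.
#' @param n_molecules number of molecules.
#' @param seed integer RNG seed.
#' @return A \linkS4class{KineticConfig}.
#' @examples
#' cfg <- kineticConfig(n_molecules = 10, seed = 7)
#' meanLag(cfg)   # 4.9 s at the defaults
#' @export
kineticConfig <- function(atp_uM = 500, k_max = (60 + 500) / (500 * 4.9),
                          K_app = 60, k_init = 0.1,
                          d_rise = 2, d_fall = 2, d_exit = 2,
                          E_exit0 = 0.7, E_exit1 = 0.25,
                          E_entry0 = 0.35, E_entry_peak = 0.9, E_entry1 = 0.15,
                          bleach_rate_cy3 = 5e-4, bleach_rate_cy5 = 5e-4,
                          bleach_rate_a750 = 5e-4,
                          duration = 120, n_molecules = 100L, seed = 1L) {
    new("KineticConfig", atp_uM = atp_uM, k_max = k_max, K_app = K_app,
        k_init = k_init, d_rise = d_rise, d_fall = d_fall, d_exit = d_exit,
        E_exit0 = E_exit0, E_exit1 = E_exit1, E_entry0 = E_entry0,
        E_entry_peak = E_entry_peak, E_entry1 = E_entry1,
        bleach_rate_cy3 = bleach_rate_cy3, bleach_rate_cy5 = bleach_rate_cy5,
        bleach_rate_a750 = bleach_rate_a750, duration = duration,
        n_molecules = as.integer(n_molecules), seed = as.integer(seed))
}

#' Mean lag time implied by a kinetic configuration
#'
#' \code{tau = (K_app + atp) / (k_max * atp)}, the reciprocal of the
#' Michaelis-Menten lag rate.
#'
#' @param cfg a \linkS4class{KineticConfig}.
#' @return Mean lag time in seconds.
#' @export
meanLag <- function(cfg) {
    stopifnot(is(cfg, "KineticConfig"))
    (cfg@K_app + cfg@atp_uM) / (cfg@k_max * cfg@atp_uM)
}

setMethod("show", "KineticConfig", function(object) {
    cat(sprintf(paste0("KineticConfig: ATP = %g uM, k_max = %.4g /s, ",
                       "K_app = %g uM (mean lag %.3g s), k_init = %.3g /s, ",
                       "%d molecule(s), %g s traces, seed %d\n"),
                object@atp_uM, object@k_max, object@K_app, meanLag(object),
                object@k_init, object@n_molecules, object@duration,
                object@seed))
})

#' Photophysics configuration of the synthetic-data generator
#'
#' Parameters of the detection model used by \code{\link{renderTraces}}: the
#' expected photon budget per excitation per frame, per-channel detection scale
#' factors (quantum yield times detector efficiency, with Cy5 defined as 1),
#' direct-excitation and bleedthrough fractions, per-channel background offsets
#' and Gaussian read-noise SDs, and a switch for Poisson shot noise.
#'
#' @slot photon_budget expected photons per excitation per frame.
#' @slot g_cy3,g_a750 detection scale factors relative to Cy5.
#' @slot d_cy5_532,d_a750_638 direct-excitation fractions in [0, 1).
#' @slot b_cy3_cy5,b_cy5_a750 bleedthrough fractions in [0, 1).
#' @slot background named numeric, per-channel background offsets (counts).
#' @slot read_noise named numeric, per-channel read-noise SDs (counts).
#' @slot shot_noise logical, apply Poisson shot noise.
#'
#' @name PhotoConfig-class
#' @rdname PhotoConfig
#' @exportClass PhotoConfig
setClass("PhotoConfig",
         representation(photon_budget = "numeric",
                        g_cy3 = "numeric", g_a750 = "numeric",
                        d_cy5_532 = "numeric", d_a750_638 = "numeric",
                        b_cy3_cy5 = "numeric", b_cy5_a750 = "numeric",
                        background = "numeric", read_noise = "numeric",
                        shot_noise = "logical"))

setValidity("PhotoConfig", function(object) {
    msg <- character()
    if (object@photon_budget <= 0)
        msg <- c(msg, "photon_budget must be > 0")
    if (object@g_cy3 <= 0 || object@g_a750 <= 0)
        msg <- c(msg, "scale factors must be > 0")
    fr <- c(object@d_cy5_532, object@d_a750_638, object@b_cy3_cy5,
            object@b_cy5_a750)
    if (any(fr < 0) || any(fr >= 1))
        msg <- c(msg, "fractions must lie in [0, 1)")
    if (any(object@read_noise < 0))
        msg <- c(msg, "read-noise SDs must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct a PhotoConfig
#'
#' The defaults (photon budget 500/frame, bleedthrough 0.1, direct excitation
#' 0.05, read noise SD 5, background 10) are conventional placeholders for a
#' TIRF/EMCCD acquisition; they are recorded with any rendered data set.
#'
#' @param photon_budget expected photons per excitation per frame.
#' @param g_cy3,g_a750 detection scale factors relative to Cy5.
#' @param d_cy5_532,d_a750_638 direct-excitation fractions.
#' @param b_cy3_cy5,b_cy5_a750 bleedthrough fractions.
#' @param background per-channel background offset (recycled to 3 channels).
#' @param read_noise per-channel Gaussian read-noise SD (recycled).
#' @param shot_noise logical, apply Poisson shot noise.
#' @return A \linkS4class{PhotoConfig}.
#' @examples
#' photoConfig()                          # default noisy acquisition
#' photoConfig(read_noise = 0, shot_noise = FALSE)   # noiseless render
#' @export
photoConfig <- function(photon_budget = 500, g_cy3 = 1.3, g_a750 = 0.8,
                        d_cy5_532 = 0.05, d_a750_638 = 0.05,
                        b_cy3_cy5 = 0.1, b_cy5_a750 = 0.1,
                        background = 10, read_noise = 5, shot_noise = TRUE) {
    chan <- c("cy3", "cy5", "a750")
    background <- stats::setNames(rep_len(background, 3L), chan)
    read_noise <- stats::setNames(rep_len(read_noise, 3L), chan)
    new("PhotoConfig", photon_budget = photon_budget, g_cy3 = g_cy3,
        g_a750 = g_a750, d_cy5_532 = d_cy5_532, d_a750_638 = d_a750_638,
        b_cy3_cy5 = b_cy3_cy5, b_cy5_a750 = b_cy5_a750,
        background = background, read_noise = read_noise,
        shot_noise = shot_noise)
}

setMethod("show", "PhotoConfig", function(object) {
    cat(sprintf(paste0("PhotoConfig: %g photons/frame, g = (%.3g, 1, %.3g), ",
                       "direct (%.3g, %.3g), bleedthrough (%.3g, %.3g), ",
                       "read noise %.3g, background %.3g, shot noise %s\n"),
                object@photon_budget, object@g_cy3, object@g_a750,
                object@d_cy5_532, object@d_a750_638, object@b_cy3_cy5,
                object@b_cy5_a750, object@read_noise[[1L]],
                object@background[[1L]], object@shot_noise))
})

#' Ground-truth event timelines
#'
#' The sampled per-molecule remodelling timelines of a synthetic data set:
#' onset of the entry-side FRET change, lag to the exit-side onset, and
#' per-dye photobleach times, together with the generating
#' \linkS4class{KineticConfig} (which carries the piecewise-linear FRET levels
#' and ramp durations shared by all molecules).  \code{\link{timelineFret}}
#' evaluates the ground-truth efficiency trajectories E1(t) (exit side,
#' Cy3 to Cy5) and E2(t) (entry side, Cy5 to A750).
#'
#' @slot data data.frame with columns molecule_id, t_entry_onset,
#'   t_lag, t_exit_onset, bleach_cy3, bleach_cy5, bleach_a750.
#' @slot config the generating \linkS4class{KineticConfig}.
#'
#' @name TimelineSet-class
#' @rdname TimelineSet
#' @exportClass TimelineSet
setClass("TimelineSet",
         representation(data = "data.frame", config = "KineticConfig"))

setValidity("TimelineSet", function(object) {
    d <- object@data
    if (nrow(d) && any(d$t_exit_onset < d$t_entry_onset))
        return("t_exit_onset must be >= t_entry_onset for every molecule")
    TRUE
})

setMethod("show", "TimelineSet", function(object) {
    cat("TimelineSet with", nrow(object@data), "molecule(s); mean lag",
        signif(mean(object@data$t_lag), 3), "s\n")
})

#' Detection parameters for onset and bleach-step calling
#'
#' @slot penalty change-point penalty (RSS-improvement units) used when
#'   accepting additional bleach steps.
#' @slot min_segment minimum points per fitted segment (>= 2).
#' @slot onset_threshold minimum absolute FRET change to call an event.
#' @slot baseline_window points used to estimate the local baseline (and the
#'   running-mean smoothing half-width is derived from it).
#' @slot max_ramp maximum length (aligned records) of the fitted ramp segment.
#'
#' @name DetectionParams-class
#' @rdname DetectionParams
#' @exportClass DetectionParams
setClass("DetectionParams",
         representation(penalty = "numeric", min_segment = "integer",
                        onset_threshold = "numeric",
                        baseline_window = "integer", max_ramp = "integer"))

setValidity("DetectionParams", function(object) {
    msg <- character()
    if (object@min_segment < 2L)
        msg <- c(msg, "min_segment must be >= 2")
    if (object@onset_threshold <= 0)
        msg <- c(msg, "onset_threshold must be > 0")
    if (object@max_ramp < 2L)
        msg <- c(msg, "max_ramp must be >= 2")
    if (length(msg)) msg else TRUE
})

#' Construct DetectionParams
#'
#' Defaults: onset threshold 0.1 FRET (above the shot-noise floor of the
#' default photophysics), baseline window 10 ALEX cycles, ramp segments up to
#' 50 cycles (10 s at the default 0.2 s cycle, well above the few-second FRET
#' transitions).
#'
#' @param penalty RSS penalty for accepting an additional bleach step.
#' @param min_segment minimum points per fitted segment.
#' @param onset_threshold minimum absolute FRET change to call an event.
#' @param baseline_window points of local baseline.
#' @param max_ramp maximum ramp length in aligned records.
#' @return A \linkS4class{DetectionParams}.
#' @export
detectionParams <- function(penalty = 20, min_segment = 3L,
                            onset_threshold = 0.1, baseline_window = 10L,
                            max_ramp = 50L) {
    new("DetectionParams", penalty = penalty,
        min_segment = as.integer(min_segment),
        onset_threshold = onset_threshold,
        baseline_window = as.integer(baseline_window),
        max_ramp = as.integer(max_ramp))
}

#' Single-exponential fit of a lag-time distribution
#'
#' @slot mean_lag fitted mean lag (s).
#' @slot sem bootstrap standard error of the mean lag (s).
#' @slot n_events number of uncensored events.
#' @slot n_censored number of censored observations used.
#' @slot ks_statistic,ks_p Kolmogorov-Smirnov goodness of fit of the
#'   uncensored lags against the fitted exponential.
#' @slot method one of "mle", "mle_censored", "binned_ls".
#'
#' @name ExpFit-class
#' @rdname ExpFit
#' @exportClass ExpFit
setClass("ExpFit",
         representation(mean_lag = "numeric", sem = "numeric",
                        n_events = "integer", n_censored = "integer",
                        ks_statistic = "numeric", ks_p = "numeric",
                        method = "character"))

setValidity("ExpFit", function(object) {
    if (!is.finite(object@mean_lag) || object@mean_lag <= 0)
        return("mean_lag must be > 0")
    if (object@n_events < 1L)
        return("n_events must be >= 1")
    TRUE
})

setMethod("show", "ExpFit", function(object) {
    cat(sprintf("ExpFit (%s): mean lag %.3g +/- %.2g s (N = %d events",
                object@method, object@mean_lag, object@sem, object@n_events))
    if (object@n_censored > 0L)
        cat(",", object@n_censored, "censored")
    cat(sprintf("), KS D = %.3g, p = %.3g\n", object@ks_statistic, object@ks_p))
})

#' Michaelis-Menten fit of the lag rate versus ATP
#'
#' @slot k_max saturating rate (1/s) with confidence interval.
#' @slot K_app half-saturation constant (uM) with confidence interval.
#' @slot k_max_ci,K_app_ci 95 percent confidence intervals.
#' @slot residuals named numeric, per-concentration residuals of 1/mean_lag.
#' @slot converged logical.
#'
#' @name HyperbolicFit-class
#' @rdname HyperbolicFit
#' @exportClass HyperbolicFit
setClass("HyperbolicFit",
         representation(k_max = "numeric", K_app = "numeric",
                        k_max_ci = "numeric", K_app_ci = "numeric",
                        residuals = "numeric", converged = "logical"))

setValidity("HyperbolicFit", function(object) {
    if (object@converged && (object@k_max <= 0 || object@K_app <= 0))
        return("k_max and K_app must be > 0")
    TRUE
})

setMethod("show", "HyperbolicFit", function(object) {
    cat(sprintf(paste0("HyperbolicFit: k_max = %.4g /s [%.4g, %.4g], ",
                       "K_app = %.4g uM [%.4g, %.4g]%s\n"),
                object@k_max, object@k_max_ci[1L], object@k_max_ci[2L],
                object@K_app, object@K_app_ci[1L], object@K_app_ci[2L],
                if (object@converged) "" else " (NOT converged)"))
})

#' Configuration of the DNA-buffering (twist-defect) model
#'
#' Discrete model of remodeller-driven DNA movement around the histone
#' octamer: on binding, the remodeller pulls \code{initial_defect} bp onto the
#' entry side as a twist defect; ATP-driven 1-bp translocations inject further
#' bp at the entry-side SHL2 until the single-stranded gap (located
#' \code{gap_offset} bp from the stall site) blocks the motor; up to
#' \code{capacity_entry_dyad} bp are absorbed between the entry SHL2 and the
#' dyad probe and up to \code{capacity_dyad_exit} bp between dyad and exit
#' probe; only the excess propagates to the exit side.
#'
#' @slot initial_defect bp pulled on at binding (default 1).
#' @slot capacity_entry_dyad bp absorbable between entry SHL2 and dyad probe.
#' @slot capacity_dyad_exit bp absorbable between dyad and exit probe.
#' @slot gap_offset bp between the ssDNA gap and the stall site (Inf = ungapped).
#' @slot k_inj injection rate (1/s per 1-bp translocation).
#' @slot k_relax relaxation rate (1/s) at which a buffered excess bp passes
#'   downstream.
#' @slot exit_propagation logical; when FALSE the last buffer never releases
#'   downstream and injections stop once every buffer is saturated.
#' @slot seed integer RNG seed for the stochastic simulator.
#'
#' @name BufferModelConfig-class
#' @rdname BufferModelConfig
#' @exportClass BufferModelConfig
setClass("BufferModelConfig",
         representation(initial_defect = "integer",
                        capacity_entry_dyad = "integer",
                        capacity_dyad_exit = "integer",
                        gap_offset = "numeric",
                        k_inj = "numeric", k_relax = "numeric",
                        exit_propagation = "logical", seed = "integer"))

setValidity("BufferModelConfig", function(object) {
    msg <- character()
    if (object@initial_defect < 0L)
        msg <- c(msg, "initial_defect must be >= 0")
    if (object@capacity_entry_dyad < 0L || object@capacity_dyad_exit < 0L)
        msg <- c(msg, "capacities must be >= 0")
    if (!(is.infinite(object@gap_offset) ||
          (object@gap_offset >= 0 && object@gap_offset == round(object@gap_offset))))
        msg <- c(msg, "gap_offset must be a non-negative integer or Inf")
    if (object@k_inj <= 0 || object@k_relax <= 0 ||
        is.infinite(object@k_inj) || is.infinite(object@k_relax))
        msg <- c(msg, "rates must be finite and > 0")
    if (length(msg)) msg else TRUE
})

#' Construct a BufferModelConfig
#'
#' Defaults (initial defect 1 bp; capacities 2 bp entry-to-dyad and 3 bp
#' dyad-to-exit) are calibrated so that the deterministic gap rule reproduces
#' the 9/7/4 nt entry/dyad/exit probe shifts of an m = 8 bp gapped nucleosome.
#'
#' @param initial_defect bp pulled onto the entry side at binding.
#' @param capacity_entry_dyad,capacity_dyad_exit buffer capacities (bp).
#' @param gap_offset gap position in bp from the stall site (Inf = ungapped).
#' @param k_inj,k_relax injection and relaxation rates (1/s).
#' @param exit_propagation allow release beyond the last buffer.
#' @param seed integer RNG seed.
#' @return A \linkS4class{BufferModelConfig}.
#' @examples
#' deterministicShifts(bufferModelConfig(gap_offset = 8))
#' @export
bufferModelConfig <- function(initial_defect = 1L, capacity_entry_dyad = 2L,
                              capacity_dyad_exit = 3L, gap_offset = Inf,
                              k_inj = 1, k_relax = 1,
                              exit_propagation = TRUE, seed = 1L) {
    new("BufferModelConfig", initial_defect = as.integer(initial_defect),
        capacity_entry_dyad = as.integer(capacity_entry_dyad),
        capacity_dyad_exit = as.integer(capacity_dyad_exit),
        gap_offset = as.numeric(gap_offset), k_inj = k_inj, k_relax = k_relax,
        exit_propagation = exit_propagation, seed = as.integer(seed))
}

setMethod("show", "BufferModelConfig", function(object) {
    cat(sprintf(paste0("BufferModelConfig: defect %d bp, capacities (%d, %d) bp, ",
                       "gap offset %s bp, k_inj %.3g /s, k_relax %.3g /s\n"),
                object@initial_defect, object@capacity_entry_dyad,
                object@capacity_dyad_exit,
                if (is.infinite(object@gap_offset)) "Inf"
                else format(object@gap_offset),
                object@k_inj, object@k_relax))
})

#' Probe shifts of the deterministic buffering model
#'
#' @slot entry_shift,dyad_shift,exit_shift probe shifts in bp (nt on the gel).
#' @slot absorbed_entry_dyad,absorbed_dyad_exit bp absorbed between probes.
#'
#' @name ProbeShifts-class
#' @rdname ProbeShifts
#' @exportClass ProbeShifts
setClass("ProbeShifts",
         representation(entry_shift = "integer", dyad_shift = "integer",
                        exit_shift = "integer",
                        absorbed_entry_dyad = "integer",
                        absorbed_dyad_exit = "integer"))

setValidity("ProbeShifts", function(object) {
    msg <- character()
    if (object@entry_shift != object@dyad_shift + object@absorbed_entry_dyad)
        msg <- c(msg, "entry_shift must equal dyad_shift + absorbed_entry_dyad")
    if (object@dyad_shift != object@exit_shift + object@absorbed_dyad_exit)
        msg <- c(msg, "dyad_shift must equal exit_shift + absorbed_dyad_exit")
    if (any(c(object@entry_shift, object@dyad_shift, object@exit_shift,
              object@absorbed_entry_dyad, object@absorbed_dyad_exit) < 0L))
        msg <- c(msg, "shifts and absorbed counts must be non-negative")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ProbeShifts", function(object) {
    cat(sprintf(paste0("ProbeShifts: entry %d, dyad %d, exit %d bp ",
                       "(absorbed %d + %d bp)\n"),
                object@entry_shift, object@dyad_shift, object@exit_shift,
                object@absorbed_entry_dyad, object@absorbed_dyad_exit))
})
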