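## Ground-truth kinetics of the synthetic-data generator -----------------------

#' Sample ground-truth remodelling timelines
#'
#' Draws, for each molecule, the onset of the entry-side FRET change
#' (exponential with rate \code{k_init}), the lag to the exit-side onset
#' (exponential with mean \code{(K_app + atp)/(k_max * atp)}, the
#' Michaelis-Menten dependence of the lag rate on ATP), and per-dye photobleach
#' times.  Bleach times are exponential in the cumulative exposure to the
#' laser(s) exciting each dye: Cy3 sees only the 532 nm half of the ALEX
#' cycle, Cy5 and Alexa750 are excited (directly or via transfer) throughout,
#' so the Cy3 wall-clock bleach time is the exposure draw divided by the 532 nm
#' duty cycle of one half.
#'
#' @param cfg a \linkS4class{KineticConfig}.
#' @param seed RNG seed; defaults to the seed stored in \code{cfg}.
#' @return A \linkS4class{TimelineSet}.
#' @examples
#' tl <- sampleKinetics(kineticConfig(n_molecules = 5, seed = 42))
#' traceData(tl)
#' @export
sampleKinetics <- function(cfg, seed = cfg@seed) {
    stopifnot(is(cfg, "KineticConfig"))
    tau <- meanLag(cfg)
    if (!is.finite(tau))
        stop("mean lag is not finite: atp_uM = 0 with k_max > 0 gives tau = Inf")
    set.seed(seed)
    n <- cfg@n_molecules
    t_entry <- stats::rexp(n, rate = cfg@k_init)
    t_lag <- stats::rexp(n, rate = 1 / tau)
    draw_bleach <- function(rate, duty) {
        if (rate <= 0) return(rep(Inf, n))
        stats::rexp(n, rate = rate) / duty
    }
    d <- data.frame(molecule_id = seq_len(n) - 1L,
                    t_entry_onset = t_entry,
                    t_lag = t_lag,
                    t_exit_onset = t_entry + t_lag,
                    bleach_cy3 = draw_bleach(cfg@bleach_rate_cy3, 0.5),
                    bleach_cy5 = draw_bleach(cfg@bleach_rate_cy5, 1),
                    bleach_a750 = draw_bleach(cfg@bleach_rate_a750, 1))
    new("TimelineSet", data = d, config = cfg)
}

#' Evaluate ground-truth FRET trajectories
#'
#' Piecewise-linear ground truth of one molecule: the exit-side efficiency
#' E1(t) stays at \code{E_exit0} until the exit onset and ramps linearly to
#' \code{E_exit1} over \code{d_exit}; the entry-side efficiency E2(t) stays at
#' \code{E_entry0} until the entry onset, ramps to \code{E_entry_peak} over
#' \code{d_rise}, then to \code{E_entry1} over \code{d_fall}.  Photobleaching
#' is not applied here; it acts on emission, not on the underlying distances.
#'
#' @param timelines a \linkS4class{TimelineSet}.
#' @param molecule molecule identifier.
#' @param t numeric vector of times (s).
#' @return A list with numeric vectors \code{E1} (exit side, Cy3 to Cy5) and
#'   \code{E2} (entry side, Cy5 to A750).
#' @export
timelineFret <- function(timelines, molecule, t) {
    stopifnot(is(timelines, "TimelineSet"))
    cfg <- timelines@config
    row <- timelines@data[timelines@data$molecule_id == molecule, , drop = FALSE]
    if (nrow(row) != 1L)
        stop("unknown molecule: ", molecule)
    ramp <- function(t, t0, dur, from, to) {
        ifelse(t < t0, from,
               ifelse(t >= t0 + dur, to, from + (to - from) * (t - t0) / dur))
    }
    E1 <- ramp(t, row$t_exit_onset, cfg@d_exit, cfg@E_exit0, cfg@E_exit1)
    peak_t <- row$t_entry_onset + cfg@d_rise
    E2 <- ifelse(t < peak_t,
                 ramp(t, row$t_entry_onset, cfg@d_rise, cfg@E_entry0,
                      cfg@E_entry_peak),
                 ramp(t, peak_t, cfg@d_fall, cfg@E_entry_peak, cfg@E_entry1))
    list(E1 = E1, E2 = E2)
}

#' Ground-truth event table of a timeline set
#'
#' @param timelines a \linkS4class{TimelineSet}.
#' @return An \linkS4class{EventTable} with the true onsets, lag and bleach
#'   times per molecule (flag \code{"complete"}).
#' @export
groundTruthTable <- function(timelines) {
    stopifnot(is(timelines, "TimelineSet"))
    d <- timelines@data
    eventTable(data.frame(molecule_id = d$molecule_id,
                          t_entry_s = d$t_entry_onset,
                          t_exit_s = d$t_exit_onset,
                          t_lag_s = d$t_lag,
                          bleach_cy3_s = d$bleach_cy3,
                          bleach_cy5_s = d$bleach_cy5,
                          bleach_a750_s = d$bleach_a750,
                          t_censor_s = NA_real_,
                          flag = "complete"))
}
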