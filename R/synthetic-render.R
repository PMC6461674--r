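## Rendering ground-truth timelines into raw ALEX traces -----------------------
##
## Forward photophysics per frame, with N the photon budget per excitation:
##   532 nm: Cy3-excited photons split Cy3 : Cy5 : A750 as
##           (1-E1) : E1(1-E2) : E1*E2 (cascaded Cy3->Cy5->A750 transfer);
##           directly excited Cy5 (fraction d_cy5_532 of N) re-transfers to
##           A750 with efficiency E2.  Cy3->A750 transfer is zero throughout.
##   638 nm: Cy5-excited photons split Cy5 : A750 as (1-E2) : E2, plus a
##           directly excited A750 fraction d_a750_638.
## Each dye's emission is scaled by its g factor (Cy5 = 1); bleedthrough mixes
## Cy3 emission into the Cy5 channel and Cy5 emission into the A750 channel.
## Poisson shot noise is applied to signal + background, Gaussian read noise
## added, and the (known) background subtracted, so rendered intensities are
## background-subtracted and may be negative.  After a dye's bleach time its
## emission is zero; a bleached acceptor no longer accepts transfer.

#' Render ground-truth timelines into a raw ALEX trace set
#'
#' @param timelines a \linkS4class{TimelineSet} from \code{\link{sampleKinetics}}.
#' @param photo a \linkS4class{PhotoConfig}.
#' @param man acquisition \linkS4class{Manifest}; defaults to one matching the
#'   timeline configuration (ATP concentration and seed recorded).
#' @param seed RNG seed for the noise stream; defaults to the timeline seed
#'   plus one so that kinetics and noise use distinct streams.
#' @return A \linkS4class{TraceSet}.
#' @examples
#' tl <- sampleKinetics(kineticConfig(n_molecules = 2, duration = 20, seed = 3))
#' ts <- renderTraces(tl, photoConfig(read_noise = 0, shot_noise = FALSE))
#' @export
renderTraces <- function(timelines, photo = photoConfig(),
                         man = NULL, seed = NULL) {
    stopifnot(is(timelines, "TimelineSet"), is(photo, "PhotoConfig"))
    cfg <- timelines@config
    if (is.null(man))
        man <- manifest(atp_uM = cfg@atp_uM, seed = cfg@seed)
    if (is.null(seed))
        seed <- cfg@seed + 1L
    set.seed(seed)

    dt <- man@frame_interval
    p <- man@alternation_period
    nframes <- max(2L, floor(cfg@duration / dt))
    frame <- seq_len(nframes) - 1L
    time <- frame * dt
    is532 <- (frame %/% p) %% 2L == 0L
    N <- photo@photon_budget
    g3 <- photo@g_cy3; ga <- photo@g_a750
    d1 <- photo@d_cy5_532; d2 <- photo@d_a750_638
    b1 <- photo@b_cy3_cy5; b2 <- photo@b_cy5_a750
    bg <- photo@background; rn <- photo@read_noise

    tl <- timelines@data
    pieces <- vector("list", nrow(tl))
    for (i in seq_len(nrow(tl))) {
        row <- tl[i, ]
        gt <- timelineFret(timelines, row$molecule_id, time)
        a3 <- time < row$bleach_cy3
        a5 <- time < row$bleach_cy5
        a7 <- time < row$bleach_a750
        E1 <- gt$E1 * a5          # no Cy3->Cy5 transfer without Cy5
        E2 <- gt$E2 * a7          # no Cy5->A750 transfer without A750

        ## per-dye emissions in their own channels (detector units)
        C3 <- ifelse(is532, a3 * g3 * N * (1 - E1 * a3), 0)
        X5 <- ifelse(is532,
                     a5 * N * (E1 * a3 + d1),   # FRET-excited + direct Cy5
                     a5 * N)                    # 638 nm excites Cy5 directly
        C5 <- X5 * (1 - E2)
        A7 <- X5 * E2 * ga + ifelse(is532, 0, a7 * d2 * N * ga)

        ## bleedthrough into neighbouring channels
        raw_cy3 <- C3
        raw_cy5 <- C5 + b1 * C3
        raw_a750 <- A7 + b2 * C5

        addnoise <- function(lam, channel) {
            lam_tot <- pmax(lam + bg[[channel]], 0)
            counts <- if (photo@shot_noise)
                stats::rpois(length(lam_tot), lam_tot) else lam_tot
            if (rn[[channel]] > 0)
                counts <- counts + stats::rnorm(length(counts),
                                                sd = rn[[channel]])
            counts - bg[[channel]]
        }
        pieces[[i]] <- data.frame(
            molecule_id = row$molecule_id, frame = frame, time_s = time,
            excitation = ifelse(is532, 532L, 638L),
            I_cy3 = addnoise(raw_cy3, "cy3"),
            I_cy5 = addnoise(raw_cy5, "cy5"),
            I_a750 = addnoise(raw_a750, "a750"))
    }
    traceSet(do.call(rbind, pieces), man)
}

#' Simulate a complete synthetic data set
#'
#' Convenience wrapper: samples timelines, renders traces and returns the
#' ground-truth event table alongside.
#'
#' @param cfg a \linkS4class{KineticConfig}.
#' @param photo a \linkS4class{PhotoConfig}.
#' @param man optional \linkS4class{Manifest}.
#' @return A list with elements \code{traces} (\linkS4class{TraceSet}),
#'   \code{timelines} (\linkS4class{TimelineSet}) and \code{truth}
#'   (\linkS4class{EventTable}).
#' @export
simulateDataset <- function(cfg, photo = photoConfig(), man = NULL) {
    tl <- sampleKinetics(cfg)
    list(traces = renderTraces(tl, photo, man = man),
         timelines = tl,
         truth = groundTruthTable(tl))
}
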