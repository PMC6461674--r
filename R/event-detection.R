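## Change-point detection: photobleach steps and FRET-change onsets ------------

## O(1) segment statistics from cumulative sums; a and b may be vectors
.segsum <- function(cs, a, b) cs[b] - ifelse(a > 1L, cs[pmax(a - 1L, 1L)], 0)

.const_rss <- function(Sy, Sy2, a, b) {
    n <- b - a + 1
    .segsum(Sy2, a, b) - .segsum(Sy, a, b)^2 / n
}

## residual sum of squares of least-squares lines on segments [a, b] (vector b)
.line_rss <- function(Sy, Sy2, St, St2, Sty, a, b) {
    n <- b - a + 1
    sy <- .segsum(Sy, a, b); syy <- .segsum(Sy2, a, b)
    st <- .segsum(St, a, b); stt <- .segsum(St2, a, b)
    sty <- .segsum(Sty, a, b)
    sxx <- stt - st^2 / n
    sxy <- sty - st * sy / n
    syc <- syy - sy^2 / n
    rss <- ifelse(sxx > 1e-12, syc - sxy^2 / sxx, syc)
    pmax(rss, 0)
}

#' Detect the onset of a FRET change
#'
#' Fits a piecewise model -- constant baseline, then linear ramp, then
#' constant plateau (the plateau may be empty) -- by exhaustive scan of the
#' two breakpoints, minimising the residual sum of squares; ramp segments are
#' limited to \code{max_ramp} points.  The onset is the timestamp of the first
#' post-baseline point.  An event is called only when the fitted change from
#' the baseline to the end of the ramp exceeds \code{onset_threshold} in the
#' required direction.  For \code{direction = "increase"} the series is first
#' truncated at the maximum of a lightly smoothed copy, so that the
#' non-monotonic entry-side trace (rise, then fall past the central dye) is
#' dated by its first rising phase.
#'
#' @param time numeric vector of timestamps (s).
#' @param value numeric vector of FRET values (NAs treated as invalid).
#' @param params a \linkS4class{DetectionParams}.
#' @param direction one of \code{"increase"}, \code{"decrease"}, \code{"any"}.
#' @return A list with elements \code{found} (logical), \code{onset} (s),
#'   \code{confidence} (RSS reduction versus a single constant fit),
#'   \code{change} (fitted FRET change over the ramp) and \code{reason} when
#'   no event is called.
#' @examples
#' t <- seq(0, 40, by = 0.2)
#' y <- c(rep(0.6, 100), seq(0.6, 0.2, length.out = 20),
#'        rep(0.2, length(t) - 120))
#' detectOnset(t, y, detectionParams(), "decrease")$onset  # t[101] = 20
#' @export
detectOnset <- function(time, value, params = detectionParams(),
                        direction = c("increase", "decrease", "any")) {
    direction <- match.arg(direction)
    stopifnot(is(params, "DetectionParams"))
    keep <- !is.na(value) & !is.na(time)
    time <- time[keep]; value <- value[keep]
    ms <- params@min_segment
    none <- function(reason) list(found = FALSE, onset = NA_real_,
                                  confidence = NA_real_, change = NA_real_,
                                  reason = reason)
    if (length(value) < 2L * ms)
        return(none("fewer than 2 * min_segment valid points"))

    if (direction == "increase") {
        w <- min(5L, length(value))
        sm <- stats::filter(value, rep(1 / w, w), sides = 2)
        sm[is.na(sm)] <- value[is.na(sm)]
        cut <- which.max(sm)
        if (cut >= 2L * ms) {
            time <- time[seq_len(cut)]
            value <- value[seq_len(cut)]
        }
    }

    n <- length(value)
    Sy <- cumsum(value); Sy2 <- cumsum(value^2)
    St <- cumsum(time); St2 <- cumsum(time^2); Sty <- cumsum(time * value)

    best <- list(rss = Inf, k1 = NA_integer_, k2 = NA_integer_)
    for (k1 in seq(ms, n - 2L)) {
        k2 <- seq(k1 + 2L, min(k1 + params@max_ramp, n))
        if (!length(k2)) next
        rss1 <- .const_rss(Sy, Sy2, 1L, k1)
        rss2 <- .line_rss(Sy, Sy2, St, St2, Sty, k1 + 1L, k2)
        rss3 <- ifelse(k2 >= n - 1L, 0,
                       .const_rss(Sy, Sy2, pmin(k2 + 1L, n), n))
        ## a one-point plateau has zero RSS
        rss3[k2 == n] <- 0
        tot <- rss1 + rss2 + rss3
        j <- which.min(tot)
        if (tot[j] < best$rss)
            best <- list(rss = tot[j], k1 = k1, k2 = k2[j])
    }
    if (!is.finite(best$rss))
        return(none("no admissible breakpoint"))

    k1 <- best$k1; k2 <- best$k2
    baseline <- .segsum(Sy, 1L, k1) / k1
    ## fitted ramp value at its last point
    a <- k1 + 1L
    nramp <- k2 - a + 1
    sy <- .segsum(Sy, a, k2); st <- .segsum(St, a, k2)
    sxx <- .segsum(St2, a, k2) - st^2 / nramp
    sxy <- .segsum(Sty, a, k2) - st * sy / nramp
    slope <- if (sxx > 1e-12) sxy / sxx else 0
    ramp_end <- sy / nramp + slope * (time[k2] - st / nramp)
    ## the post-ramp plateau is the most reliable measure of the change when
    ## it is long enough; otherwise use the fitted ramp endpoint
    change <- if (n - k2 >= params@min_segment)
        .segsum(Sy, k2 + 1L, n) / (n - k2) - baseline
    else ramp_end - baseline

    ok <- switch(direction,
                 increase = change >= params@onset_threshold,
                 decrease = change <= -params@onset_threshold,
                 any = abs(change) >= params@onset_threshold)
    if (!ok)
        return(none("fitted change below onset threshold"))
    rss0 <- .const_rss(Sy, Sy2, 1L, n)
    ## significance guard: the breakpoint model must beat a flat fit by more
    ## than the penalty times the point-noise variance
    sigma2 <- (stats::mad(diff(value)) / sqrt(2))^2
    if (rss0 - best$rss <= params@penalty * sigma2)
        return(none("change-point improvement below penalty"))
    ## date the onset where the fitted ramp crosses the baseline level; on a
    ## clean baseline-then-ramp series this is the first ramp timestamp
    onset <- time[k1 + 1L]
    if (abs(slope) > 1e-12) {
        t_cross <- st / nramp + (baseline - sy / nramp) / slope
        onset <- min(max(t_cross, time[max(k1 - 2L, 1L)]), time[k2])
    }
    list(found = TRUE, onset = onset,
         confidence = rss0 - best$rss, change = change, reason = NA_character_)
}

## recursive two-segment mean-shift scan; returns accepted downward steps.
## A step must exceed 5 robust noise SDs AND rel_thresh times the pre-step
## mean, so that small redistributions (e.g. FRET transitions perturbing a
## summed signal through unequal detection efficiencies) are not mistaken for
## photobleaching.
.find_down_steps <- function(time, y, min_seg = 5L, max_depth = 4L,
                             rel_thresh = 0.25) {
    sigma <- stats::mad(diff(y)) / sqrt(2)
    thr <- 5 * sigma + 1e-9
    steps <- list()
    recurse <- function(idx, depth) {
        n <- length(idx)
        if (n < 2L * min_seg || depth > max_depth) return()
        yy <- y[idx]
        Sy <- cumsum(yy); Sy2 <- cumsum(yy^2)
        ks <- seq(min_seg, n - min_seg)
        rss <- .const_rss(Sy, Sy2, 1L, ks) +
            vapply(ks, function(k) .const_rss(Sy, Sy2, k + 1L, n), numeric(1))
        k <- ks[which.min(rss)]
        m1 <- Sy[k] / k
        m2 <- (Sy[n] - Sy[k]) / (n - k)
        rss0 <- .const_rss(Sy, Sy2, 1L, n)
        if (rss0 - min(rss) <= n * sigma^2 * 0.5 + 1e-12) return()
        if (abs(m1 - m2) > max(thr, rel_thresh * abs(m1))) {
            if (m2 < m1)
                steps[[length(steps) + 1L]] <<-
                    list(t = time[idx[k + 1L]], size = m1 - m2)
            recurse(idx[seq_len(k)], depth + 1L)
            recurse(idx[seq(k + 1L, n)], depth + 1L)
        }
    }
    recurse(seq_along(y), 1L)
    if (!length(steps))
        return(data.frame(t = numeric(), size = numeric()))
    out <- do.call(rbind, lapply(steps, as.data.frame))
    out[order(out$t), , drop = FALSE]
}

#' Detect single-step photobleaching of each dye
#'
#' Detects downward intensity steps by recursive two-segment mean-shift fits.
#' Cy5 bleaching is detected on the summed Cy5-excited (638 nm) signal
#' \code{I_cy5 + I_a750}: that total is conserved under FRET transitions
#' (which only redistribute photons between the two channels, perturbing the
#' sum by at most the detection-efficiency mismatch) and collapses only when
#' Cy5 itself dies.  Cy3 bleaching is detected on the 532 nm Cy3 channel,
#' whose downward steps can only be bleach-caused (FRET changes move it
#' upward).  Alexa750 bleaching is detected on the 638 nm A750 channel, with
#' steps coincident with a Cy5 bleach attributed to Cy5; during an active
#' FRET transition the A750 channel genuinely falls, so an A750 "bleach" call
#' there is conservative (it merely truncates the entry-side validity
#' window).  A molecule with more than one downward step in the summed
#' Cy5-excited signal or the Cy3 channel -- the signature of a doubly
#' labelled nucleosome -- is not single-step and is excluded from lag
#' analysis (flag \code{multi_step_bleach}).
#'
#' @param traces a \linkS4class{TraceSet}.
#' @param molecule optional single molecule id; default all molecules.
#' @return A data.frame with columns molecule_id, bleach_cy3_s, bleach_cy5_s,
#'   bleach_a750_s (Inf if no bleach detected), single_step (logical; NA for
#'   traces shorter than 20 frames) and too_short.
#' @export
detectBleachSteps <- function(traces, molecule = NULL) {
    stopifnot(is(traces, "TraceSet"))
    df <- traces@data
    ids <- if (is.null(molecule)) unique(df$molecule_id) else molecule
    res <- lapply(ids, function(id) {
        m <- df[df$molecule_id == id, , drop = FALSE]
        if (nrow(m) < 20L)
            return(data.frame(molecule_id = id, bleach_cy3_s = Inf,
                              bleach_cy5_s = Inf, bleach_a750_s = Inf,
                              single_step = NA, too_short = TRUE))
        s532 <- m[m$excitation == 532L, ]
        s638 <- m[m$excitation == 638L, ]
        st_cy3 <- .find_down_steps(s532$time_s, s532$I_cy3)
        st_cy5 <- .find_down_steps(s638$time_s, s638$I_cy5 + s638$I_a750)
        st_a750 <- .find_down_steps(s638$time_s, s638$I_a750)
        if (nrow(st_a750) && nrow(st_cy5)) {
            coincident <- vapply(st_a750$t, function(tt)
                any(abs(st_cy5$t - tt) < 3 * traces@manifest@frame_interval *
                        traces@manifest@alternation_period * 2), logical(1))
            st_a750 <- st_a750[!coincident, , drop = FALSE]
        }
        first <- function(s) if (nrow(s)) s$t[1L] else Inf
        data.frame(molecule_id = id,
                   bleach_cy3_s = first(st_cy3),
                   bleach_cy5_s = first(st_cy5),
                   bleach_a750_s = first(st_a750),
                   single_step = nrow(st_cy3) <= 1L && nrow(st_cy5) <= 1L,
                   too_short = FALSE)
    })
    do.call(rbind, res)
}

#' Extract per-molecule remodelling events and lag times
#'
#' For each molecule: the entry onset is detected on the entry-side FRET
#' series (direction \code{increase}, since the entry-side FRET rises first),
#' the exit onset on the exit-side series restricted to times at or after the
#' entry onset (direction \code{decrease}), and the lag is their difference --
#' by construction never negative.  As a diagnostic against this ordering
#' prior, the exit onset is also detected without the constraint and the
#' fraction of molecules whose unconstrained exit onset precedes the entry
#' onset is attached as attribute \code{unconstrained_exit_before_entry} of
#' the returned table's data.  Molecules whose observation of the exit side
#' ends (bleach of Cy3 or Cy5, or end of trace) without an exit onset are
#' censored at that time; molecules flagged \code{multi_step_bleach} by the
#' bleach annotation are excluded from detection.
#'
#' @param fret a \linkS4class{FretTraceSet}.
#' @param params a \linkS4class{DetectionParams}.
#' @param bleach optional bleach annotation (data.frame from
#'   \code{\link{detectBleachSteps}} or an \linkS4class{EventTable}).
#' @return An \linkS4class{EventTable}; every molecule appears exactly once.
#' @export
extractEvents <- function(fret, params = detectionParams(), bleach = NULL) {
    stopifnot(is(fret, "FretTraceSet"))
    d <- fret@data
    ids <- unique(d$molecule_id)
    bl <- NULL
    if (!is.null(bleach))
        bl <- if (is(bleach, "EventTable")) bleach@data else as.data.frame(bleach)
    rows <- vector("list", length(ids))
    n_unconstrained_bad <- 0L
    n_unconstrained <- 0L
    for (i in seq_along(ids)) {
        id <- ids[i]
        m <- d[d$molecule_id == id, , drop = FALSE]
        b <- c(cy3 = Inf, cy5 = Inf, a750 = Inf)
        multi <- FALSE
        if (!is.null(bl)) {
            brow <- bl[bl$molecule_id == id, , drop = FALSE]
            if (nrow(brow)) {
                b <- c(cy3 = brow$bleach_cy3_s[1L], cy5 = brow$bleach_cy5_s[1L],
                       a750 = brow$bleach_a750_s[1L])
                b[is.na(b)] <- Inf
                if (!is.null(brow$single_step) &&
                    isFALSE(brow$single_step[1L])) multi <- TRUE
            }
        }
        mk <- function(t_entry, t_exit, t_censor, flag)
            data.frame(molecule_id = id, t_entry_s = t_entry, t_exit_s = t_exit,
                       t_lag_s = if (!is.na(t_entry) && !is.na(t_exit))
                           t_exit - t_entry else NA_real_,
                       bleach_cy3_s = b[["cy3"]], bleach_cy5_s = b[["cy5"]],
                       bleach_a750_s = b[["a750"]], t_censor_s = t_censor,
                       flag = flag)
        if (multi) {
            rows[[i]] <- mk(NA_real_, NA_real_, NA_real_, "multi_step_bleach")
            next
        }
        entry <- detectOnset(m$t638_s[m$valid_entry], m$E_entry[m$valid_entry],
                             params, "increase")
        exit_series_t <- m$t532_s[m$valid_exit]
        exit_series_y <- m$E_exit[m$valid_exit]
        if (!entry$found) {
            rows[[i]] <- mk(NA_real_, NA_real_, NA_real_, "no_event")
            next
        }
        sel <- exit_series_t >= entry$onset
        exit <- detectOnset(exit_series_t[sel], exit_series_y[sel],
                            params, "decrease")
        exit_unc <- detectOnset(exit_series_t, exit_series_y, params,
                                "decrease")
        if (exit_unc$found) {
            n_unconstrained <- n_unconstrained + 1L
            if (exit_unc$onset < entry$onset)
                n_unconstrained_bad <- n_unconstrained_bad + 1L
        }
        if (exit$found) {
            rows[[i]] <- mk(entry$onset, exit$onset, NA_real_, "complete")
        } else {
            t_obs_end <- if (length(exit_series_t)) max(exit_series_t) else
                entry$onset
            t_censor <- max(t_obs_end - entry$onset, 0)
            flag <- if (min(b[["cy3"]], b[["cy5"]]) <= t_obs_end +
                        2 * fret@manifest@frame_interval)
                "entry_only;censored_by_bleach" else "entry_only"
            rows[[i]] <- mk(entry$onset, NA_real_, t_censor, flag)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "unconstrained_exit_before_entry") <-
        if (n_unconstrained > 0L) n_unconstrained_bad / n_unconstrained else 0
    eventTable(out)
}
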