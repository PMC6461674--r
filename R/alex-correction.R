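## ALEX spectral corrections and FRET observables ------------------------------
##
## Correction order is fixed: direct excitation, then bleedthrough, then
## channel scaling.  The direct-excited-Cy5 population in a 532 nm frame
## behaves exactly like a 638 nm excitation scaled by d_cy5_532, so its
## signature is removed from BOTH the Cy5 and the A750 channel using the
## corrected 638 nm record of the same aligned time point; the 638 nm A750
## direct-excitation term is solved self-consistently.  With noiseless input
## this inverts the rendering model exactly (to machine precision).

#' Apply spectral corrections to aligned ALEX records
#'
#' Corrected intensities (g_a750 = 1/s_a750):
#' \preformatted{
#'   I638_cy5'  = I638_cy5
#'   I638_a750' = (I638_a750 - b_cy5_a750 * I638_cy5
#'                            - d_a750_638 * g_a750 * I638_cy5) / (1 + d_a750_638)
#'   I532_cy5'  = I532_cy5 - b_cy3_cy5 * I532_cy3 - d_cy5_532 * I638_cy5
#'   I532_a750' = I532_a750 - b_cy5_a750 * (I532_cy5' + d_cy5_532 * I638_cy5)
#'                          - d_cy5_532 * I638_a750'
#' }
#' followed by scaling of the Cy3 channel by \code{s_cy3} and of both A750
#' channels by \code{s_a750}.  Negative corrected intensities are permitted
#' and flagged in the \code{negative_corrected} column.
#'
#' @param aligned an \linkS4class{AlexSeries}.
#' @param params a \linkS4class{CorrectionParams}.
#' @return An \linkS4class{AlexSeries} with corrected, scaled intensities.
#' @seealso \code{\link{computeFret}}, \code{\link{estimateCorrections}}
#' @export
applyCorrections <- function(aligned, params) {
    stopifnot(is(aligned, "AlexSeries"), is(params, "CorrectionParams"))
    d <- aligned@data
    out <- .correct_record(d, params)
    new("AlexSeries", data = out, dropped = aligned@dropped,
        manifest = aligned@manifest)
}

## correction arithmetic on a data.frame holding the five raw channel columns;
## shared by applyCorrections and the bleach-step deltas in estimateCorrections
.correct_record <- function(d, params) {
    b1 <- params@b_cy3_cy5; b2 <- params@b_cy5_a750
    d1 <- params@d_cy5_532; d2 <- params@d_a750_638
    ga <- 1 / params@s_a750
    cy5_638 <- d$I638_cy5
    a750_638 <- (d$I638_a750 - b2 * cy5_638 - d2 * ga * cy5_638) / (1 + d2)
    cy5_532 <- d$I532_cy5 - b1 * d$I532_cy3 - d1 * cy5_638
    a750_532 <- d$I532_a750 - b2 * (cy5_532 + d1 * cy5_638) - d1 * a750_638
    out <- d
    out$I532_cy3 <- d$I532_cy3 * params@s_cy3
    out$I532_cy5 <- cy5_532
    out$I532_a750 <- a750_532 * params@s_a750
    out$I638_cy5 <- cy5_638
    out$I638_a750 <- a750_638 * params@s_a750
    out$negative_corrected <- out$I532_cy3 < 0 | cy5_532 < 0 |
        a750_532 < 0 | cy5_638 < 0 | a750_638 < 0
    out
}

#' Compute entry- and exit-side FRET observables
#'
#' From corrected, scaled intensities: the exit-side observable (all FRET
#' originating from Cy3 under 532 nm excitation)
#' \deqn{E_{exit} = 1 - I^{532}_{Cy3} / (I^{532}_{Cy3} + I^{532}_{Cy5} +
#'   I^{532}_{A750})}
#' and the entry-side observable (Cy5 to A750 transfer under 638 nm
#' excitation)
#' \deqn{E_{entry} = I^{638}_{A750} / (I^{638}_{Cy5} + I^{638}_{A750}).}
#' Records whose denominator falls below \code{denominator_floor} are marked
#' invalid (never dropped); when per-dye bleach times are supplied, records
#' after the bleach of a dye required by an observable are likewise marked
#' invalid (exit: Cy3 and Cy5; entry: Cy5 and A750).
#'
#' @param corrected an \linkS4class{AlexSeries} from
#'   \code{\link{applyCorrections}}.
#' @param bleach optional \linkS4class{EventTable} (or data.frame) with
#'   per-molecule \code{bleach_cy3_s}, \code{bleach_cy5_s}, \code{bleach_a750_s}.
#' @param denominator_floor minimum summed intensity for a defined FRET value;
#'   the default 3 * 5 * sqrt(3) corresponds to three times the read-noise SD
#'   of the default photophysics accumulated over three channels.
#' @return A \linkS4class{FretTraceSet}.
#' @examples
#' # (30, 50, 20) under 532 nm gives an exit-side FRET of 0.70
#' @export
computeFret <- function(corrected, bleach = NULL,
                        denominator_floor = 3 * 5 * sqrt(3)) {
    stopifnot(is(corrected, "AlexSeries"))
    d <- corrected@data
    den_exit <- d$I532_cy3 + d$I532_cy5 + d$I532_a750
    den_entry <- d$I638_cy5 + d$I638_a750
    E_exit <- ifelse(den_exit >= denominator_floor,
                     1 - d$I532_cy3 / den_exit, NA_real_)
    E_entry <- ifelse(den_entry >= denominator_floor,
                      d$I638_a750 / den_entry, NA_real_)
    valid_exit <- !is.na(E_exit)
    valid_entry <- !is.na(E_entry)
    if (!is.null(bleach)) {
        bl <- if (is(bleach, "EventTable")) bleach@data else as.data.frame(bleach)
        idx <- match(d$molecule_id, bl$molecule_id)
        b3 <- bl$bleach_cy3_s[idx]; b5 <- bl$bleach_cy5_s[idx]
        b7 <- bl$bleach_a750_s[idx]
        b3[is.na(b3)] <- Inf; b5[is.na(b5)] <- Inf; b7[is.na(b7)] <- Inf
        valid_exit <- valid_exit & d$t532_s < b3 & d$t532_s < b5
        valid_entry <- valid_entry & d$t638_s < b5 & d$t638_s < b7
    }
    ## clamp pathological excursions into invalidity rather than failing
    valid_exit <- valid_exit & !is.na(E_exit) & E_exit >= -0.2 & E_exit <= 1.2
    valid_entry <- valid_entry & !is.na(E_entry) & E_entry >= -0.2 & E_entry <= 1.2
    out <- data.frame(molecule_id = d$molecule_id, time_s = d$time_s,
                      t532_s = d$t532_s, t638_s = d$t638_s,
                      E_exit = E_exit, E_entry = E_entry,
                      valid_exit = valid_exit, valid_entry = valid_entry,
                      I532_cy3 = d$I532_cy3, I532_cy5 = d$I532_cy5,
                      I532_a750 = d$I532_a750, I638_cy5 = d$I638_cy5,
                      I638_a750 = d$I638_a750)
    new("FretTraceSet", data = out, manifest = corrected@manifest)
}

#' Estimate correction parameters from photobleaching segments
#'
#' Standard ALEX practice: each crosstalk coefficient is identified from trace
#' segments in which a subset of dyes has photobleached.
#' \itemize{
#'   \item \code{b_cy3_cy5}: mean of I532_cy5 / I532_cy3 where Cy5 and A750
#'     are bleached (Cy3 emission only);
#'   \item \code{b_cy5_a750}: mean of I638_a750 / I638_cy5 where A750 is
#'     bleached and Cy5 alive;
#'   \item \code{d_cy5_532}: mean of I532_cy5 / I638_cy5 where Cy3 is bleached
#'     and Cy5 alive;
#'   \item \code{s_a750}: across A750 bleach steps (Cy3 and Cy5 alive), the
#'     A750-channel loss divided by the Cy5-channel gain identifies
#'     g_a750 - b_cy5_a750;
#'   \item \code{s_cy3}: across Cy5 bleach steps (Cy3 alive), the Cy3-channel
#'     gain divided by the Cy5-equivalent loss of the corrected Cy5 + A750
#'     channels identifies g_cy3;
#'   \item \code{d_a750_638}: mean I638_a750 over A750-only segments divided
#'     by g_a750 times the Cy5-excitation budget estimated from
#'     A750-bleached segments.
#' }
#' Parameters without qualifying segments keep the value supplied in
#' \code{prior} and are flagged as not estimated.
#'
#' @param traces a \linkS4class{TraceSet}.
#' @param bleach_annotations an \linkS4class{EventTable} (or data.frame) with
#'   per-dye bleach times (e.g. from \code{\link{detectBleachSteps}} or the
#'   generator ground truth).
#' @param prior a \linkS4class{CorrectionParams} supplying defaults for
#'   parameters that cannot be estimated.
#' @param margin_s seconds excluded on both sides of every bleach step.
#' @return A \linkS4class{CorrectionParams} with \code{estimated} flags and
#'   per-parameter segment counts.
#' @export
estimateCorrections <- function(traces, bleach_annotations,
                                prior = correctionParams(),
                                margin_s = 1) {
    stopifnot(is(traces, "TraceSet"))
    bl <- if (is(bleach_annotations, "EventTable")) bleach_annotations@data
          else as.data.frame(bleach_annotations)
    for (col in c("bleach_cy3_s", "bleach_cy5_s", "bleach_a750_s"))
        bl[[col]][is.na(bl[[col]])] <- Inf
    df <- traces@data
    ids <- intersect(unique(df$molecule_id), bl$molecule_id)

    est <- list(b_cy3_cy5 = numeric(), b_cy5_a750 = numeric(),
                d_cy5_532 = numeric(), d_a750_638 = numeric(),
                s_cy3 = numeric(), s_a750 = numeric())
    n638_ref <- numeric()       # Cy5-excitation budget from A750-dark segments
    a750_only <- numeric()      # raw I638_a750 in A750-only segments
    scy3_pending <- list()      # deferred: needs g_a750 and fractions first

    seg_means <- function(m, from, to) {
        sel <- m$time_s >= from & m$time_s < to
        if (sum(sel & m$excitation == 532L) < 3L ||
            sum(sel & m$excitation == 638L) < 3L) return(NULL)
        s5 <- m[sel & m$excitation == 532L, ]
        s6 <- m[sel & m$excitation == 638L, ]
        data.frame(I532_cy3 = mean(s5$I_cy3), I532_cy5 = mean(s5$I_cy5),
                   I532_a750 = mean(s5$I_a750), I638_cy5 = mean(s6$I_cy5),
                   I638_a750 = mean(s6$I_a750))
    }

    for (id in ids) {
        m <- df[df$molecule_id == id, , drop = FALSE]
        b <- bl[bl$molecule_id == id, , drop = FALSE][1L, ]
        t_end <- max(m$time_s)
        b3 <- b$bleach_cy3_s; b5 <- b$bleach_cy5_s; b7 <- b$bleach_a750_s

        ## Cy3-only: Cy5 and A750 bleached
        from <- max(b5, b7) + margin_s
        to <- min(b3, t_end)
        if (to - from > margin_s) {
            s <- seg_means(m, from, to)
            if (!is.null(s) && s$I532_cy3 > 0)
                est$b_cy3_cy5 <- c(est$b_cy3_cy5, s$I532_cy5 / s$I532_cy3)
        }
        ## A750 bleached, Cy5 alive
        from <- b7 + margin_s
        to <- min(b5, t_end)
        if (to - from > margin_s) {
            s <- seg_means(m, from, to)
            if (!is.null(s) && s$I638_cy5 > 0) {
                est$b_cy5_a750 <- c(est$b_cy5_a750, s$I638_a750 / s$I638_cy5)
                n638_ref <- c(n638_ref, s$I638_cy5)
            }
        }
        ## Cy3 bleached, Cy5 alive
        from <- b3 + margin_s
        to <- min(b5, t_end)
        if (to - from > margin_s) {
            s <- seg_means(m, from, to)
            if (!is.null(s) && s$I638_cy5 > 0)
                est$d_cy5_532 <- c(est$d_cy5_532, s$I532_cy5 / s$I638_cy5)
        }
        ## A750 only: Cy3 and Cy5 bleached
        from <- max(b3, b5) + margin_s
        to <- min(b7, t_end)
        if (to - from > margin_s) {
            s <- seg_means(m, from, to)
            if (!is.null(s))
                a750_only <- c(a750_only, s$I638_a750)
        }
        ## scale factors from intensity matching across a bleach step
        win <- 5 * margin_s
        if (is.finite(b7) && b7 < min(b3, b5, t_end) - margin_s) {
            before <- seg_means(m, max(0, b7 - margin_s - win), b7 - margin_s)
            after <- seg_means(m, b7 + margin_s,
                               min(b7 + margin_s + win, b3, b5, t_end))
            if (!is.null(before) && !is.null(after)) {
                dcy5 <- after$I532_cy5 - before$I532_cy5
                da750 <- after$I532_a750 - before$I532_a750
                if (dcy5 > 0)
                    est$s_a750 <- c(est$s_a750, -da750 / dcy5)  # g_a - b2
            }
        }
        if (is.finite(b5) && b5 < min(b3, t_end) - margin_s) {
            before <- seg_means(m, max(0, b5 - margin_s - win), b5 - margin_s)
            after <- seg_means(m, b5 + margin_s,
                               min(b5 + margin_s + win, b3, t_end))
            if (!is.null(before) && !is.null(after))
                scy3_pending[[length(scy3_pending) + 1L]] <-
                    list(before = before, after = after)
        }
    }

    clamp01 <- function(x) min(max(x, 0), 1 - 1e-9)
    take <- function(name, prior_val, transform = identity) {
        if (length(est[[name]]) > 0L)
            list(value = transform(mean(est[[name]])), estimated = TRUE,
                 n = length(est[[name]]))
        else list(value = prior_val, estimated = FALSE, n = 0L)
    }
    b1 <- take("b_cy3_cy5", prior@b_cy3_cy5, clamp01)
    b2 <- take("b_cy5_a750", prior@b_cy5_a750, clamp01)
    d1 <- take("d_cy5_532", prior@d_cy5_532, clamp01)
    ## s_a750: segment estimates identify g_a750 - b_cy5_a750
    sa <- take("s_a750", prior@s_a750,
               transform = function(x) max(1 / (x + b2$value), 1e-9))
    ga <- 1 / sa$value

    ## s_cy3 from Cy5 bleach steps: correct the before/after means with the
    ## fractions (and g_a750) obtained above, then
    ## g_cy3 = delta(I532_cy3) / (-delta(I532_cy5') - delta(I532_a750')/g_a750)
    pars_nofret <- correctionParams(d_cy5_532 = d1$value,
                                    d_a750_638 = prior@d_a750_638,
                                    b_cy3_cy5 = b1$value,
                                    b_cy5_a750 = b2$value,
                                    s_cy3 = 1, s_a750 = sa$value)
    for (pend in scy3_pending) {
        cb <- .correct_record(pend$before, pars_nofret)
        ca <- .correct_record(pend$after, pars_nofret)
        ## with s_a750 applied by .correct_record, the corrected A750 channel
        ## is already in Cy5-equivalent units
        dcy3 <- ca$I532_cy3 - cb$I532_cy3
        drop5eq <- -(ca$I532_cy5 - cb$I532_cy5) -
            (ca$I532_a750 - cb$I532_a750)
        if (drop5eq > 0 && dcy3 > 0)
            est$s_cy3 <- c(est$s_cy3, dcy3 / drop5eq)
    }
    s3 <- take("s_cy3", prior@s_cy3, transform = function(x) 1 / x)

    ## d_a750_638 needs the excitation budget N (from A750-dark segments)
    d2 <- list(value = prior@d_a750_638, estimated = FALSE, n = 0L)
    if (length(a750_only) > 0L && length(n638_ref) > 0L && sa$estimated) {
        d2 <- list(value = mean(a750_only) / (ga * mean(n638_ref)),
                   estimated = TRUE, n = length(a750_only))
    }

    correctionParams(
        d_cy5_532 = clamp01(d1$value), d_a750_638 = clamp01(d2$value),
        b_cy3_cy5 = clamp01(b1$value), b_cy5_a750 = clamp01(b2$value),
        s_cy3 = max(s3$value, 1e-9), s_a750 = max(sa$value, 1e-9),
        estimated = c(d_cy5_532 = d1$estimated, d_a750_638 = d2$estimated,
                      b_cy3_cy5 = b1$estimated, b_cy5_a750 = b2$estimated,
                      s_cy3 = s3$estimated, s_a750 = sa$estimated),
        n_segments = c(d_cy5_532 = d1$n, d_a750_638 = d2$n,
                       b_cy3_cy5 = b1$n, b_cy5_a750 = b2$n,
                       s_cy3 = s3$n, s_a750 = sa$n))
}

#' Read/write correction parameters as flat key-value text
#'
#' @param path file path.
#' @return \code{readCorrectionParams} returns a
#'   \linkS4class{CorrectionParams}; \code{writeCorrectionParams} returns
#'   \code{path} invisibly.
#' @name correction-io
NULL

#' @rdname correction-io
#' @export
readCorrectionParams <- function(path) {
    if (!file.exists(path))
        stop("correction parameter file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    kv <- strsplit(lines, "[\t=]")
    keys <- vapply(kv, function(x) trimws(x[[1L]]), character(1))
    vals <- as.numeric(vapply(kv, function(x) trimws(x[[2L]]), character(1)))
    get <- function(key, default) if (key %in% keys) vals[[match(key, keys)]] else default
    correctionParams(d_cy5_532 = get("d_cy5_532", 0),
                     d_a750_638 = get("d_a750_638", 0),
                     b_cy3_cy5 = get("b_cy3_cy5", 0),
                     b_cy5_a750 = get("b_cy5_a750", 0),
                     s_cy3 = get("s_cy3", 1), s_a750 = get("s_a750", 1))
}

#' @rdname correction-io
#' @param params a \linkS4class{CorrectionParams}.
#' @export
writeCorrectionParams <- function(params, path) {
    stopifnot(is(params, "CorrectionParams"))
    lines <- c(paste0("d_cy5_532\t", format(params@d_cy5_532, digits = 15)),
               paste0("d_a750_638\t", format(params@d_a750_638, digits = 15)),
               paste0("b_cy3_cy5\t", format(params@b_cy3_cy5, digits = 15)),
               paste0("b_cy5_a750\t", format(params@b_cy5_a750, digits = 15)),
               paste0("s_cy3\t", format(params@s_cy3, digits = 15)),
               paste0("s_a750\t", format(params@s_a750, digits = 15)))
    writeLines(lines, path)
    invisible(path)
}
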