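## Trace and manifest I/O ------------------------------------------------------
##
## Traces travel as plain TSV (one row per molecule-frame, columns in the fixed
## order molecule_id, frame, time_s, excitation, I_cy3, I_cy5, I_a750); the
## manifest as a flat key-value text file with keys frame_interval_s,
## alternation_period, atp_uM, remodeller, seed.  Both formats are diffable and
## round-trip exactly (integers bit-exact, intensities to better than 1e-9
## relative via %.12g formatting).

#' Read an experiment manifest
#'
#' @param path path to a flat key-value manifest file (\code{key<TAB>value}).
#' @return A \linkS4class{Manifest}.
#' @seealso \code{\link{writeManifest}}
#' @export
readManifest <- function(path) {
    if (!file.exists(path))
        stop("manifest file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    kv <- strsplit(lines, "[\t=]")
    keys <- vapply(kv, function(x) trimws(x[[1L]]), character(1))
    vals <- vapply(kv, function(x) trimws(paste(x[-1L], collapse = " ")),
                   character(1))
    get <- function(key, default) if (key %in% keys) vals[[match(key, keys)]] else default
    manifest(frame_interval = as.numeric(get("frame_interval_s", "0.1")),
             alternation_period = as.integer(get("alternation_period", "1")),
             atp_uM = as.numeric(get("atp_uM", "500")),
             remodeller = get("remodeller", "unknown"),
             seed = suppressWarnings(as.integer(get("seed", NA))))
}

#' Write an experiment manifest
#'
#' @param man a \linkS4class{Manifest}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeManifest <- function(man, path) {
    stopifnot(is(man, "Manifest"))
    lines <- c(paste0("frame_interval_s\t", format(man@frame_interval, digits = 15)),
               paste0("alternation_period\t", man@alternation_period),
               paste0("atp_uM\t", format(man@atp_uM, digits = 15)),
               paste0("remodeller\t", man@remodeller))
    if (!is.na(man@seed))
        lines <- c(lines, paste0("seed\t", man@seed))
    writeLines(lines, path)
    invisible(path)
}

#' Read a three-channel ALEX trace table
#'
#' Reads a TSV trace table plus its manifest and returns a validated
#' \linkS4class{TraceSet}.  Validation checks the column contract, strictly
#' increasing frames per molecule, the manifest frame interval (within 1e-6 s)
#' and the alternating excitation pattern, and names the offending column,
#' molecule or frame in its error message.
#'
#' @param path path to the trace TSV.
#' @param manifest_path path to the manifest file.
#' @return A \linkS4class{TraceSet}.
#' @seealso \code{\link{writeTraces}}, \code{\link{pairAlexFrames}}
#' @export
readTraces <- function(path, manifest_path) {
    if (!file.exists(path))
        stop("trace file not found: ", path)
    man <- readManifest(manifest_path)
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    missing_cols <- setdiff(.TRACE_COLUMNS, names(df))
    if (length(missing_cols))
        stop("format error: missing column(s): ",
             paste(missing_cols, collapse = ", "))
    traceSet(df, man)
}

#' Write a TraceSet to TSV
#'
#' @param traces a \linkS4class{TraceSet}.
#' @param path output TSV path.
#' @param manifest_path optional path to also write the manifest.
#' @return \code{path}, invisibly.
#' @export
writeTraces <- function(traces, path, manifest_path = NULL) {
    stopifnot(is(traces, "TraceSet"))
    df <- traces@data
    out <- data.frame(molecule_id = df$molecule_id,
                      frame = df$frame,
                      time_s = sprintf("%.12g", df$time_s),
                      excitation = df$excitation,
                      I_cy3 = sprintf("%.12g", df$I_cy3),
                      I_cy5 = sprintf("%.12g", df$I_cy5),
                      I_a750 = sprintf("%.12g", df$I_a750))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(manifest_path))
        writeManifest(traces@manifest, manifest_path)
    invisible(path)
}

#' Pair alternating-excitation frames into aligned ALEX records
#'
#' Groups the frames of each molecule into excitation blocks of
#' \code{alternation_period} frames, averages intensities within each block,
#' and pairs each 532 nm block with the nearest-in-time 638 nm block (the
#' adjacent one, given strict alternation).  The aligned record carries the
#' midpoint of the two block timestamps.  Unpaired trailing blocks are dropped
#' and counted; molecules with fewer than 2 frames are skipped with a warning.
#'
#' @param traces a \linkS4class{TraceSet}.
#' @param man the acquisition \linkS4class{Manifest}; defaults to the one
#'   carried by \code{traces}.
#' @return An \linkS4class{AlexSeries}.
#' @examples
#' ts <- renderTraces(sampleKinetics(kineticConfig(n_molecules = 2, seed = 1)),
#'                    photoConfig(read_noise = 0, shot_noise = FALSE))
#' pairAlexFrames(ts)
#' @export
pairAlexFrames <- function(traces, man = traceManifest(traces)) {
    stopifnot(is(traces, "TraceSet"))
    df <- traces@data
    p <- man@alternation_period
    ids <- unique(df$molecule_id)
    pieces <- vector("list", length(ids))
    dropped <- stats::setNames(integer(length(ids)), as.character(ids))
    skipped <- 0L
    for (i in seq_along(ids)) {
        m <- df[df$molecule_id == ids[i], , drop = FALSE]
        if (nrow(m) < 2L) {
            skipped <- skipped + 1L
            dropped[i] <- nrow(m)
            next
        }
        block <- factor(m$frame %/% p, levels = unique(m$frame %/% p))
        agg <- function(v) as.numeric(tapply(v, block, mean))
        bt <- agg(m$time_s)
        bex <- as.integer(tapply(m$excitation, block, function(x) x[1L]))
        i532 <- which(bex == 532L)
        i638 <- which(bex == 638L)
        n <- min(length(i532), length(i638))
        dropped[i] <- (length(i532) - n) * p + (length(i638) - n) * p
        if (n == 0L) next
        i532 <- i532[seq_len(n)]
        i638 <- i638[seq_len(n)]
        cy3 <- agg(m$I_cy3); cy5 <- agg(m$I_cy5); a750 <- agg(m$I_a750)
        pieces[[i]] <- data.frame(
            molecule_id = ids[i],
            time_s = (bt[i532] + bt[i638]) / 2,
            t532_s = bt[i532], t638_s = bt[i638],
            I532_cy3 = cy3[i532], I532_cy5 = cy5[i532],
            I532_a750 = a750[i532],
            I638_cy5 = cy5[i638], I638_a750 = a750[i638])
    }
    if (skipped > 0L)
        warning(skipped, " molecule(s) with fewer than 2 frames skipped")
    out <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
    if (is.null(out))
        out <- data.frame(molecule_id = integer(), time_s = numeric(),
                          t532_s = numeric(), t638_s = numeric(),
                          I532_cy3 = numeric(), I532_cy5 = numeric(),
                          I532_a750 = numeric(), I638_cy5 = numeric(),
                          I638_a750 = numeric())
    rownames(out) <- NULL
    new("AlexSeries", data = out, dropped = dropped, manifest = man)
}
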