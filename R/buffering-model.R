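## Discrete DNA-buffering (twist-defect) model ---------------------------------
##
## The remodeller ATPase at the entry-side SHL2 injects DNA in 1-bp steps.
## Between the entry SHL2 and the exit side, segments of nucleosomal DNA can
## absorb base pairs as local twist defects: up to capacity_entry_dyad bp
## between the entry SHL2 and the dyad probe and up to capacity_dyad_exit bp
## between dyad and exit probe.  A single-stranded gap m bp ahead of the
## stall site limits total injection to m bp.  Only the excess over the
## buffer capacities propagates to the exit side, so probe shifts decrease
## from entry to exit.

#' Deterministic probe shifts under the gap rule
#'
#' With gap offset \code{m}: total DNA moved past the entry probe is
#' \code{m + initial_defect} bp; the entry-dyad buffer absorbs up to its
#' capacity, the remainder shifts the dyad probe; the dyad-exit buffer absorbs
#' up to its capacity, the remainder shifts the exit probe (order-of-passage
#' filling, upstream buffer first).
#'
#' @param cfg a \linkS4class{BufferModelConfig} with finite \code{gap_offset}.
#' @return A \linkS4class{ProbeShifts}.
#' @examples
#' # m = 8 with the default capacities gives entry/dyad/exit = 9/7/4 bp
#' deterministicShifts(bufferModelConfig(gap_offset = 8))
#' @export
deterministicShifts <- function(cfg) {
    stopifnot(is(cfg, "BufferModelConfig"))
    if (is.infinite(cfg@gap_offset))
        stop("gap_offset is infinite (ungapped nucleosome): ",
             "use simulateCtmc for unconstrained sliding")
    m <- as.integer(cfg@gap_offset)
    entry <- m + cfg@initial_defect
    absorbed1 <- min(cfg@capacity_entry_dyad, entry)
    dyad <- entry - absorbed1
    absorbed2 <- min(cfg@capacity_dyad_exit, dyad)
    exit <- dyad - absorbed2
    new("ProbeShifts", entry_shift = entry, dyad_shift = dyad,
        exit_shift = exit, absorbed_entry_dyad = absorbed1,
        absorbed_dyad_exit = absorbed2)
}

#' Stochastic twist-defect kinetics (continuous-time Markov chain)
#'
#' State: cumulative injections j, buffer occupancies b_i, exit count.
#' Transitions: an injection (rate \code{k_inj}) adds one bp to the first
#' buffer while \code{j < m}; each buffer holding more bp than its capacity
#' passes one bp downstream at rate \code{k_relax}; a bp passing the last
#' buffer increments the exit shift.  The first injection marks the first
#' entry-probe movement, the first bp beyond the last buffer the first
#' exit-probe movement; the lag is their difference.  At long times the
#' buffers retain exactly their capacities (stable twist defects) and the
#' final shifts agree with \code{\link{deterministicShifts}}.  The two
#' mechanistic scenarios -- threshold-triggered transfer versus spontaneous
#' defect collapse -- correspond to \code{k_relax >> k_inj} and
#' \code{k_relax << k_inj} respectively.
#'
#' @param cfg a \linkS4class{BufferModelConfig}.
#' @param t_max simulation horizon (s).
#' @param seed RNG seed; defaults to the config seed.
#' @param capacities optional integer vector of buffer capacities overriding
#'   \code{c(capacity_entry_dyad, capacity_dyad_exit)}; a single-element
#'   vector gives a one-stage model.
#' @return A list with \code{events} (data.frame of time and type),
#'   \code{t_entry} (first injection), \code{t_exit} (first exit movement,
#'   NA if censored), \code{lag}, \code{censored} (logical), and the final
#'   \code{entry_shift}, \code{buffers}, \code{exit_shift}.
#' @export
simulateCtmc <- function(cfg, t_max = Inf, seed = cfg@seed,
                         capacities = NULL) {
    stopifnot(is(cfg, "BufferModelConfig"))
    if (is.infinite(cfg@gap_offset) && is.infinite(t_max))
        stop("an ungapped nucleosome (gap_offset = Inf) never stops ",
             "injecting; supply a finite t_max")
    if (!is.null(seed)) set.seed(seed)
    .simulate_ctmc_once(cfg, t_max, capacities)
}

.simulate_ctmc_once <- function(cfg, t_max, capacities = NULL,
                                stop_at_first_exit = FALSE) {
    caps <- if (is.null(capacities))
        c(cfg@capacity_entry_dyad, cfg@capacity_dyad_exit)
    else as.integer(capacities)
    ns <- length(caps)
    m <- cfg@gap_offset
    b <- integer(ns)
    b[1L] <- cfg@initial_defect
    j <- 0L; exit_n <- 0L
    t <- 0
    t_entry <- NA_real_; t_exit <- NA_real_
    times <- numeric(0); types <- character(0)
    if (is.finite(m) && cfg@initial_defect + m <= sum(caps) &&
        is.infinite(t_max))
        stop("no exit movement is possible: m + initial_defect <= total ",
             "buffer capacity; supply a finite t_max")
    repeat {
        rate_inj <- if (j < m &&
                        (cfg@exit_propagation || any(b <= caps)))
            cfg@k_inj else 0
        excess <- b > caps
        if (!cfg@exit_propagation) excess[ns] <- FALSE
        rates <- c(rate_inj, ifelse(excess, cfg@k_relax, 0))
        total <- sum(rates)
        if (total <= 0) break
        t <- t + stats::rexp(1L, total)
        if (t > t_max) { t <- t_max; break }
        ev <- sample.int(length(rates), 1L, prob = rates)
        if (ev == 1L) {
            j <- j + 1L
            b[1L] <- b[1L] + 1L
            if (is.na(t_entry)) t_entry <- t
            times <- c(times, t); types <- c(types, "injection")
        } else {
            i <- ev - 1L
            b[i] <- b[i] - 1L
            if (i < ns) {
                b[i + 1L] <- b[i + 1L] + 1L
                times <- c(times, t); types <- c(types, "relaxation")
            } else {
                exit_n <- exit_n + 1L
                if (is.na(t_exit)) t_exit <- t
                times <- c(times, t); types <- c(types, "exit")
                if (stop_at_first_exit) break
            }
        }
    }
    censored <- is.na(t_exit)
    list(events = data.frame(time = times, type = types),
         t_entry = t_entry, t_exit = t_exit,
         lag = if (censored || is.na(t_entry)) NA_real_ else t_exit - t_entry,
         censored = censored,
         entry_shift = j + cfg@initial_defect,
         buffers = b, exit_shift = exit_n)
}

#' Sample lag times from the buffering model
#'
#' Runs \code{n} independent stochastic trajectories and returns their lag
#' times (first exit movement minus first entry movement); trajectories
#' censored at \code{t_max} are discarded with a warning.  The output is
#' suitable for \code{\link{fitExponential}}.
#'
#' @param cfg a \linkS4class{BufferModelConfig}.
#' @param n number of lag times (>= 1).
#' @param t_max per-trajectory horizon (s).
#' @param seed RNG seed; defaults to the config seed.
#' @param capacities optional capacity override (see \code{\link{simulateCtmc}}).
#' @return Numeric vector of lag times (s).
#' @export
lagDistributionFromModel <- function(cfg, n, t_max = Inf, seed = cfg@seed,
                                     capacities = NULL) {
    stopifnot(is(cfg, "BufferModelConfig"))
    if (length(n) != 1L || is.na(n) || n < 1L)
        stop("n must be >= 1")
    caps <- if (is.null(capacities))
        c(cfg@capacity_entry_dyad, cfg@capacity_dyad_exit)
    else as.integer(capacities)
    if (is.finite(cfg@gap_offset) &&
        cfg@initial_defect + cfg@gap_offset <= sum(caps))
        stop("no exit movement is possible with this configuration: ",
             "m + initial_defect <= total buffer capacity")
    if (!cfg@exit_propagation)
        stop("lag times require exit propagation (exit_propagation = TRUE)")
    if (!is.null(seed)) set.seed(seed)
    lags <- numeric(n)
    n_censored <- 0L
    for (i in seq_len(n)) {
        tr <- .simulate_ctmc_once(cfg, t_max, capacities,
                                  stop_at_first_exit = TRUE)
        if (tr$censored) {
            n_censored <- n_censored + 1L
            lags[i] <- NA_real_
        } else lags[i] <- tr$lag
    }
    if (n_censored > 0L)
        warning(n_censored, " censored trajectory(ies) discarded")
    lags[!is.na(lags)]
}
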