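## Fixture builders shared across the test files -------------------------------

## a small hand-built trace table with strict 532/638 alternation
make_trace_df <- function(n_mol = 2L, n_frames = 10L, dt = 0.1,
                          intensities = NULL) {
    rows <- lapply(seq_len(n_mol) - 1L, function(id) {
        frame <- seq_len(n_frames) - 1L
        data.frame(molecule_id = id, frame = frame, time_s = frame * dt,
                   excitation = ifelse(frame %% 2L == 0L, 532L, 638L),
                   I_cy3 = if (is.null(intensities)) 100 + frame + id else
                       intensities[1L],
                   I_cy5 = if (is.null(intensities)) 200 - frame else
                       intensities[2L],
                   I_a750 = if (is.null(intensities)) 50 + 0.5 * frame else
                       intensities[3L])
    })
    do.call(rbind, rows)
}

## a TimelineSet of constant-FRET molecules (entry onset far beyond the trace)
## with prescribed per-dye bleach times; used to probe corrections and
## bleach-step handling without remodelling events
make_static_timelines <- function(bleach_cy3 = Inf, bleach_cy5 = Inf,
                                  bleach_a750 = Inf, n = NULL,
                                  duration = 60, seed = 1L) {
    n <- if (is.null(n)) max(length(bleach_cy3), length(bleach_cy5),
                             length(bleach_a750)) else n
    cfg <- kineticConfig(n_molecules = n, duration = duration, seed = seed)
    d <- data.frame(molecule_id = seq_len(n) - 1L,
                    t_entry_onset = 1e6, t_lag = 1, t_exit_onset = 1e6 + 1,
                    bleach_cy3 = rep_len(bleach_cy3, n),
                    bleach_cy5 = rep_len(bleach_cy5, n),
                    bleach_a750 = rep_len(bleach_a750, n))
    new("TimelineSet", data = d, config = cfg)
}

## exact inverse correction parameters of the default photophysics
default_inverse_params <- function(photo = photoConfig())
    correctionParamsFromPhoto(photo)

noiseless_photo <- function(...) photoConfig(read_noise = 0,
                                             shot_noise = FALSE, ...)
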