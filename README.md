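# slideFRET

Three-colour ALEX smFRET analysis of nucleosome sliding kinetics.

## The scientific problem

Chromatin remodellers (Chd1, SNF2h/ISWI) slide nucleosomes by translocating
DNA at an internal site of the nucleosome, but how DNA propagates around the
histone core is not directly visible to a single FRET pair.  A three-colour
design labels the exit-side DNA with Cy3, the entry-side DNA with Alexa750
and the histone core with Cy5, so that alternating 532/638 nm laser
excitation (ALEX) reports both sides of the same nucleosome simultaneously:

```
E_exit  = 1 - I532_cy3 / (I532_cy3 + I532_cy5 + I532_a750)   (532 nm frames)
E_entry =     I638_a750 / (I638_cy5 + I638_a750)             (638 nm frames)
```

after correction for direct excitation, spectral bleedthrough and
detection-efficiency scaling.  During remodelling, entry-side FRET changes
*before* exit-side FRET; the lag `t_lag` between the two onsets is
single-exponentially distributed with a rate that rises hyperbolically with
ATP (`1/tau = k_max * [ATP] / (K_app + [ATP])`), implicating one
rate-limiting ATP-binding step and transient buffering of one to a few base
pairs of DNA on the nucleosome as local twist defects.

The package is aimed at single-molecule biophysicists who need a tested,
reproducible version of this analysis: trace I/O and validation, ALEX
crosstalk corrections, change-point detection of photobleaching steps and
FRET-change onsets, censoring-aware exponential lag fits, Michaelis-Menten
ATP-dependence fits, a synthetic trace generator for end-to-end validation,
and a discrete DNA-buffering model (deterministic gap-rule arithmetic plus a
stochastic twist-defect simulator).

## Worked example

Simulate a Chd1 experiment at 500 uM ATP (60 molecules, 120 s traces),
run the full analysis chain, and fit the lag distribution:

```r
library(slideFRET)

cfg <- kineticConfig(atp_uM = 500, n_molecules = 60, duration = 120,
                     seed = 42)
sim <- simulateDataset(cfg)
sim$traces
#> TraceSet with 60 molecule(s), 72000 frames total
#> Manifest: frame_interval = 0.1 s, alternation_period = 1 frame(s),
#>   ATP = 500 uM, remodeller = Chd1 , seed = 42

res <- analyzeTraces(sim$traces, correctionParamsFromPhoto(photoConfig()))
res$events
#> EventTable with 60 molecule(s)
#>    complete : 58
#>    no_event : 2

lt <- lagTimes(res$events)
fitExponential(lt$lags, lt$censored, method = "mle_censored")
#> ExpFit (mle_censored): mean lag 4.85 +/- 0.75 s (N = 58 events),
#>   KS D = 0.0901, p = 0.701
```

The generator's default mean lag is 4.9 s (its `k_max` is chosen so that
`(K_app + 500)/(k_max * 500) = 4.9` with `K_app = 60` uM); the fit recovers
4.85 +/- 0.75 s from the rendered noisy traces, and the KS test is
consistent with a single exponential.  Two molecules photobleached before
any detectable transition and are flagged rather than silently dropped.

The buffering model's worked example — a nucleosome with a single-stranded
gap 8 bp beyond the stall site, an initial 1 bp twist defect and buffer
capacities of 2 bp (entry-to-dyad) and 3 bp (dyad-to-exit):

```r
deterministicShifts(bufferModelConfig(gap_offset = 8))
#> ProbeShifts: entry 9, dyad 7, exit 4 bp (absorbed 2 + 3 bp)
```

The probes shift by 9, 7 and 4 bp: the 5 bp held as twist defects between
the probes are exactly what makes the DNA movement discontinuous.

See `vignettes/three-colour-fret-lag-kinetics.Rmd` for the models, the
parameter defaults and their rationale, and known limitations.

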