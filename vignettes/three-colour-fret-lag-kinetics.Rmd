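---
title: "Three-colour ALEX smFRET analysis of nucleosome sliding: models and methods"
author: "slideFRET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-colour ALEX smFRET analysis of nucleosome sliding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slideFRET)
```

# The experiment this package models

ATP-dependent chromatin remodellers such as Chd1 and SNF2h reposition
nucleosomes by translocating DNA at an internal site (SHL2) of the
nucleosome.  A three-colour single-molecule FRET design places Cy3 on the
exit-side DNA, Alexa750 on the entry-side DNA and Cy5 on the histone core,
giving two FRET pairs that share the central Cy5.  Alternating 532 nm and
638 nm laser excitation (ALEX) disentangles the two pairs frame by frame:
the 532 nm frames report all energy transfer originating from Cy3
(exit side), the 638 nm frames report Cy5-to-Alexa750 transfer (entry side).

During remodelling the entry-side FRET changes first -- non-monotonically,
rising as the Alexa750 label approaches the central Cy5 and falling as it
passes -- and the exit-side FRET decreases only after a lag, `t_lag`.  The
lag distribution is single-exponential, and its rate grows hyperbolically
with ATP concentration, implicating a single rate-limiting, ATP-binding
step before exit-side movement.  The discrete lag implies that the
nucleosome transiently *buffers* one to a few base pairs of DNA between the
entry and exit sides, stored as local twist defects.

The package implements the full analysis chain for such data, a synthetic
trace generator that emulates the experiment's statistical structure, and a
discrete DNA-buffering model.  Raw data for the original experiment are not
publicly deposited, so validation rests on synthetic data whose generating
parameters take the published summary statistics as inputs.

# FRET observables and spectral corrections

With corrected, Cy5-equivalent intensities, the two observables are

* exit side (532 nm excitation, all FRET originating from Cy3):
  `E_exit = 1 - I532_cy3 / (I532_cy3 + I532_cy5 + I532_a750)`;
* entry side (638 nm excitation):
  `E_entry = I638_a750 / (I638_cy5 + I638_a750)`.

Cy3-to-Alexa750 transfer is taken to be zero throughout (the dye separation
exceeds twice that pair's Förster radius), so no three-way de-mixing is
attempted.

The correction model has six coefficients (`CorrectionParams`): two
direct-excitation fractions (`d_cy5_532`, `d_a750_638`; direct excitation
of Alexa750 at 532 nm is negligible and carries no coefficient), two
bleedthrough fractions (`b_cy3_cy5`, `b_cy5_a750`) and two channel scale
factors (`s_cy3`, `s_a750`) that compensate quantum-yield and
detection-efficiency differences relative to Cy5.  The correction order is
fixed: direct excitation, then bleedthrough, then scaling.

A design point worth making explicit: a Cy5 population directly excited in
a 532 nm frame behaves exactly like a 638 nm excitation scaled by
`d_cy5_532` -- it emits in the Cy5 channel *and* re-transfers to Alexa750.
`applyCorrections` therefore subtracts that scaled 638 nm signature from
both 532 nm acceptor channels, and solves the 638 nm A750 channel
self-consistently for its own direct-excitation term.  With this
completion, the corrections invert the forward model of the synthetic
renderer exactly (to machine precision) on noiseless data; truncating the
correction to the Cy5 channel alone would leave a residual of order
`d_cy5_532 * E_entry` in the exit-side denominator.

Records whose denominator falls below a floor (default `3 * 5 * sqrt(3)`,
i.e. three read-noise SDs of the default photophysics accumulated over
three channels) are marked invalid rather than clipped: FRET is undefined,
not zero, when no photons remain after bleaching.

`estimateCorrections` recovers all six coefficients from photobleaching
segments, the standard ALEX practice: bleedthrough from segments where only
the donor of a channel pair survives, direct excitation from segments where
the 532 nm donor is dark, scale factors from intensity matching across
bleach steps.  Parameters without qualifying segments keep their prior and
are flagged.  Because an active FRET transition genuinely moves intensity
between channels, correction estimation should use event-free data (e.g. a
no-ATP control), as is usual for ALEX calibrations.

# The synthetic-data generator

`sampleKinetics` draws, per molecule: an entry-onset time (exponential,
rate `k_init`), a lag (exponential with mean
`tau = (K_app + S)/(k_max * S)` at ATP concentration `S`), and per-dye
photobleach times.  `renderTraces` converts the piecewise-linear
ground-truth efficiency trajectories into raw three-channel ALEX frames:

* 532 nm frames split the Cy3-excited photon budget `N` as
  `(1-E1) : E1*(1-E2) : E1*E2` across Cy3/Cy5/A750 (cascaded transfer),
  plus a direct-excited Cy5 fraction that re-transfers with `E2`;
* 638 nm frames split as `(1-E2) : E2` plus direct-excited A750;
* per-dye detection gains, bleedthrough mixing, Poisson shot noise,
  Gaussian read noise and background follow, with the (known) background
  subtracted so that rendered intensities can be negative, as in real
  background-subtracted traces.

Defaults and the reasoning behind them:

| parameter | default | rationale |
|---|---|---|
| `frame_interval` | 0.1 s | conventional EMCCD frame time; gives a 0.2 s ALEX cycle |
| `K_app` | 60 uM | within the published 50-60 uM Michaelis constant for ATP |
| `k_max` | `560/(500*4.9)` /s | makes the mean lag at 500 uM ATP equal the published 4.9 s (original 601 orientation); the flipped orientation uses the same formula with 21.0 s |
| `k_init` | 0.1 /s | a ~10 s initial waiting phase, short relative to trace length |
| `d_rise`, `d_fall`, `d_exit` | 2 s | few-second gradual multi-bp transitions |
| FRET levels | 0.7/0.25 exit, 0.35/0.9/0.15 entry | high-contrast levels matching the qualitative trace shapes (entry rise past the central dye, exit decrease) |
| `photon_budget` | 500 /frame | gives a FRET shot-noise SD of ~0.02-0.03 |
| bleedthrough 0.1, direct excitation 0.05, read noise 5, background 10 | -- | conventional placeholders for a three-colour TIRF setup; the published calibration values are not available, so all are configurable and recorded |
| bleach rates | 5e-4 /s exposure | most molecules survive a 2-4 min observation; Cy3 sees only the 532 nm half of the cycle |
| `duration` | 120 s | covers entry wait + lag + transitions for the fast condition; analyses of the slow (21 s) condition use 240 s |

What the generator does *not* emulate: dye blinking and triplet states,
anisotropy effects, baseline drift, stage drift, multi-burst catalysis
(each molecule undergoes exactly one rise-fall entry excursion and one exit
decrease), and day-to-day calibration variability.  Passing tests on these
data therefore demonstrate the correctness of the analysis arithmetic and
the statistical behaviour of the estimators under idealised single-event
kinetics -- not robustness to every photophysical artefact of real traces.

One deliberate subtlety: ALEX pairs each 532 nm block with the
nearest-in-time 638 nm block (no interpolation, which would smooth change
points).  When the entry-side efficiency moves *within* a half cycle, the
direct-excitation correction -- which references the paired 638 nm frame --
mis-splits a quantity of order `d_cy5_532 * N * dE2` between the two 532 nm
acceptor channels.  That term cancels exactly in the summed denominator of
`E_exit` and does not enter `E_entry`, so both observables remain exact;
only the individual corrected acceptor intensities during a ramp carry it.

# Event detection

The published analysis dated onsets by visual inspection; the package
replaces this with a deterministic change-point fit.  `detectOnset` fits a
three-piece model -- constant baseline, linear ramp (at most `max_ramp`
points), constant plateau (possibly empty) -- by exhaustive scan of both
breakpoints, minimising the residual sum of squares via cumulative-sum
algebra (O(n * max_ramp)).  An event is called only if

* the fitted change (plateau mean minus baseline, or ramp endpoint when the
  plateau is short) exceeds `onset_threshold` (default 0.1 FRET) in the
  required direction, and
* the model beats a flat fit by more than `penalty` (default 20) times the
  robust point-noise variance (`mad(diff(y))/sqrt(2)` squared).  At the
  default noise the false-onset rate on flat traces is below 1%, with no
  measurable loss of sensitivity.

The onset is dated where the fitted ramp line crosses the baseline level
(clamped near the breakpoint).  On a clean baseline-then-ramp series this
is exactly the first ramp timestamp; under noise it removes the late bias
of the raw breakpoint, leaving residual onset errors of ~1 ALEX cycle
(median) at noise SD 0.05.  For the non-monotonic entry-side trace the
series is first truncated at the maximum of a 5-point running mean, so the
onset always dates the *first rising phase*; this stands in for a full
multi-breakpoint segmentation, of which only the first breakpoint would be
used anyway.

`extractEvents` searches the exit onset only at times at or after the
entry onset, encoding the observed ordering; `t_lag >= 0` by construction.
To keep this prior from hiding contrary data, the unconstrained exit onset
is also computed and the fraction of molecules where it precedes the entry
onset is attached as a diagnostic attribute.

Photobleach steps are found by recursive two-segment mean-shift fits.  Cy5
bleaching is detected on the *summed* 638 nm signal: FRET transitions
redistribute photons between the Cy5 and A750 channels but perturb their
sum only through the detection-efficiency mismatch, whereas a Cy5 bleach
collapses it; steps must also exceed 25% of the pre-step level, which
separates the two cleanly at the default photophysics.  Cy3 bleaching is
read from the 532 nm Cy3 channel (FRET changes only move it upward).
Alexa750 bleaching is read from the 638 nm A750 channel and is the one
genuinely ambiguous case -- the entry-side FRET fall also empties that
channel -- so an A750 bleach call during an event is conservative: it
truncates the entry-side validity window (harmless for onset-of-rise
detection) but means entry-side *population* histograms after remodelling
are best built with independent bleach annotations.  Molecules with more
than one downward step in the summed Cy5-excited signal or the Cy3 channel
are doubly labelled and excluded (`multi_step_bleach`), mirroring the
experimental single-bleach-step selection.

# Lag-time and ATP-dependence fits

The primary lag estimator is the closed-form exponential MLE (the sample
mean), not a histogram fit: it is bin-free and unbiased.  A binned
least-squares mode (Freedman-Diaconis bins) is retained for comparison
with the traditional histogram procedure.  Molecules whose observation
ended (bleach or end of trace) after the entry onset but before an exit
onset contribute censoring times; the right-censored MLE
`(sum(lags) + sum(censored))/n_uncensored` is exact for exponential data
and is the estimator used in the end-to-end validation, where bleaching
would otherwise bias the mean downward by preferentially removing long
lags.  SEMs are seeded nonparametric bootstraps (1000 resamples); whether
the original SEMs came from fit covariance or resampling is not stated, so
a resampling definition was chosen and declared.  KS goodness-of-fit
p-values are reported per condition without multiplicity correction --
they are descriptive, not a screen.

`fitAtpDependence` fits `v = k_max * S / (K_app + S)` to the per-
concentration lag rates by weighted nonlinear least squares (weights
`1/SEM^2` propagated through the reciprocal), with multi-start
initialisation over decades of `K_app`.  The hyperbolic (Michaelis-Menten)
form is a modelling decision: the source data show an increasing,
saturating `1/t_lag` versus ATP and a single ATP-binding rate-limiting
step, for which this is the minimal model.  It is worth noting the
information limit: with five concentrations of 100 events each, the
per-point rate SE is 10% and the implied SE of `K_app` is roughly 20%, so
a 10%-accuracy recovery of `K_app` from one such data set is expected to
succeed only in favourable realisations; larger event counts tighten it
in proportion to `1/sqrt(n)`.

# The DNA-buffering (twist-defect) model

The model has two layers.

**Deterministic gap rule** (`deterministicShifts`): a 2-nt single-stranded
gap placed `m` bp ahead of the motor's stall position limits total
injection to `m` bp.  On binding, the remodeller pulls `initial_defect`
(default 1) bp onto the entry side; the entry probe therefore registers
`m + initial_defect` bp.  Buffers between entry SHL2 and dyad (capacity 2)
and between dyad and exit (capacity 3) absorb in order of passage; only the
excess shifts the downstream probes.  The default capacities are calibrated
so that `m = 8` reproduces the measured 9/7/4 nt entry/dyad/exit shifts,
and are declared as such.  Whether the entry probe registers the initial
defect in addition to the injected bp is an inference from the 9 nt entry
shift; the decomposition `8 + 1` is a model choice.  The slower, weaker
response observed at `m = 5` (a stronger gap barrier) is documented as out
of model scope: the model deliberately has no barrier-strength parameter.

**Stochastic kinetics** (`simulateCtmc`): a continuous-time Markov chain in
which injections (rate `k_inj`) load the first buffer and any buffer
holding more than its capacity passes one bp downstream at rate `k_relax`;
a bp passing the last buffer is an exit movement.  Buffers end at exactly
their capacities (twist defects are stable; only excess propagates), so
long-time shifts agree with the deterministic rule.  The two mechanistic
scenarios discussed for the lag map onto rate extremes rather than separate
code paths: with `k_relax >> k_inj` (threshold-triggered transfer) the lag
is the Erlang wait for the injections that saturate the buffers; with a
single rate-limiting relaxation (spontaneous defect collapse; e.g. one
buffer of capacity 1 preloaded by the initial defect) the lag is exactly
exponential, matching the observed single-exponential `t_lag`.

# Numerical choices and degenerate inputs

* Frames are 0-based, times in seconds, intervals half-open.
* Trace tables and manifests are plain TSV/key-value text; intensities are
  written with `%.12g`, so files round-trip to better than 1e-9 relative.
* Traces with fewer than 2 frames are skipped with a warning; unpaired
  trailing excitation blocks are dropped and counted.
* Series with fewer than `2 * min_segment` valid points yield "no onset"
  with a reason, never an error.
* Negative corrected intensities are permitted and flagged.
* `atp_uM = 0` is rejected at configuration time (infinite mean lag).
* Degenerate buffering configurations that can never produce an exit
  movement (`m + initial_defect <= total capacity`) are rejected with an
  explicit message, as are ungapped simulations without a time horizon.
* All stochastic steps take explicit integer seeds; identical seeds give
  bit-identical outputs.

# Problem sizes used in the validation suite

The test suite regenerates everything it checks: lag recovery runs the full
simulate-render-correct-detect-fit chain at 185 events (mean lag 4.9 s,
120 s traces) and 190 events (21.0 s, 240 s traces); the correction round
trip uses 20 noiseless molecules; ATP-dependence recovery uses five
concentrations of 100 events; the buffering-model property checks use
10,000 short trajectories plus 100 repetitions of 200-event single-stage
KS tests.  These sizes put each estimator's sampling error in the regime
the published experiment reports while keeping the whole suite at a few
minutes on one core.

# Known limitations

* The correction-parameter estimator reconstructs a calibration whose
  published numerical values are unavailable; it is validated against the
  package's own forward model, not against instrument data.
* The onset convention (baseline-crossing of the fitted ramp) is declared,
  not derived from the original visual-inspection procedure; any constant
  offset between conventions cancels in `t_lag` only to the extent that
  entry and exit transitions have similar shapes.
* Single rise-fall entry trajectories and single-step sliding are
  simplifications; real traces may contain multiple catalytic bursts.
* The two-buffer layout is a minimal choice; the number and positions of
  twist-defect sites on the nucleosome are unresolved, and alternatives
  with the same total capacity produce the same deterministic shifts.
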