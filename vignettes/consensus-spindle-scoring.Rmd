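---
title: "Crowd-consensus sleep spindle scoring: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crowd-consensus sleep spindle scoring: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindler)
```

## The problem

Sleep spindles are 10–16 Hz bursts of N2/N3 sleep EEG, usually 0.5–1 s long,
with a waxing–waning envelope. Human experts disagree on borderline events,
so a single scorer is a noisy reference. The crowd-consensus approach asks
many scorers to mark candidate spindles with a confidence rating and keeps
only the stretches of signal on which the panel, on average, agrees. This
vignette documents the models and the concrete numerical choices `spindler`
makes at every stage, what the synthetic generator does and does not emulate,
and the known limitations.

## Signal conditioning

EEG enters the pipeline broad-band filtered to 0.3–30 Hz and resampled to
100 Hz; all later stages assume that rate.

**Band-pass filter.** A Butterworth IIR filter of final order 10 (an order-5
low-pass prototype transformed to a band-pass), designed in zero-pole-gain
form, packed into second-order sections, and applied forward–backward
(`bandpass_filter()`). The forward–backward pass squares the magnitude
response and cancels the phase, so in-band oscillations come through with
zero lag — essential when event boundaries are compared across methods at
10 ms resolution. Edge handling: odd-reflection padding of `3 * order`
samples, with each biquad initialized at its step steady state with respect
to the first padded sample. Two practical consequences are worth knowing:

* the 0.3 Hz high-pass edge has a multi-second impulse response, so the
  first/last couple of seconds of a record keep a visible transient; the
  package's own tests measure passband gain and phase away from the edges;
* a *rectangular* burst switched on at full amplitude excites ~6 %
  Gibbs overshoot in the 11–16 Hz band-passed output. Tapered (Hann)
  envelopes — which is what real spindles and the synthetic generator
  produce — do not.

**Resampling.** Rational-factor polyphase resampling (`resample_to()`):
zero-stuff by `p`, FIR low-pass at the lower of the two Nyquist frequencies
(`fir1`, 10 taps per phase, group delay compensated), take every `q`-th
sample. Each polyphase branch is normalized to unit DC gain so a constant
signal resamples exactly to itself. Output length is
`round(n * target_fs / fs)`, so durations are preserved.

## The scoring grid

Scorers view 25 s epochs cut from 115 s blocks, five epochs per block at
offsets 0, 22.5, 45, 67.5 and 90 s — consecutive epochs overlap by 2.5 s and
exactly tile the block (25 + 4 × 22.5 = 115). `build_epoch_grid()` builds
this grid; epoch ids are `b<block>e<epoch>`, 0-based. All event coordinates
are seconds from recording start with half-open intervals
`[onset, onset + duration)`; sample `i` (0-based) covers `[i/fs, (i+1)/fs)`,
and rasterization rounds interval ends to samples with round-half-even.

## Building the group consensus

Each marking contributes a per-sample weight: 1 (high confidence), 0.75
(medium), 0.5 (low); unmarked samples contribute 0. Three rules matter:

1. **Epoch-overlap max rule.** A spindle falling in the 2.5 s overlap zone
   appears on two epoch images and may be marked on either; per scorer, the
   highest weight at each sample is kept (`rasterize_scorer()`).
2. **Viewer denominator.** The per-sample mean is taken over the scorers who
   *viewed* an epoch covering that sample (`average_scores()`). A scorer who
   viewed an epoch and marked nothing contributes 0 to the numerator and 1 to
   the denominator; a scorer who never saw it contributes to neither. This is
   why the views table is mandatory in the annotation format, and why a
   scorer who viewed epochs but marked no events must still be declared
   (events alone cannot reveal their subtype).
3. **Strict threshold.** A sample enters the consensus when its mean score is
   *strictly greater* than the group consensus threshold GCt
   (`threshold_and_clean()`). Reading "exceeds" strictly keeps `GCt = 0`
   meaningful: it admits anything at least one viewer marked, which is
   exactly how a maximally inclusive consensus is built.

Cleanup afterwards: adjacent candidates separated by less than 0.1 s are
merged when at least one of the pair is shorter than 0.3 s (repeated to a
fixed point), then events shorter than 0.3 s or longer than 2.5 s are
dropped. The merge-then-filter order follows the order in which the cleanup
steps are conventionally described; requiring only *one* member of the pair
to be short is this package's reading of "too short adjacent spindles were
merged" — the alternative (both short) is a one-line change in
`merge_short_adjacent()` and the choice is surfaced here deliberately.

The expert panel's consensus is labelled the gold standard
(`build_group_consensus(..., subtype = "expert")`). When an individual
scorer is evaluated, the reference is rebuilt without that scorer's tracks in
either numerator or denominator (`leave_one_out_consensus()`), avoiding
self-agreement bias.

## Event-level evaluation

Two events match when their intersection-over-union — intersection length
divided by the length of the spanning interval — reaches the overlap
threshold (default 0.2, the conventional permissive setting). Matching is
greedy and one-to-one: repeatedly take the globally largest qualifying IoU,
with ties broken by earlier reference onset then earlier detection onset.
The tie rule is not prescribed anywhere; earlier-onset is the deterministic
choice that keeps the matcher order-independent. A brute-force
re-implementation (explicit IoU table, repeated arg-max scans) lives in the
test suite and is held equal to the production matcher on 1000 random
instances.

Degenerate conventions, chosen so sweep curves stay plottable: precision is
0 when there are no detections, recall is `NA` (flagged undefined) when
there are no reference events, f1 is 0 when `p + r = 0`.

`optimize_gct()` picks the GCt maximizing mean individual leave-one-out f1
over a grid (default 0.05–0.95 by 0.05, smallest grid value on ties).
`scorers_needed_experiment()` subsamples `n` scorers per epoch (3 draws by
default) and rebuilds partial consensuses under a panel-size-dependent
threshold schedule. The default schedule (`gct_schedule_linear()`) starts at
0.4 for one scorer — so a lone scorer's low-confidence markings (weight 0.5)
still count — and moves linearly to the panel optimum at five scorers.
Only those endpoints are anchored by convention; the interpolation is this
package's choice and is configurable. One property of any such schedule is
worth knowing: around 2–3 scorers per epoch a lone high-confidence false
positive can clear the threshold (1/3 > 0.3), which costs a percent or two
of precision right there; with three random draws per size this makes
*adjacent* panel sizes statistically indistinguishable, so panel-size curves
are best read at well-separated sizes (e.g. 1, 3, 5, 10).

## Per-subject characteristics

* **Density**: events per minute of scored time (115 s per block).
* **Duration**: mean of event durations.
* **Amplitude**: the signal is filtered to 11–16 Hz and the maximum absolute
  difference between *consecutive local extrema* inside the event is taken
  (the oscillatory peak-to-peak convention; for a sinusoid it equals global
  max − min, but it is robust to slow residual drift).
* **Dominant frequency**: the event is filtered to 10–16 Hz, zero-padded by
  5 s (0.167 Hz FFT resolution for a 1 s event), and the arg-max of the FFT
  magnitude within 9–17 Hz is returned. Restricting the search band guards
  against filter-skirt leakage; events with essentially no in-band energy
  are flagged `NA` rather than given a spurious peak.

The two bands differ (11–16 for amplitude, 10–16 for frequency) because that
is how the two measures are conventionally specified; both are arguments.
Cross-method agreement uses squared Pearson correlation per feature
(`characteristic_correlation()`; r² is the quantity conventionally reported)
and group contrasts use the two-sided Mann–Whitney test
(`compare_groups()`), with 0.05/0.01/0.001 star coding.

## Automated detectors

Five classic detectors, run with their published defaults on the broad-band
100 Hz signal (`detect_spindles()`); baseline statistics are computed over
the whole record, which is assumed artifact-free N2:

| method | band (Hz) | statistic | threshold |
|---|---|---|---|
| `envelope` | 11–15 | analytic-signal envelope | seed > 8 × mean, extend to ≥ 2 × mean |
| `rms` | 11.3–15.7 | RMS, 100 ms / 50 ms windows | > 1.5 × SD of the RMS series |
| `rms_percentile` | 11–15 | RMS, 25 ms windows | > 95th percentile |
| `wavelet` | ~10–16 | Morlet power, 0.1 s moving average | > 4.5 × mean |
| `a7` | 11–16 | four features, 0.3 s / 0.1 s windows | 1.25, 1.6 SD, 1.3 SD, 0.69 |

Choices the published one-line descriptions leave open, resolved here:

* `envelope`: "envelope" is realized as the analytic-signal magnitude.
* `rms`: the threshold is read literally as 1.5 × SD of the RMS series
  (not mean + 1.5 SD); `params$threshold_form = "mean_plus_sd"` selects the
  alternative. The literal form over-detects (the detector's known bias).
* `wavelet`: no wavelet parameters are published; the Morlet is centered at
  13 Hz with spectral SD 3.6 Hz, putting the half-power points near 10 and
  16 Hz.
* `a7`: the absolute sigma-power criterion ("1.25 µV²") is applied on the
  log10 scale, i.e. `log10(mean square) > 1.25`; the relative-power and
  covariance features are z-scored against a 30 s centered sliding baseline
  (records shorter than 30 s are an error). The covariance is floored at
  0.1 µV² before the log10 transform — background windows have near-zero or
  negative covariance, and an unbounded log floor would inflate the baseline
  SD until the z-score never fires.
* All detectors share a 0.3–3 s duration filter (none is published;
  unbounded events are degenerate), configurable via
  `params$duration_bounds`.

Scaling behavior: `rms`, `rms_percentile` and `wavelet` use purely relative
thresholds and are invariant to rescaling the input; `envelope` is also
relative; `a7`'s absolute-power feature is deliberately scale-dependent
(microvolts are physical units for it).

## The synthetic generator

`simulate_eeg()` produces the signal model the pipeline assumes:
1/f^α Gaussian background (α = 1, RMS 15 µV — a plausible artifact-free N2
C3 level) plus Hann-enveloped constant-frequency sinusoidal bursts. Defaults
describe a healthy younger sleeper: density 4.2 spindles/min, durations
0.5–1.5 s, frequencies 11–16 Hz, peak-to-peak amplitudes 20–45 µV. Events
are placed by a thinned Poisson process with a 0.5 s dead time and a 1 s
block-edge margin, so truth lists always satisfy the matcher's
non-overlapping contract. Bursts have constant frequency (no chirp) so the
dominant-frequency estimator's target is exact.

`simulate_panel()` models a scorer as: a detection probability per event
(constant, or logistic in event amplitude), independent Gaussian jitter on
each boundary (SD 0.05 s default), Poisson false positives (0.5/min
default), and a confidence rating given by the event's amplitude tertile
(loudest third → high) with optional label noise. Every scorer draws from an
independent sub-stream seeded from the master seed, so panels are
reproducible and individual scorers are independent.

What this does **not** emulate — and therefore what passing tests do not
show about real data: artifacts and arousals, non-stationary background,
chirping spindles, scorer idiosyncrasies beyond the parametric family
(fatigue, drift, systematic onset bias), and correlated errors between
scorers. The pipeline's *bookkeeping* (grids, weighting, matching,
thresholds) is fully exercised; claims about real-EEG detector rankings are
not transferable from synthetic results.

## Problem sizes and reproducibility

The test suite and the acceptance script run on 1–3 block subjects
(115–345 s at 100 Hz), 3–10 scorer panels, and 1000-instance matcher
comparisons; these sizes make every property checkable in seconds while
keeping all estimators well inside their asymptotic regimes. All stochastic
steps take explicit seeds, and `scripts/acceptance.R --seed S --out F`
recomputes every reported quantity from scratch.

## Known limitations

* No EDF reader: EEG enters via the plain-text `fs=` CSV dialect (or any
  numeric vector through `eeg_signal()`). EDF conversion must happen
  upstream.
* Scorer reliability is not modelled beyond uniform averaging — no
  Dawid–Skene-style weighting; that is a deliberate scope boundary, since
  the consensus definition under study *is* the uniform weighted average.
* The two under-specified published detectors that rely on external
  decomposition/solver designs are out of scope; the five implemented ones
  are those whose published descriptions fix the algorithm completely (up to
  the documented choices above).
* By-sample agreement metrics and ROC analyses are not provided; evaluation
  is by-event PRF throughout.
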