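---
title: "Cycle-by-cycle waveform shape and phase-amplitude coupling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cycle-by-cycle waveform shape and phase-amplitude coupling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycleshape)
library(dplyr)
```

## The scientific problem

Beta-band (13-30 Hz) activity over sensorimotor cortex is excessively
synchronized in Parkinson's disease, and both its coupling to broadband
gamma amplitude (phase-amplitude coupling, PAC) and the non-sinusoidal
*shape* of individual beta cycles change with medication state. Because
synchronous synaptic input sharpens cortical waveform extrema, shape
metrics computed directly on the raw signal - no narrowband filtering of
the features themselves - are a candidate non-invasive biomarker. This
package implements that analysis chain end to end: preprocessing, cycle
decomposition, shape ratios, PAC, spectral screening, and the group
statistics layer, together with a synthetic-data generator that provides
ground truth for every stage.

## The cycle decomposition and the four shape ratios

Cycles are delimited in a band-pass filtered copy of the signal (one-pass
linear-phase FIR, Hamming window, tap count `round(order_ms * fs / 1000)`
forced odd - 119 taps for the default 231 ms order at 512 Hz - with the
group delay compensated so filtered indices address the raw trace
directly). A rising zerocrossing is a sample `i` with `x[i] < 0` and
`x[i+1] >= 0`; exact zeros count as nonnegative. Between consecutive
crossings the *raw* signal supplies the peak (maximum) and trough
(minimum), first index winning ties.

Per cycle we measure:

* **peak / trough sharpness** - the mean of the two voltage differences
  between the extremum and the samples `width` points (default 3, about
  5.9 ms at 512 Hz) before and after it;
* **rise / decay steepness** - the maximum one-sample slope between a
  trough and the next peak, and the maximum downward slope between a peak
  and the next trough.

Channel-level metrics are logs of ratios of the per-cycle means:

* peak-to-trough ratio `PTR = ln(mean peak sharpness / mean trough sharpness)`
* rise-to-fall ratio `RTF = ln(mean rise steepness / mean decay steepness)`
* sharpness ratio `SR = |PTR|`, steepness ratio `STR = |RTF|`

The `(PTR, RTF)` sign pair defines four shape quadrants; Q4
(`PTR > 0, RTF < 0`: sharper peaks, steeper decays) is the canonical
sensorimotor shape and is used as an inclusion criterion in the group
layer (`q4_inclusion()`).

Natural logarithms are used throughout (the base only rescales, never
reorders). Decay steepness is implemented as the maximum *downward* slope
rather than the maximum absolute slope: on a genuine peak-to-trough decay
the two coincide, and the signed form makes the exact antisymmetries below
hold to machine precision even on noisy segments, where an upward noise
blip could otherwise be picked by the absolute value.

These symmetries are tested properties, not aspirations: negating a signal
swaps peaks with troughs (`PTR(-x) = -PTR(x)`), time reversal swaps rises
with decays (`RTF(rev(x)) = -RTF(x)`), and positive rescaling changes
nothing. A deliberately naive loop-based reference implementation
reproduces the pipeline's cycle table exactly on synthetic fixtures.

### Handling of artifacts and boundaries

Artifact intervals are half-open sample ranges (1-based start, exclusive
end), normalized by sorting, merging and clipping. Filtering is applied to
the continuous recording and masking afterwards. A cycle is invalidated
when its extremum lies in a flagged interval, a steepness segment overlaps
one, or the extremum sits within `width` samples of the recording
boundary. At least `min_cycles = 5` fully valid cycles are required for a
defined metric; otherwise the result is `NA` with a classed warning. A
trough preceding the first detected peak still contributes to the trough
mean (as a partial leading row), which is what makes the negation symmetry
exact rather than approximate.

## Phase-amplitude coupling

Beta phase (13-30 Hz, 231 ms order) and gamma amplitude (50-150 Hz,
240 ms order) come from the angle and magnitude of the analytic signal
after one-pass FIR filtering. The normalized modulation index bins
amplitude by phase into 18 equal bins over `(-pi, pi]`, normalizes the bin
means to a distribution P and reports `KL(P || uniform) / ln(18)`, which
lies in [0, 1]. 18 bins is the conventional choice for this metric and is
exposed as an argument. An exactly flat profile returns exactly 0 (the KL
term is short-circuited rather than accumulated through floating-point
normalization).

Two processing orders are available. The default filters, removes
artifact-flagged regions, and Hilbert-transforms the concatenated
remainder; the alternative (`order = "filter_hilbert_remove"`) transforms
the continuous signal and drops flagged samples only at binning, avoiding
concatenation discontinuities. Either way one combined filter length is
discarded at each end of every continuous segment to suppress edge
transients. On clean recordings the two orders agree; the choice matters
only for heavily interrupted data.

## Preprocessing

`reference_average()` demeans every good channel and subtracts the
per-sample mean across good channels (bad channels are excluded from the
average and passed through untouched); the operation is idempotent.
`reference_bipolar()` derives clinical-style pairs such as C3-CP1.
`filter_highpass()` removes drift with a two-way (forward-backward,
zero-phase) FIR high-pass at 0.5 Hz; the length heuristic is
`3 * round(fs / cutoff)` taps, forced odd and capped at a third of the
recording with a warning. The designed kernel is given an exact spectral
null at DC (window-method designs otherwise leave ~1e-3 residual DC gain
at this length). Noisy channels are excluded *before* the common average
is formed.

`composite_channels()` implements the one-value-per-participant rule:
metrics are computed per electrode (C3, C4) and averaged; if only one
electrode has a defined value, that value is used alone.

## Spectral screening

Shape analysis of the raw trace is only meaningful when a dominant
oscillation exists. `welch_psd()` (Hamming window, 256-sample segments,
50% overlap, 450-point transform) feeds `oscillation_present()`, which
requires a local spectral maximum in the band exceeding a log-log linear
aperiodic fit (fitted outside 5-35 Hz over 1-100 Hz) by a configurable
factor (default 2). The original screening of this kind is done by eye;
the quantitative gate is this package's construction and its threshold is
deliberately conservative.

## The synthetic generator

`simulate_oscillation()` builds each cycle from half-cosine arcs: the rise
(trough to peak) occupies `rdsym` of the period and the decay the rest, so
`rdsym` tunes rise-decay asymmetry independently of everything else;
positive and negative half-cycles are raised to `peak_exp` and
`trough_exp`, sharpening an extremum while preserving its amplitude (so
sharpness and amplitude decouple). The waveform is evaluated from
continuous cycle position (no cumulative rounding) and recentred by its
analytic cycle mean; with `rdsym = 0.5` and unit exponents it is a pure
sinusoid to ~1e-13. The construction's instantaneous phase (0 at peaks) is
returned alongside and drives `inject_pac()`, a gamma carrier with
envelope proportional to `1 + m cos(phase)`. The aperiodic background is
spectrally shaped Gaussian noise (`power ~ 1/f^chi`, DC bin zeroed,
standardized). Artifact segments are high-amplitude broadband bursts whose
ground-truth intervals are recorded in the output.

A recording generated by the defaults emulates resting sensorimotor EEG at
the study's scale: 512 Hz, beta oscillation at 20 Hz of unit amplitude, an
alpha/mu sinusoid at 10 Hz (amplitude 0.5), unit-variance `1/f^2`
background, and a gamma carrier (80 Hz, amplitude 0.3) optionally
modulated by beta phase. These defaults were chosen once, on the criterion
that the resulting Welch spectrum shows distinct mu/alpha and beta peaks
standing clearly above the aperiodic slope - the qualitative picture
expected of sensorimotor EEG - and they are exercised as-is by the test
suite.

`simulate_cohort()` mirrors a paired medication design: per-subject shape
offsets (s.d. 0.02 on `rdsym`, and on the log of `exp - 1` for the
sharpening exponents) are drawn once and shared across conditions, so the
only systematic off/on difference is the one written into the two
parameter sets. Fifteen subjects, two channels (C3, C4) and 180 s
recordings reproduce the study scale.

What the generator does *not* emulate: volume conduction and channel
covariance, ocular or muscle artifact morphology, nonstationary bursting,
multiple simultaneous oscillators per band, or between-channel phase
structure. Passing tests on synthetic cohorts therefore demonstrate that
the pipeline measures what it claims under known ground truth - not that
any particular clinical effect size will be observed in real EEG.

```{r quadrants, fig.width = 5, fig.height = 4}
rec <- simulate_recording(
  synth_params(duration = 30, rdsym = 0.58, pac_depth = 0.5,
               gamma_amp = 0.1, seed = 1))
analyze_recording(rec) |> select(channel, quadrant, steepness_ratio, pac)
```

## Group statistics

Paired comparisons use the Wilcoxon signed-rank test (statistic = smaller
rank sum, matching the convention in which small values are the
significant ones; zero differences dropped; exact p for n <= 25 without
ties, else normal approximation with continuity correction). Unpaired
comparisons use a tie-corrected rank-sum z. Spearman correlations use the
t approximation on n - 2 df. Multiple comparisons are corrected with
Benjamini-Hochberg step-up FDR, one family per comparison table. Cohen's d
uses the pooled unbiased-variance formula for both paired and unpaired
designs (keeping effect sizes comparable across tables), log-scaling PAC
first since raw modulation indices are strongly right-skewed.

Topographic map values set non-significant electrodes to zero and rescale
significant ones to `100 * score / max(score among significant)`. The
`score` must be on a larger-is-more-significant scale (|z| or -log10 p);
the package computes map values only and draws them as bars - scalp
interpolation is out of scope.

## Numerical choices and degenerate inputs

* Zerocrossing ties: a sample exactly at zero is nonnegative.
* Extremum ties: first index wins.
* FIR application is FFT-based (mixed-radix padding), with kernel
  transforms cached; edges are zero-padded, so roughly half a kernel
  length at each end is attenuated and treated accordingly (edge cycles
  are dropped by the boundary rule; PAC discards a full filter length per
  segment end).
* All-zero amplitude, empty phase bins, constant vectors, all-zero paired
  differences, and metric computation with fewer than `min_cycles` valid
  cycles raise classed conditions (`cycleshape_error_*`,
  `cycleshape_warning_undefined_metric`) rather than returning silent
  numbers.
* Generators are bit-reproducible for identical parameter sets including
  the seed.

## Problem sizes used by the test suite

The suite validates calibration and power on scaled study-like problems
chosen as the smallest sizes at which the properties are stable: type-I
error of the full pipeline on 200 null cohorts of 15 subjects (30 s,
single channel - the error rate does not depend on recording length);
detection power on 100 cohorts of 15 subjects at the full 180 s, two
channels, with rise fraction 0.42 off versus 0.48 on medication; the
modulation-index oracle on one million samples; and BH monotonicity on
10,000 random p-vectors.

## Two estimator behaviours worth knowing about

Working with the generator surfaced two properties of the max-slope
steepness estimator that users of the real pipeline should also expect:

* **Strong phase-locked gamma contaminates steepness.** The maximum slope
  within a rise or decay segment picks up the carrier's slope once the
  gamma amplitude approaches `osc_amp * f_osc / f_gamma`; because the
  phase-locked envelope peaks at the beta peak, it inflates rise and
  decay maxima almost equally and compresses the rise-to-fall ratio
  toward zero. In scalp EEG gamma is far weaker than beta, so the
  demonstration cohort in `scripts/acceptance.R` uses a gamma amplitude
  of 0.1; the generator default (0.3) deliberately stresses the
  shape/PAC interaction instead.
* **Near-symmetric waveforms show a segment-length bias.** Under additive
  noise, the maximum of more samples is stochastically larger, so the
  longer of the two segments (rise, when `rdsym > 0.5`) collects a
  slightly larger noise maximum. For clearly asymmetric cycles the true
  slope difference dominates; within about 0.03 of `rdsym = 0.5` the sign
  of the measured rise-to-fall ratio can flip. Quadrant labels of nearly
  symmetric, noisy recordings should be treated as unstable - which is
  precisely why the Q4 criterion demands the canonical shape in *both*
  conditions before a subject is retained.

## Known limitations

* The quantitative oscillation gate is a package construction; its factor
  (2x over the aperiodic fit) is conservative and adjustable.
* Sharpness is measured at a fixed sample width; at very different
  sampling rates the default width corresponds to a different time span
  (use `samples_to_ms()` to check), though rank orderings are robust
  across widths 2-4.
* The PAC estimator is the binned modulation index only; surrogate-based
  significance and comodulograms are out of scope.
* EDF/BDF ingestion is not provided; recordings enter as matrices or via
  the TSV + JSON sidecar format (`read_recording()`).
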