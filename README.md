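# cycleshape

Cycle-by-cycle waveform-shape and phase-amplitude-coupling analysis of
resting EEG, in R.

## What this package is for

Beta-band (13-30 Hz) oscillations over sensorimotor cortex are excessively
synchronized in Parkinson's disease, and this synchrony leaves two
measurable fingerprints in scalp EEG: coupling between beta phase and
broadband gamma (50-150 Hz) amplitude, and a *non-sinusoidal waveform
shape* - sharper peaks and steeper decays of individual beta cycles. Both
are reduced by dopaminergic medication, which makes them candidate
non-invasive biomarkers of disease state.

`cycleshape` is for electrophysiologists who want to compute these
measures reproducibly. It implements:

- **Cycle decomposition**: zerocrossings of a band-pass filtered copy
  (linear-phase FIR, group delay compensated) delimit cycles; peaks and
  troughs are then located in the *raw* signal.
- **Shape metrics** per channel, from per-cycle features:
  - peak sharpness `= ((x[p] - x[p-w]) + (x[p] - x[p+w])) / 2` (default
    width w = 3 samples, about 5.9 ms at 512 Hz), trough sharpness
    analogously;
  - rise steepness = max one-sample slope from trough to peak, decay
    steepness = max downward slope from peak to trough;
  - peak-to-trough ratio `PTR = ln(mean peak sharp / mean trough sharp)`,
    rise-to-fall ratio `RTF = ln(mean rise steep / mean decay steep)`,
    and their absolute values, the **sharpness ratio** and **steepness
    ratio**. The sign pair (PTR, RTF) classifies waveforms into four
    quadrants; Q4 (+, -) is the canonical sensorimotor shape.
- **PAC** as the normalized modulation index: gamma amplitude binned by
  beta phase (18 bins), `MI = KL(P || uniform) / ln(18)` in [0, 1].
- **Preprocessing**: demeaning, common-average or bipolar referencing,
  zero-phase FIR high-pass (0.5 Hz), artifact-interval bookkeeping.
- **Spectral screening**: Welch PSD plus a quantitative
  oscillation-presence gate.
- **Group layer**: Wilcoxon signed-rank / rank-sum tests, Spearman
  correlations, Benjamini-Hochberg FDR, Cohen's d (log-scaled PAC), the
  Q4 inclusion rule, and topographic statistic maps.
- **A synthetic-data generator** with controllable rise-decay asymmetry
  (`rdsym`), extremum sharpening, 1/f background, beta-phase-locked gamma
  and paired two-state cohorts - ground truth for validating every stage.

## Worked example

Simulate a paired 15-subject cohort in which the untreated state has a
more asymmetric waveform (rise fraction 0.58 vs 0.55; the canonical Q4
shape) and deeper coupling (PAC depth 0.5 vs 0.25, with a weak gamma
carrier as in scalp EEG), then run the full pipeline:

```r
library(cycleshape)

spec <- cohort_spec(
  n_subjects = 15, channels = c("C3", "C4"),
  off = synth_params(duration = 180, rdsym = 0.58, pac_depth = 0.5,
                     gamma_amp = 0.1),
  on  = synth_params(duration = 180, rdsym = 0.55, pac_depth = 0.25,
                     gamma_amp = 0.1),
  seed = 1
)

values <- simulate_cohort(spec) |>
  analyze_cohort() |>       # per channel: shape ratios, quadrant, PAC
  composite_metrics()       # average C3/C4 -> one value per subject

compare_conditions(values)
```

```
# A tibble: 3 × 6
  metric              n statistic    p_raw   p_fdr cohens_d
  <chr>           <int>     <dbl>    <dbl>   <dbl>    <dbl>
1 sharpness_ratio    15         6 0.000854 0.00128    1.47
2 steepness_ratio    15         8 0.00153  0.00153    1.33
3 pac                15         6 0.000854 0.00128    0.535
```

`statistic` is the smaller signed-rank sum (small values = strong paired
effect), `p_fdr` the BH-adjusted p value across the three metrics, and
`cohens_d` the pooled-SD effect size (natural-log-scaled for PAC). All
three metrics are higher off than on medication, as injected.

Single-recording use, and the shape typology:

```r
rec <- simulate_recording(synth_params(duration = 30, rdsym = 0.58,
                                       pac_depth = 0.5, gamma_amp = 0.1,
                                       seed = 1))
analyze_recording(rec)[, c("channel", "peak_trough_ratio",
                           "rise_fall_ratio", "quadrant", "pac")]
```

```
# A tibble: 2 × 5
  channel peak_trough_ratio rise_fall_ratio quadrant     pac
  <chr>               <dbl>           <dbl> <chr>      <dbl>
1 C3                  0.301          -0.134 Q4       0.00516
2 C4                  0.385          -0.143 Q4       0.00607
```

Positive PTR with negative RTF places both channels in Q4 - sharp peaks
with steep decays. `plot_quadrants()`, `plot_cycle_features()` and
`autoplot()` methods (PSD, PAC histograms) provide the matching displays;
`tidy()`/`glance()` methods give broom-style access to PAC and
group-comparison objects.

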