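---
title: "Ramped cochlear-implant pulses and cortical growth functions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ramped cochlear-implant pulses and cortical growth functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rampulse)
```

## The problem

Cochlear implants conventionally stimulate the auditory nerve with
charge-balanced rectangular biphasic current pulses. Spiral ganglion
neurons, however, are sensitive to the *rate* at which a depolarizing
input rises, which motivates "ramped" pulse shapes whose current grows
linearly from zero to a peak instead of switching on instantaneously.
This package implements the computational side of that comparison: it
synthesizes the pulse families, quantifies electrically evoked
growth functions of auditory-cortex multi-unit recordings, and runs the
paired nonparametric comparison of ramped versus rectangular shapes. A
spike-train simulator with known ground truth stands in for in-vivo
recordings, which are not publicly deposited.

## Pulse families and the charge solver

A biphasic pulse has two consecutive phases of opposite polarity so net
injected charge is zero. We parameterize one phase by its peak amplitude
$A$ (µA), duration $t$ (µs) and, for ramps, the slope $s = A/t$
(µA/µs). Each ramped phase rises linearly from 0 to $A$, so one phase
carries charge $At/2$ and the biphasic pulse $Q = At$ in magnitude. The
package treats the stated charge level as this **total biphasic
charge**: it is the only reading under which the published
fixed-amplitude geometry is internally consistent — a 750 µA pulse
spans 4 µs at 3 nC and 42 µs at 31.5 nC, and a 500 µA pulse spans 6 to
63 µs, exactly as `solve_phase()` returns (1 nC = 1000 µA·µs). A
per-phase convention is available via `charge_convention = "per_phase"`.

The closed forms are trivial but worth stating:

* fixed amplitude: $t = Q/A$;
* fixed slope: $t = \sqrt{Q/s}$, $A = \sqrt{Qs}$, with
  $s = \tan(\text{angle})$ **read in µA/µs** — the angle is schematic,
  so this scale (85° ≈ 11.43 µA/µs, 80° ≈ 5.67 µA/µs) is a declared
  convention of the package, not a physical fact;
* rectangular: $A = Q/(2t)$ at a fixed phase duration, default 21 µs.
  The source protocol never states the rectangular duration; holding
  $t$ fixed keeps charge the only varying quantity, mirroring the ramp
  families.

```{r}
fa750 <- pulse_shape_spec("fixed_amplitude", "cathodic", peak_amplitude_uA = 750)
solve_phase(fa750, 31.5)$phase_duration_us
```

### Sampling and quantization

`synthesize()` samples each phase at bin midpoints with the bin width
adjusted to divide the phase exactly; the midpoint rule integrates
linear and constant segments exactly, so the continuous waveform's
numerical charge equals $Q$ to machine precision — this is a designed
property, not a tolerance. The second phase is the sign-flipped copy of
the first (each phase independently ramps 0 → peak); a time-mirrored
second phase is available behind `mirrored_second_phase` but is not
validated against the published protocol.

The stimulation hardware realizes ramps as staircases with a 25 µA
current step. With `quantize = TRUE` the ramp becomes
$\lceil A/25 \rceil$ equal-dwell levels, every sample a multiple of
25 µA. The staircase slightly overshoots the triangle's area, so all
dwell times are scaled by one common factor to restore the target
charge; dwell scaling was chosen over peak adjustment to preserve the
printed peak amplitudes (750, 500 µA). The platform's stated 3–4 µs
temporal resolution is ambiguous — it may constrain whole-phase timing
or each staircase dwell. Applied to dwells it would forbid the
30-level staircase that the hardware demonstrably delivered (at
31.5 nC a 750 µA ramp's mean dwell is 1.4 µs), so the package does not
enforce a dwell floor by default; `min_dwell_us = 3` turns the
constraint on, in which case the staircase is coarsened to a larger
multiple of 25 µA and flagged `constraint_violated` rather than
erroring.

## The synthetic cohort

`simulate_recording()` models a multi-unit site as the superposition of

* spontaneous activity: homogeneous Poisson at `spont_rate_Hz` over the
  full 250 ms inter-pulse interval (4 Hz stimulation), and
* an evoked response: per trial a Poisson count with mean
  $r(Q)\,\Delta$, where $\Delta = 36$ ms is the evoked-window duration
  and the transfer function is a sigmoid of charge,
  $$ r(Q) = g\,R_\max \,/\, \bigl(1 + e^{-(Q - (Q_{50} - \delta))/k}\bigr), $$
  with shape effects entering as a midpoint shift $\delta$ (nC) and a
  gain $g$ on the asymptote. Evoked spike latencies are truncated
  normal on [9, 45) ms, so every evoked spike is visible to the
  analysis window; simulating sub-9 ms responses would only exercise
  the discard rule, which has its own fixtures.

Defaults: trials are ordered as ascending 32-trial charge blocks (the
raster layout of the recording protocol; the presentation order was not
stated explicitly and interleaving is available via
`trial_order = "random"`). Refractoriness is not modelled: a multi-unit
cluster aggregates several neurons, so Poisson superposition is a
defensible approximation at these rates. Ground-truth priors
(`draw_ground_truth()`: spontaneous 5–15 Hz, $R_\max$ 30–90 Hz,
$Q_{50}$ 10–20 nC, $k$ 1–3 nC, latency mean 12–18 ms, SD 2 ms) are a
calibration chosen so simulated cohort summaries land near the scale of
the published cathodic-first cohort; they are not measured facts.
`default_shape_effects()` carries shifts and gains computed from the
published mean thresholds and maximal rates per ramped shape.

What the simulator deliberately omits — adaptation across the 32
repetitions, cross-channel correlation of the 16-electrode array,
non-stationary spontaneous rates, electrophonic contamination — bounds
what green tests show: they validate the *quantification machinery*
under the model's assumptions, not the biology of real recordings.

## Growth-function quantification

For each recording × shape, per-trial firing rates are counted in two
windows: evoked [9, 45) ms after pulse onset (the 45 ms analysis
window with responses before the 9 ms physiological latency floor
discarded — implemented as a per-spike exclusion; the alternative
per-recording screen is `early_onset_recordings()`) and spontaneous
[150, 250) ms, the last 100 ms of the inter-pulse interval. Rates are
counts divided by window duration (36 ms and 100 ms).

The growth function is the across-repetition mean evoked rate per
level. The baseline mean and SD are pooled over **all** trials of the
recording × shape (the pooling unit was not stated at finer grain; 640
trials give a stable SD estimate). Extraction rules:

* a level is *significant* when its raw mean evoked rate exceeds the
  spontaneous mean + 3 SD (`sd_multiplier` configurable; 3 is the
  Methods' criterion and the default);
* *threshold* = lowest significant level whose two immediate successors
  are also significant — the confirmation rule is the only guard
  against chance crossings, and deliberately no multiple-testing
  correction is applied across levels;
* *MaxFR* = max over levels of (mean − spontaneous mean);
  *charge-at-max* = that level's charge, ties broken toward the lowest
  charge, which makes the dynamic range conservative;
* *dynamic range* = charge-at-max − threshold; *DynRange80* replaces
  the max level by the first level reaching 80% of MaxFR.

A recording with no confirmed threshold gets `significant = FALSE` and
`NA` ranges; such recordings drop out of paired comparisons.

Numerical notes: the cohort path (`quantify_recordings()`) computes the
same statistics via `rowsum()` sweeps and is tested to agree with the
per-recording path; variances use the moment form guarded by
`pmax(0, ·)` against negative rounding. Degenerate inputs (missing
levels, spike times outside the interval, fewer than 3 levels) error
with stage-specific messages rather than propagating NA.

## Paired statistics

Each ramped shape is compared against the rectangular reference over
the recordings significant under **both** shapes (this intersection is
the `n` of the published tables). The test is the two-tailed Wilcoxon
signed-rank: zero differences dropped before ranking (Wilcoxon's
original treatment — the source names only the test, not the variant),
average ranks for ties, exact null distribution for n ≤ 25 (computed
by convolution over sign assignments, which stays exact under ties),
tie-corrected normal approximation with continuity correction beyond.
The n = 25 switch keeps fixture-scale p-values exactly reproducible
while the cohort scale uses the standard approximation. The in-package
implementation exists because the exact-under-ties branch is not
available in `stats::wilcox.test`; the latter serves as an independent
cross-check in the test suite, alongside a brute-force $2^n$
enumeration oracle.

`summarize_comparison()` reports mean ± sem under each shape, p, n and
the above/below-diagonal counts of the paired scattergram. DynRange80
comparisons are computed but flagged `reported = FALSE`: the published
tables do not include them.

```{r, eval = FALSE}
cfg <- run_config(n_recordings = 20, seed = 1)
res <- run_pipeline(cfg, "out")
res$summary
```

## Validation design and problem sizes

The package validates itself at sizes chosen to keep the full suite in
the low minutes on one core:

* pulse geometry: exact closed-form checks plus charge conservation
  over all 5 families × 2 polarities × 20 levels;
* threshold rule: equivalence with an exhaustive-scan oracle on 1000
  significance patterns including boundary runs at the top levels;
* parameter recovery: 5 cohorts of 100 recordings; median absolute
  threshold error against the infinite-trial criterion crossing must
  stay within one schedule step (1.5 nC). For MaxFR the estimator
  prescribed by the analysis — a max over 20 noisy level means — is
  upward-biased by construction (extreme-value bias of order one
  measurement sem), so recovery is assessed per recording against the
  measurement sem of the level mean at the maximum (across-trial
  SD/√32), requiring the median standardized error ≤ 2; a cohort-mean
  criterion would conflate this bias with estimator error at any n;
* statistical calibration: 100 null cohorts (n = 24, a realistic
  per-animal yield) must reject in 1–11% of runs at α = 0.05; 100
  cohorts with a 2.3 nC injected threshold shift at n = 106 (the scale
  of the published rectangular-vs-80° comparison) must reject in ≥ 95
  and show a below-diagonal majority for thresholds;
* signed-rank exactness: equality with the brute-force enumeration for
  all n ≤ 10 fixtures.

## Known limitations

The slope-angle scale is conventional; absolute fixed-slope amplitudes
should not be compared against hardware without fixing that scale. The
simulator's sigmoid is monotone — non-monotonic growth functions
(e.g. suppression at high charge) are not generated, though the
quantification handles them. Electrode impedance, current spread and
electrophonic responses are out of scope. The rectangular phase
duration default (21 µs) is a package choice, not a published value.
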