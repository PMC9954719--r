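# rampulse

Charge-balanced cochlear-implant pulse shapes and auditory-cortex
growth-function quantification.

Cochlear implants conventionally drive the auditory nerve with
rectangular biphasic current pulses. Because spiral ganglion neurons are
sensitive to how fast a depolarizing input rises, *ramped* pulses —
phases that rise linearly from 0 to a peak — are a candidate for more
efficient stimulation. `rampulse` is for researchers who want to
(re)run that comparison computationally: it synthesizes the pulse
families, quantifies evoked growth functions from multi-unit spike
trains, and performs the paired nonparametric shape comparison, with a
calibrated spike-train simulator providing ground truth.

## What it computes

**Pulse synthesis.** Five charge-balanced biphasic families —
rectangular (`Rec`), fixed-slope ramps (`FS85`, `FS80`) and
fixed-amplitude ramps (`FA750`, `FA500`), cathodic- or anodic-first —
across a 20-level charge schedule from 3 to 31.5 nC. With each ramped
phase rising 0 → A over t µs, one phase carries charge A·t/2 and the
pulse carries Q = A·t (1 nC = 1000 µA·µs), so:

- fixed amplitude: t = Q/A  (750 µA → 4–42 µs, 500 µA → 6–63 µs over
  the schedule)
- fixed slope: t = √(Q/s), A = √(Q·s), s = tan(angle) in µA/µs
- rectangular: A = Q/(2t) at fixed t

Waveforms can be quantized to the 25 µA current step of the
stimulation hardware (a dwell-renormalized staircase that conserves
charge to machine precision).

**Growth-function quantification.** Per recording × shape: evoked
firing rate in the [9, 45) ms post-pulse window (spikes before the
9 ms cortical latency floor are discarded), spontaneous baseline over
the last 100 ms of the 250 ms inter-pulse interval, and four
parameters — threshold (lowest level whose rate exceeds baseline + 3 SD,
confirmed by two consecutive significant successors), maximal evoked
rate (MaxFR), charge at MaxFR, dynamic range — plus DynRange80.

**Paired statistics.** Each ramped shape versus the rectangular
reference over recordings significant under both, with a two-tailed
Wilcoxon signed-rank test (exact null for n ≤ 25, ties handled;
tie-corrected normal approximation beyond) and above/below-diagonal
counts of the paired scattergram.

**Simulation.** Poisson multi-unit activity with a sigmoid
charge-to-rate transfer, truncated-normal evoked latencies, and
shape effects (sigmoid midpoint shift, asymptote gain) calibrated to
the published cohort comparisons — with the generating parameters
returned for recovery testing.

## Worked example

```r
library(rampulse)

# solve and synthesize the 750 uA fixed-amplitude pulse at full charge
fa750 <- pulse_shape_spec("fixed_amplitude", "cathodic", peak_amplitude_uA = 750)
solve_phase(fa750, 31.5)$phase_duration_us
#> [1] 42

synthesize(fa750, 31.5, quantize = TRUE)
#> <waveform> FA750-C, target 31.5 nC, realized 31.5 nC (imbalance 0 nC)
#>   60 samples at 1.355 us, quantized to 25 uA

# simulate a small paired cohort, quantify, compare
cfg <- run_config(n_recordings = 12, shapes = c("Rec-C", "FS80-C"), seed = 1)
res <- run_pipeline(cfg, "out")
res$summary[, c("parameter", "n", "mean_ref", "mean_shape", "p_value", "above", "below")]
#>          parameter  n mean_ref mean_shape  p_value above below
#> 1        max_fr_Hz 11    72.34      87.11 0.000977    11     0
#> 2     threshold_nC 11    16.23      12.27 0.000977     0    11
#> 3 charge_at_max_nC 11    27.00      24.82 0.270508     4     7
#> 4     dyn_range_nC 11    10.77      12.55 0.476562     5     3
#> 5   dyn_range80_nC 11     3.68       5.59 0.203125     6     3
```

Eleven of the twelve simulated recordings respond significantly under
both shapes. The ramped shape raises the maximal evoked rate (all 11
pairs above the identity diagonal) and lowers the threshold (all 11
below), while the dynamic range is not systematically changed — the
qualitative fingerprint the shape effects were calibrated to.
`run_pipeline()` also writes the waveform geometry, spike events,
per-level growth functions, per-recording parameters, the comparison
table (TSV + Markdown) and a JSON log carrying the seed and a
configuration hash.

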