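# surro4dct

Analysis tools for comparing two synchronized external respiratory
surrogates — an infrared marker-block channel (RPM-style, millimetres at
30 Hz) and a pneumatic bellows belt (arbitrary pressure units at
~38 Hz) — in the context of retrospective phase-based 4D CT sorting.

It is written for medical-physics workflows in which both surrogate
signals are recorded simultaneously with the scanner's X-RAY ON flag,
and the question is whether the choice of surrogate changes the sorted
4D CT, the maximum intensity projection (MIP), and the target or lung
volumes delineated on it.

## What it computes

**Waveform chain.** Each channel is cropped to the X-RAY ON interval
(the mutual time origin), the bellows is downsampled onto the 30 Hz
marker-block timestamps, both are normalized to their maximum detected
end-inhale peak, and the package reports amplitude mean ± SD, the
coefficient of variation (%CV = σ/μ × 100, a breathing-irregularity
index), breathing rate (BPM), the inter-channel Pearson r, and the
inter-surrogate latency: per matched end-inhale peak pair,
Δt = t_bellows − t_rpm (positive ⇔ the marker block leads). Peaks are
local maxima found by a prominence-filtered bounding-box search; flat
(truncated/plateau) tops longer than 0.3 s are reported at the run
midpoint. Mann–Whitney U (exact for small untied samples) tests
channel differences.

**Phase sorting.** Continuous respiratory phase is linear in time
between consecutive end-inhale (0%) tags; each slice of an oversampled
helical acquisition goes to the nearest of ten phase bins (circular,
0% = end-inhale, 50% ≈ end-exhale), and per couch position the slice
closest to each bin center is selected. Empty (position, bin) pairs
are flagged as sorting artifacts.

**Image metrics.** MIP = voxelwise maximum over the ten phase volumes.
Segmentations are compared with

- DSC = 2|A∩B| / (|A|+|B|),
- OI = |A∩B| / |A| (A = accepted volume),
- percent volume change = (V_A − V_B)/V_A × 100,
- centroid differences (x lateral, y anterior–posterior, z
  superior–inferior, mm), and
- percent difference from the ground-truth internal target volume,
  ITV_TRUE = union of the object masks at end-inhale, end-exhale and
  mid-position.

**Digital phantom.** A programmable moving phantom (lung-density slab,
−800 HU, with high-contrast inserts) driven by regular or irregular
raised-cosine-power breathing, imaged by a simulated low-pitch helical
acquisition, with both surrogate channels synthesized from the same
chest-wall motion (independent gain, lag, noise, sampling rate, and
optional low-amplitude plateau clamping). This provides ground truth
for validating every step end to end.

## Worked example

```r
library(surro4dct)

prog   <- make_breathing_curve("irregular", study_program_params(3), seed = 3)
traces <- synthesize_surrogates(prog,
            bellows_model = surrogate_model(gain = 2.5, lag_ms = 100,
                                            sampling_rate_hz = 38),
            seed = 4)
wf <- compare_waveforms_report(traces$rpm, traces$bellows)
wf$stats
#>   surrogate  amp_mean    amp_sd cv_percent      bpm pearson_r
#> 1       rpm 0.2817136 0.2840024   100.8125 15.61644 0.9852784
#> 2   bellows 0.2810354 0.2836988   100.9477 14.79452 0.9852784
wf$latency
#> <latency_summary> 18 pairs: mean 98.8 ms, sd 5.1 ms, range [78.7, 103.1] ms
```

Both channels see the same normalized waveform (r = 0.985 once the
100 ms bellows lag decorrelates them slightly), and the latency
pipeline recovers the injected lag: mean +98.8 ms, positive because
the marker-block channel leads.

A full synthetic sorting experiment:

```r
res <- run_phantom_study(seed = 3, program_params = study_program_params(3))
res$comparison
#> <similarity_report> 24.75 vs 24.75 cc (+0.00%), DSC 1.000, OI 1.000
#>   centroid delta (x, y, z): (0.00, 0.00, 0.00) mm
res$diff_rpm_percent
#> [1] 11.85897
```

With identical underlying motion and noise-free channels the two
surrogates sort to the same target (DSC = 1), while the MIP-derived
ITV falls 11.9% short of ITV_TRUE — the sorting-artifact volume loss
that grows with breathing irregularity.

The bundled reference-study tables can be recomputed with
`reference_study_stats()`, which reports each derivable population
statistic (e.g. the %CV vs ITV-shortfall correlation r = 0.74 for the
marker-block channel) beside its printed value.

A command-line front end is installed as `exec/surro4dct` with
subcommands `simulate`, `compare-waveforms`, `phantom-study`, `mip`,
`metrics`, and `tables`.

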