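---
title: "Dual-surrogate 4D CT analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-surrogate 4D CT analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surro4dct)
```

## The problem

Respiratory-correlated (4D) CT oversamples each couch position over at
least one breathing cycle and retrospectively sorts the slices into
respiratory phases using an external surrogate of breathing — commonly
an infrared-tracked marker block on the abdomen (millimetres, 30 Hz)
or a pneumatic bellows belt (pressure in arbitrary units, ~38 Hz).
Whether the choice of surrogate changes the sorted images, the maximum
intensity projection (MIP), and the volumes delineated on them is a
practical commissioning question. This package implements the full
comparison chain for two synchronized surrogate channels and a digital
moving phantom that provides ground truth for validating it.

## Waveform model and synchronization

Both channels record the scanner's X-RAY ON flag, which serves as the
mutual time origin: `crop_to_beam_on()` keeps the first contiguous
beam-on run and re-zeroes time, and all statistics are computed over
beam-on samples only. Because the channels sample at different rates,
the faster bellows channel is linearly interpolated onto the
marker-block timestamps (`resample_to()`); linear interpolation of a
band-limited breathing signal at 30 Hz leaves errors far below the
other uncertainties in the chain (the test suite bounds it at <0.5% of
amplitude for a 4 s sine).

The channels report different physical quantities, so amplitudes are
made comparable by dividing each channel by the amplitude of its
tallest detected end-inhale peak (`normalize_to_max_peak()`). Dividing
by the tallest *peak* rather than the largest single sample makes the
normalization robust to isolated noise spikes; this choice is one the
underlying acquisition convention leaves open, and it is deliberately
explicit here.

## End-inhale peak detection

`detect_end_inhale_peaks()` finds local maxima subject to:

- **minimum prominence**, default 10% of the amplitude range — rejects
  cardiac ripple and noise bumps;
- **minimum separation**, default 1.5 s — one peak per breathing cycle
  for rates up to about 22 breaths per minute, while a 7 BPM breather
  is unaffected;
- **plateau midpoint rule**: when the maximal run of samples within 2%
  of the local maximum lasts longer than 0.3 s (a truncated or
  flat-topped peak, as a slack bellows belt produces), the peak is
  placed at the run's temporal midpoint;
- **quadratic refinement**: sharp peaks are refined to sub-sample
  precision by the vertex of the parabola through the discrete maximum
  and its neighbours;
- **pre-smoothing**, default 0.4 s moving average, applied only to the
  series used for localization. Breathing cycles last seconds, so a
  0.4 s window passes the signal essentially unchanged while shrinking
  the position jitter of noisy broad tops from hundreds of
  milliseconds to a few tens. Raw amplitudes are always used for
  normalization and amplitude statistics.

Latency between the channels is summarized over greedily matched
nearest-neighbour peak pairs (each peak used once, offsets capped at
half the median breathing period to avoid cross-cycle matches) as
`t_bellows − t_rpm` in ms, so a positive mean means the marker-block
channel leads. The acquisition literature states this convention both
ways; the package fixes the sign as above and prints it in every
latency export.

## Phase assignment and slice sorting

Phase is *time-based*: linear from 0 at one end-inhale tag to 1 at the
next, so 50% falls at end-exhale for symmetric cycles. Automatic tags
are the detected peaks (at least two, more than 1 s apart);
`edit_tags()` supports the manual add/remove corrections clinical
practice requires, with an audit trail. Times before the first or
after the last tag have no cycle context and are excluded rather than
extrapolated.

Binning is circular over ten bins {0%, 10%, …, 90%}: a fraction of
0.98 is nearer to the cycle start than to 90% and lands in bin 0
(threshold 0.95), and an exact interior midpoint breaks toward the
lower bin for determinism. Slice sorting assigns each slice to the bin
of its continuous phase and, per couch position and bin, selects the
member slice circularly closest to the bin center — a closest-phase
rule, chosen over first-acquired because it minimizes the phase error
of the selected slice; the rule is recorded in the study output.
Empty (position, bin) pairs are flagged as sorting artifacts and the
corresponding voxels stay `NA`, which the MIP then ignores.

## The digital phantom and surrogate synthesis

The synthetic study emulates a programmable motion platform
translating a lung-density slab (−800 HU, within the −900 to −600 HU
band used for lung thresholding) with a high-contrast spherical insert
superior–inferiorly, while a chest-wall platform drives both
surrogates anterior–posteriorly at 0.3 × the S-I amplitude (the
coupling ratio is not a measured quantity; 0.3 is a representative
surface-to-target ratio and is configurable).

Breathing is a raised-cosine-power cycle, `A·cos^4(πt/T)`, which
spends most of the cycle near end-exhale as real breathing does and
yields an amplitude %CV near 97% for the regular case — inside the
63–155% range such studies report. Irregular programs draw each
cycle's period and peak amplitude from mean-one lognormal jitter
(specified as a CV in percent) and can add a linear baseline drift;
the amplitude envelope interpolates between consecutive end-inhale
peaks so displacement stays continuous across cycles. The eight
frozen `study_program_params()` cases span amplitudes 0.5–2.5 cm and
amplitude jitter 5–65% at 15% period jitter over 75 s — nearly
periodic through erratic breathing, the spread the real study covered
with eight patient-derived curves.

Surrogate channels sample the chest-wall displacement with their own
gain, lag, white Gaussian amplitude noise, sampling rate, and an
optional plateau floor that clamps low excursions (the bellows
truncates extreme low positions when the belt goes slack). The beam
window starts on an integer second so the X-RAY ON rising edge falls
exactly on a sample of both a 30 Hz and a 38 Hz channel, as hardware
that latches the TTL flag per sample behaves.

The acquisition model is purely geometric: the couch advances at
`detector width × pitch / rotation period` (default 20 mm × 0.07 /
0.5 s, i.e. a dwell of ~7 s per position, comfortably more than one
4 s breathing period), and each slice under the detector at each
rotation images the phantom shifted by the instantaneous S-I
displacement with nearest-neighbour resampling. No projection physics,
partial-volume blur, scatter or reconstruction kernels are modelled:
the questions at stake concern sorting and delineation, not
reconstruction fidelity, and this is what passing tests do and do not
show about real scanner data. Likewise the synthetic channels share
one noiseless driving signal, so the near-perfect inter-channel
correlations of the default study (r ≈ 1) bound, rather than
reproduce, the 0.88–0.999 range seen with two physically different
sensors on a patient.

Ground truth is `ITV_TRUE`: the union of the object mask at
end-inhale (maximum displacement), end-exhale (minimum), and their
midpoint — the envelope a platform paused at those three positions
would yield. For irregular curves the extremes are taken over the
beam-on window. An intermediate sphere position can protrude laterally
from this three-position union by at most `sqrt(r² + (A/4)²) − r`
(sub-voxel for the default geometry), which is why the MIP-derived ITV
is required to stay within one voxel layer of `ITV_TRUE` rather than
strictly inside it.

## Numerical and statistical choices

- Sample standard deviation (n−1) everywhere; %CV = σ/μ × 100 with a
  zero mean raising an explicit error.
- Breathing rate = detected peaks per beam-on minute.
- Pearson correlation via the standard product-moment estimator with
  explicit zero-variance errors.
- Mann–Whitney U from midranked rank sums; exact two-sided p when the
  pooled sample is ≤ 20 without ties, otherwise the normal
  approximation with tie and continuity corrections. The exact branch
  is verified against full enumeration of all label assignments up to
  6 + 6 in the test suite.
- Voxel geometry: physical position = origin + (0-based index + 0.5) ×
  spacing; x lateral, y anterior–posterior, z superior–inferior.
  Connected components use 26-connectivity; the lung flood fill uses
  6-connectivity so it cannot leak through voxel corners.
- Degenerate inputs fail loudly: all-off beam flags, empty peak lists,
  zero-variance correlations, empty masks and mismatched grids raise
  errors naming the failed stage.

## Problem sizes

The test and acceptance runs use 45–75 s programs sampled at 100 Hz, a
32 × 32 × 40 phantom grid at 3 × 3 × 2.5 mm, and eight study cases
plus twenty seeds per injected-lag setting. These sizes were chosen so
a complete end-to-end study takes well under a second while every
property under test (phase coverage, containment, recovery to within
one 30 Hz sample) is already binding at this scale; results are
geometry-dependent in magnitude but not in direction.

## Known limitations

- No amplitude-based (as opposed to phase-based) binning.
- No DICOM-RT, dose, or deformable-registration support; NIfTI is the
  only volume format.
- The simplified lung segmentation assumes air fully enclosed by body
  voxels on the grid; lungs touching the volume boundary are treated
  as outside air.
- Manual contour adjustment after thresholding is out of scope;
  thresholds are exact, so segmentation comparisons on synthetic data
  are sharper than a clinical delineation study would be.
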