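---
title: "Cue-cell analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cue-cell analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuemap)
```

# The problem

During navigation along a virtual linear track, a subpopulation of medial
entorhinal cortex (MEC) neurons fires preferentially near prominent visual
landmarks ("cues") rather than tiling space like place or grid cells.
`cuemap` implements the complete analysis chain for discovering and
characterizing these **cue cells**: occupancy-normalized rate maps,
shuffle-based firing-field detection, the **cue score** with its
side-specific and bilateral variants, the classic open-arena scores (grid,
border, head direction, split-half stability), population sequence
statistics, cue-removal perturbation analysis, and a calcium-imaging
branch. A synthetic-data module generates sessions with ground-truth
labels so every stage is testable without any recording on disk.

# Data model and conventions

A **track session** holds a trajectory sampled at 50 Hz (time, position on
a track of length 8–18 m), integer run labels (incremented at each
teleport back to the track start, detected as a backward jump of more than
half the track length), and per-unit spike times or per-cell dF/F traces.
An **arena session** holds 2D position and head direction in a 0.5 m
square box. Spatial bins are half-open, 0-based intervals
`[(i-1)*w, i*w)`; track bins are 5 cm, arena bins 2.5 cm, angular bins 3
degrees. Spikes are assigned to the nearest preceding trajectory sample.
All files are UTF-8 tab-separated tables with headers; numeric columns
round-trip bit-exactly.

# Rate maps and velocity gating

Instantaneous speed is boxcar-averaged over 1 s; only samples with
smoothed speed above 1 cm/s contribute to any rate estimate, and spikes
inherit the mask of their enclosing sample. Binned spike counts and
occupancy are smoothed *independently* and then divided:

* track: 3-point Gaussian, sigma = 1 bin;
* arena: 5 x 5 bin Gaussian, sigma = 1 bin; bins with less than 0.3 s of
  raw occupancy are undefined;
* head direction: 5-bin (15 degree) circular boxcar.

Kernels are truncated and renormalized at map edges (the angular domain
wraps instead). This choice — the main numerical decision the source
recipe leaves open — preserves total mass in the interior and avoids
inventing wrap-around structure on a linear track.

# Firing-field detection

The velocity-gated session is re-expressed as 100 ms chunks carrying a
spike count and the spatial bin of the mean position. The spike-count
series is circularly rotated by 100 offsets drawn uniformly between 5%
and 95% of its length (snapped to whole chunks), and a smoothed rate map
is recomputed from each rotation against the *fixed* position series, so
occupancy is preserved exactly. Each bin's p-value is the fraction of
rotations whose rate exceeds the actual rate, ties counting as not
exceeding; bins with p < 0.3 (strict) are field bins. On spatially
untuned units the flagged fraction calibrates to
`P(at most 29 of 100 rotations exceed) ~ 0.30`, which the acceptance
suite verifies on 200 homogeneous Poisson units.

# The cue score

The cue template is a binary vector with 1 in every 5 cm bin overlapping a
cue (an edge falling mid-bin marks the whole bin). Scoring a rate map
proceeds in two stages:

1. **Alignment.** Pearson correlation between rate and template at every
   lag within +-300 cm (5 cm steps), using only the overlapping segment at
   each lag; lags with fewer than 10 overlapping bins are skipped. The
   **spatial shift** is the local maximum of this lag profile nearest zero
   (boundary points count when they exceed their single neighbour;
   plateaus take the point nearest zero; equidistant peaks take the
   higher correlation). Positive shift displaces the template toward
   larger positions — a cell firing beyond each cue has positive shift.
2. **Local correlations.** The template is displaced by the shift; for
   each cue, rate and displaced template are correlated over a window
   spanning the cue plus half the cue width on each side (`ceiling(w/2)`
   bins), clipped at track ends; windows shorter than 3 bins or with a
   constant rate are excluded. The **cue score** is the mean of the
   per-cue correlations.

Because Pearson correlation is invariant under positive affine maps of
the rate, the score measures the *shape* of cue-locking, not its
amplitude; a corollary (exercised in the tests) is that a cell responding
with equal fidelity but different amplitude on two templates ties their
scores exactly.

**Thresholds.** Each cell is scored against location-shuffled templates
(same cue count and widths, placed uniformly at random without overlap and
with at least a 1-bin gap so cues never fuse; 100 per cell for spike data,
200 for imaging). All cells' shuffled scores are pooled and the threshold
is the pooled 95th percentile; cells whose real-template score strictly
exceeds it are cue cells. The acceptance suite checks the implied 5%
false-positive rate on an independent sample of 200 null cells against a
binomial 99% band.

**Side-specific and bilateral scores.** Left and right templates are
built from single-side cues. Cells passing one threshold get that side;
double passers go to the higher-scoring side. The bilateral score aligns
the cell to its preferred template at that template's own best shift S,
evaluates the other template's local-correlation mean at the same S, and
reports left minus right; single-side responders produce large absolute
values. Whether double passers are excluded before or after bilateral
scoring is left to the caller (both orders are trivial with the exposed
functions); we default to scoring all side-classified cells.

# Classic arena scores

* **Autocorrelogram**: Pearson correlation of the 2D map with itself at
  every offset over mutually valid bins (at least 20), computed with an
  FFT-based sum decomposition and pinned to a direct-loop oracle at 1e-10
  in the tests.
* **Grid score**: inner radius = min(first local minimum of the radial
  mean profile, first negative crossing, 10 cm); annuli run from
  inner + 4 bins to the autocorrelogram half-width - 4 bins; each annulus
  scores max(r60, r120) - min(r30, r90, r150) over bilinear rotations of
  the autocorrelogram, and the grid score is the maximum over annuli.
  Note this "max minus min" form is more permissive than the classic
  "min minus max" gridness; a parallel-stripe map scores near zero rather
  than negative under it.
* **Head-direction score**: rate-weighted mean vector length, with the
  von Mises closed form `R = I1(k)/I0(k)` as an exact oracle.
* **Border score**: fields are 4-connected components above 0.3 x peak
  covering at least 200 cm^2 (constants configurable); cM is the maximal
  single-wall coverage by a single field, dM the rate-weighted mean
  distance of field bins to the nearest wall normalized by half the arena
  width; score = (cM - dM)/(cM + dM).
* **Split-half stability**: Pearson correlation of the two half-session
  maps over mutually valid bins (at least 20).

Thresholds for all of these pool 100 circular spike-time shuffles per
cell, with offsets uniform in [0.5 L, 0.95 L].

**Duplicate removal.** Within a day, a pair is duplicate when arena-map
correlation + track-map correlation + an ISI-histogram similarity exceeds
2.25 (the more-spikes cluster is kept); across days, when the arena
correlation reaches 0.8 or the track correlation 0.75 (the higher arena
peak is kept). The ISI component is not fully specified by the source
recipe; we use the mean correlation of the merged train's log-binned ISI
histogram with each cluster's own, after dropping sub-refractory
(< 1.5 ms) intervals that arise from double-detected spikes. Units with
fewer than 100 spikes, track rate minima above 10 Hz, or maxima above
50 Hz are excluded up front.

# Sequences, ridge/background, and the field shuffle

Cue-cell rates normalized to their own maxima and sorted by spatial shift
form a repeated diagonal band at each cue. The **ridge/background ratio**
quantifies this: after displacing the template by the cell's shift, the
ridge is the mean rate over the 5 bins centered on each cue (even-width
cues center on the lower-middle bin) and the background is the mean over
bins at distances (half-width + 20, half-width + 30] cm from the cue
center on both sides, excluding bins inside any cue; the cell's ratio
averages over cues, and a flat rate gives exactly 1. The null
**field-shuffles** each cell: the rate vector is segmented into maximal
field and gap runs, field segments are permuted among themselves and gap
segments among themselves (preserving alternation and total length), the
shift is re-estimated, and the population mean ratio recomputed. Both the
source recipe's idiosyncratic p (shuffle means above the data mean divided
by those below) and the conventional `(above + 1)/(n + 1)` are reported;
re-estimating shifts on shuffled data mirrors how shuffled sequences are
re-sorted before display.

# Perturbation analysis

For a with-cues / missing-cues track pair the run counts are equalized by
truncating to the earliest runs, and two per-region measures are compared
cell by cell: the value of the region-restricted lag-correlation profile
at its nearest-zero local maximum, and the fraction of region bins inside
firing fields. Region boundaries are configurable bin intervals (they are
figure-defined in the source, not printed numbers); the natural default
used in the tests ends Region A at the last shared cue. A paired
one-tailed t-test (with-cues greater) quantifies the contrast; on
synthetic populations Region B is strongly positive while Region A stays
inside the two-sided 95% band around zero.

# Imaging branch

dF/F is `(F - F0)/F0` with F0 a rolling 8th-percentile baseline (window
configurable, 30 s default) — the baseline estimator is our choice,
consistent with the usual practice for GCaMP traces, since the source
recipe does not pin it down. Significant transients are excursions above
k sigma lasting at least d seconds, with (k, d) chosen per cell over
k in {2, 2.5, 3, 3.5, 4} and d in [0.2, 1] s as the least strict pair for
which matching negative-going excursions number at most 1% of positive
events. In/out-of-field periods per 5 cm bin use 1000 circular rotations
of the dF/F trace (offsets uniform in [0.05 N, 0.95 N] samples): in-field
periods are runs of at least 3 adjacent bins with p <= 0.2 (2 suffice at
the track ends) in which at least 10% of runs contain a transient
*overlapping* the period (overlap rather than onset — the stricter onset
reading is not what participation means for slow indicators); out-of-field
periods are runs of at least 2 bins with p >= 0.75. Candidate cue cells
need one of each. The cue-score path for imaging feeds mean-dF/F-per-bin
vectors through exactly the same scoring functions as spike rates.

Cross-environment analysis pairs the same cells on two tracks: the
fraction of track-A cue cells that are cue cells on track B (likewise
non-cue), against a band (mean +- SD) from 50 random reassignments
preserving per-track class counts, plus the Pearson correlation of the
paired spatial shifts.

# The synthetic-data generator

The generator emulates the study's recording conditions and is the basis
of every calibration: 8–18 m tracks sampled at 50 Hz with
Ornstein-Uhlenbeck speed (mean 15 cm/s) and occasional sub-1 cm/s pauses
that exercise the velocity gate; a 0.5 m arena foraging walk (reflected
random walk with OU speed) that occupies over 95% of 2.5 cm bins for at
least 0.3 s within 20 minutes; and head direction equal to movement
heading plus an independent slow head-scanning offset (OU, 45 degree
spread, 2 s timescale) — slaving head direction to movement would give
wall-locked cells spurious directional tuning through the
wall-conditioned heading distribution, which real head scanning
decorrelates.

Tuned classes: cue cells place one Gaussian field (sigma 10 cm, peak
10 Hz over a 0.5 Hz baseline, per-cue amplitude jitter 15%) at each cue
center displaced by a per-cell shift drawn in +-20 cm; grid cells use a
thresholded three-cosine interference pattern with spacing drawn in
30–40 cm — spacings much beyond 45 cm put the six-peak autocorrelogram
ring outside every admissible annulus of a 0.5 m arena map, making such
cells undetectable by construction, so the default samples the dorsal-MEC
module range the arena can resolve; border cells decay exponentially
(6 cm scale) from one wall; head-direction cells are von Mises (kappa 4);
untuned cells fire homogeneously at 2 Hz. Spikes come from an
inhomogeneous Poisson thinning along the trajectory; calcium traces
convolve spikes with a difference-of-exponentials kernel (50 ms rise,
400 ms decay) plus Gaussian noise.

What the generator does *not* emulate — theta modulation, bursting,
behavior-dependent rate remapping, slow drift, optical crosstalk —
bounds what passing tests show: calibrations and recoveries demonstrate
the implementation is correct and well calibrated under Poisson
statistics, not that the biological claims hold for any particular
recording.

# Problem sizes and determinism

Every stochastic routine takes a seed; the pipeline driver derives
per-stage seeds from one master seed, stamps outputs with a configuration
hash, and reproduces byte-identical files on re-runs. The test suite runs
the calibrations at the study's scale where that is what is being
verified (200 null cells for the threshold calibration, 200 Poisson units
for field detection, an 80-cell mixed population with 30-minute track and
20-minute arena sessions for class recovery) and at reduced scale (fewer
runs, 10–60 shuffles) for unit-level properties, a balance chosen so the
whole suite exercises the full pipeline in well under half an hour on one
core.

# Known limitations

* The grid score follows the permissive max-minus-min rotation contrast;
  scores are not comparable numerically to the classic gridness variant.
* The within-day duplicate ISI term is an interpretation (documented
  above) of an under-specified recipe component.
* Region A/B boundaries for perturbation analysis must be supplied by the
  user for real recordings; no figure-derived constants are hard-coded.
* The transient detector assumes approximately stationary noise; traces
  with strong slow artifacts should be detrended before `compute_dff`.
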