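---
title: "Staging cornification events in 3D time-lapse imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging cornification events in 3D time-lapse imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

In stratified epidermis and in reconstructed epidermal-equivalent models,
the uppermost granular keratinocytes transform into flat, anucleate
corneocytes. Live two-photon imaging of dye-labelled models resolves this
transformation into a reproducible sequence of events per cell:

1. **Vesicle arrest** — acidic vesicles (LysoTracker-class dyes), which
   normally move fast enough to occupy different positions in neighbouring
   frames, suddenly stop;
2. **Onset of the morphological change** — the cell begins to expand in z;
3. **Maximum expansion** — the z-extent peaks (about 1.4x baseline in our
   reference conditions);
4. **Flattening** — the cell collapses to roughly one axial step;
5. **DNA leakage** — minutes after flattening, nuclear-dye signal appears
   radially outside the nuclear region, read here as nuclear-envelope/lamina
   collapse.

cornitrack turns each event into an operational detector on calibrated
`(T, C, Z, Y, X)` stacks, reports per-cell event times and the four
inter-event intervals, and summarizes cohorts (mean ± SD, Wilcoxon rank-sum
comparisons between conditions, onset events per hour). A fourth channel
carrying a mitochondrial potential dye supports the orthogonal
classification of granular cells into four morphology groups (small/punctate
through large/elongated) and their cross-tabulation against the
four-hour flattening outcome.

Because no raw imaging data are deposited with the study this package is
modelled on, every detector is validated against a synthetic
ground-truth generator (below) rather than against archived acquisitions.

## Detectors

### Vesicle arrest: frame-pair correlation

For consecutive frames of the vesicle channel restricted to a cell ROI,
the Pearson coefficient

$$ r = \frac{\sum (a-\bar a)(b - \bar b)}
           {\sqrt{\sum(a-\bar a)^2\,\sum(b-\bar b)^2}} $$

is low while vesicles move (structures decorrelate between frames) and
jumps towards 1 when they stop. `detect_arrest()` median-filters the
series (window 3), then calls the first pair at which r stays at or above
`threshold_r` (default 0.6) for `sustain_frames` pairs (default 3, about
6 min at 2-min sampling), provided the median of all preceding pairs is
below the threshold — a moving baseline must exist. Absence is a valid
outcome, not an error.

The raw rule is quantized to whole pairs and systematically late: a pair
that straddles the freeze can already exceed the threshold. For diffusing
Gaussian puncta with per-frame step SD $s$ and punctum width $\sigma$, a
pair whose gap is spent moving for a fraction $f$ has expected correlation

$$ r(f) \;=\; \frac{r_p}{1 + f\,\beta}, \qquad
   \beta = \frac{r_p}{r_b} - 1, $$

the Gaussian-overlap $e^{-d^2/4\sigma^2}$ averaged over the
$\chi^2$-distributed squared step length; $r_p$ is the arrested plateau
(f = 0) and $r_b$ the fully-moving baseline (f = 1). Since $1/r$ is linear
in $f$, the default refinement fits the freeze time by weighted least
squares of $1/r$ over the pairs bracketing the call (weights $r^2$, the
delta-method variance of $1/r$). We first tried the log-linear chord
between $\log r_b$ and $\log r_p$; it is provably convex-biased and
mislocated the freeze by a quarter of a frame on simulated cells, which is
why the harmonic model is the default. `refine = FALSE` returns the raw
pair time.

### Onset, maximum expansion, flattening: the thickness series

`cell_thickness()` computes the per-z mean intensity profile of the
cytoplasm channel over the ROI footprint, thresholds it at half of its own
maximum, and takes the longest contiguous run. The threshold is relative
on purpose: the cytoplasmic dye visibly dims during the morphological
change and brightens after flattening, and an absolute threshold would
confound brightness with geometry. Beyond the integer run length
(`thickness_um`, the value matching the slab convention: an 11-slice run
at 0.6 um is 6.6 um), a partial-volume refinement weights the run's edge
slices by their relative intensity, recovering sub-slice extent
(`thickness_pv_um`); the staging rules below operate on it.

`stage_morphology()` applies three rules to the series:

* **onset** — first frame at `onset_factor` (default 1.10) times the
  pre-event baseline (median of pre-crossing frames), sustained 2 frames;
* **maximum expansion** — argmax between onset and the first return below
  baseline, tie plateaus averaged;
* **flattening** — first frame at or below `flatten_um` (default two
  z-steps, 1.2 um: true corneocyte thickness of 0.2-0.5 um is below the
  axial sampling, so the detector uses the smallest measurable band),
  sustained 2 frames, after the maximum.

A 1.10x threshold on a linear expansion ramp is crossed about a quarter of
the way up — roughly +2.3 min at the reference expansion rate, larger than
the recovery tolerance we hold ourselves to — so the default refinement
back-extrapolates a line fitted through the monotone rising segment to its
baseline intersection (onset), intersects lines fitted to the two flanks of
the expansion tent (maximum: the discrete argmax of a tent with a shallow
rise and steep fall is biased toward the shallow flank), and intersects the
collapse ramp with the post-flattening floor (flattening). All raw rule
times remain available (`*_raw`, `refine = FALSE`).

### DNA leakage: the perinuclear ring

`nuclear_series()` segments the nucleus in the ROI sub-volume by Otsu
threshold and 26-connected components, tracks it by maximal overlap with
the previous mask (ties to the larger component), and measures the mean
intensity in an xy ring around the nuclear footprint. Two geometric
choices matter and are config-exposed:

* the ring is separated from the mask by `ring_gap_px` (default 3): the
  half-max segmentation mask underestimates the true nuclear boundary, so
  a flush ring sits on the nuclear intensity tail and responds to nuclear
  shape changes rather than leaked dye;
* the ring spans the full z-range by default (`ring_z = "all"`): the
  nuclear z-extent collapses abruptly at flattening, and a ring tied to
  the nucleus' slices jumps at that moment for purely geometric reasons.
  Both failure modes produced spurious leakage calls at the flattening
  frame in simulation before these defaults were adopted.

`detect_leakage()` takes the ring baseline (mean, SD) over pre-flattening
frames and calls leakage at the first frame at/after flattening where the
ring mean exceeds `baseline + max(k_sd * SD, min_rise)` sustained 2 frames
(`k_sd = 3`; `min_rise = 0.5` guards against a near-zero baseline
variance). The refined time is the midpoint of the straddled frame gap.

### Mitochondrial morphology groups

`segment_mito()` (Otsu within the ROI, 3D 26-connected components, minimum
4 voxels) feeds `mito_features()`: total volume in physical units,
per-component elongation as the ratio of the largest to the middle
principal axis of the second-moment ellipsoid (moments computed in
physical coordinates, so anisotropic voxels are handled; the voxel's own
second moment is added so single-voxel components are well-posed), and the
volume-weighted punctate fraction (elongation < 2.5). `classify_group()`
maps profiles to the four-group taxonomy: small amount & punctate (1),
small amount & mixed (2), moderate (3), large (4); boundaries go to the
lower-numbered group, and a zero-volume profile is group 1 (vacuously
all-punctate). The volume cutoffs (`v_small = 12`, `v_moderate = 30` um^3)
are calibrated on segmented synthetic cells — an Otsu component includes
the resolution-blurred skirt of the organelle, roughly three times the
bare geometric volume — because the underlying taxonomy is qualitative
("small/moderate/large amount") and carries no printed numeric boundaries.
Classification conventionally uses the first observation frame;
`flattening_outcome()` (flattened within 240 min) and `contingency()`
build the 4 x 2 group-by-outcome table with per-group flattened
percentages.

`mito_disappearance()` times the abrupt loss of potential-dye signal in
small sub-ROIs (baseline mean − 3 SD, sustained 2 frames) and reports its
co-timing against vesicle arrest.

### Preprocessing

Drift is modelled as rigid xy translation only. `estimate_drift()` works
on the max-intensity z-projection of the cytoplasm channel (brightest,
most persistent structure) by Hann-windowed phase correlation with
parabolic sub-pixel peak refinement. Because the projections are
low-texture (a nearly uniform disk), the whitened spectrum occasionally
throws an isolated 1-2 px outlier, and per-frame jitter would itself
decorrelate neighbouring frames if applied as a correction; the trace is
therefore despiked (Hampel filter, window 5) and smoothed with a running
local-linear fit (window 7) that is exact on constant-velocity drift,
including at the ends of the series — both steps justified by the
slow-drift assumption and switchable off. `apply_drift()` resamples each frame
(bilinear by default), fills out-of-field voxels with 0 and records them
in a validity mask that every downstream statistic respects (correlation
pairs drop voxels invalid in either frame). `denoise()` provides the
usual median/Gaussian slice filters; the default analysis path does not
denoise, because every detector already aggregates over many voxels.

### Statistics

`summarize_durations()` reports mean and sample SD (n−1) per interval over
cells where both endpoints exist; intervals are excluded per-interval, not
per-cell, and negative values within one frame interval (quantization
slack) are clamped to zero with a message. `wilcoxon_rank_sum()` performs
the two-sided rank-sum test — exact by enumeration when tie-free and
n + m ≤ 25, otherwise the tie-corrected normal approximation with
continuity correction; requesting exact with ties is an error rather than
a silent approximation. Stars follow the *<0.05, **<0.01, ***<0.001
legend. `events_per_hour()` is the onset count normalized per observed
field-hour (whether such rates should be normalized per field or per cell
population is ambiguous in this assay class; the per-field-hour convention
is documented here and used throughout).

## The synthetic generator

`sim_config()` + `sample_timeline()` + `build_phantom()` + `render_stack()`
produce single-cell (or small multi-cell) crops with complete ground
truth. The defaults are the package's reference study conditions:

| parameter | default | meaning |
|---|---|---|
| `frame_interval_min` | 2 min | acquisition cadence of the duration statistics |
| `z_step_um` | 0.6 um | axial step |
| `xy_pixel_um` | 0.25 um | lateral sampling |
| `stack_shape` | 44 x 17 x 48 x 48 | frames x z x y x x per cell crop |
| `interval_params` | 2.3/3.1, 9.2/3.3, 9.0/3.0, 3.9/4.7 min | mean/SD of the four inter-event intervals |
| `leak_probability` | 21/22 | flattened cells showing DNA leakage |
| `group_probs` | 84:82:126:191 / 483 | mitochondrial group frequencies |
| `flatten_prob_by_group` | 62/84, 23/82, 6/126, 0/191 | 4-h flattening odds per group |
| `expansion_factor` | 1.4 | peak z-extent over baseline |
| `flattened_thickness_um` | one z-step | rendered corneocyte thickness |
| `cell_radius_um`, `baseline_thickness_um` | 5, 6 um | granular-cell geometry |
| `n_vesicles`, `vesicle_step_px` | 25, 2 px/frame | vesicle count and random-walk step SD |
| `drift_per_frame_px` | (0.05, 0.03) | slow stage drift |
| `noise` | gaussian_sd 2, poisson_scale 1 | read + shot noise |

Intervals are drawn from normals truncated at zero whose parent parameters
are moment-matched to the configured mean/SD (`tnorm_match()`). A
zero-truncated normal cannot exceed a coefficient of variation of 1, so
the two intervals whose printed SD exceeds the mean (arrest-to-onset,
flattening-to-leakage) cannot have both moments matched; the fit weights
the mean 25:1 over the SD, because every downstream summary and recovery
check compares means, and the realized SDs saturate near the exponential
limit (approximately equal to the mean). This is the one deliberate
departure from the printed second moments, and it makes the realized
arrest-to-onset distribution heavily right-skewed with substantial mass
near zero — which is also why near-tie orderings of arrest and onset are
intrinsically hard to resolve at 2-min sampling.

Scene construction: an elliptical footprint (radius jittered ±10%), a
z-extent track following baseline → linear expansion → linear collapse →
flattened, with exact per-slice z-coverage so boundary slices carry
partial-volume information; a soft nuclear ellipsoid riding mid-cell;
vesicles doing an isotropic Gaussian random walk reflected at the
footprint, frozen from the arrest time on (a pair straddling the freeze
receives the diffusion-scaled partial step $\sqrt f$); mitochondrial
primitives per group (spheres and capsule rods, minimum 1.4-um center
separation so puncta do not fuse into pseudo-elongated components; group-2
rods are 3.5 um long so that "elongated structures" are actually elongated
under the rendering blur); brightness scripts encode the cytoplasmic dip
during the change and rise after flattening, the post-flattening nuclear
and vesicle fades, abrupt mitochondrial-channel extinction at onset, and a
perinuclear halo from the leakage time on. Global xy drift accumulates
sub-pixel per frame and moves every object; Poisson shot noise and
Gaussian read noise are added last. Timelines whose flattening falls
beyond the simulated duration warn and render right-censored (as a finite
real acquisition would); `strict = TRUE` makes them an error.

What the generator does **not** emulate: optical transfer (no PSF
convolution or two-photon excitation physics — organelles are rendered as
Gaussian stamps), photobleaching beyond the scripted exponential fades,
touching or overlapping cells, xy nuclear shrinkage, tissue-level context
(a single granular cell per crop, no neighbouring layers), and
segmentation-confounding structures. Passing recovery tests therefore
demonstrates that the detectors are correct and well-calibrated *for data
matching these generative assumptions*; they do not demonstrate
robustness to the full variability of real two-photon acquisitions, where
ROI drawing, cell crowding and uneven staining add failure modes the
simulator does not produce.

## Conventions and degenerate inputs

* Frame k (1-based in R) is acquired at (k−1) x frame interval, minutes;
  correlation pairs are stamped at pair midpoints; 0-based pixel
  coordinates with centers on the integer grid; axes fixed as (T, C, Z,
  Y, X).
* Constant masked images are an error in `pearson_frame_pair()` (an
  undefined correlation is never silently 0); within a series they yield
  `NA` with a warning.
* Detector absence (no arrest, no onset, no leakage) is a valid outcome;
  per-cell failures (nucleus never segmentable) warn and return a failure
  record while the cohort continues.
* `stage_cell()` flags interval orderings more negative than one frame
  interval instead of reordering; cohort summaries clamp small negative
  intervals to zero with a logged count.
* Stacks are written as plain multi-page TIFF (T-major page order, 32-bit
  samples normalized to the stack maximum) with a JSON sidecar carrying
  axes, shape, calibration, channel names and scale; reading without a
  sidecar requires an explicit shape and warns while falling back to the
  documented default calibration.

## Reference problem sizes

Cohort-level checks in this package use 200 cornifying cells at the
default conditions for interval recovery and event ordering, and 400
first-frame renders for group classification; per-cell crops are
44 frames x 17 z x 48 x 48 px at 0.25 um/px. These sizes give sub-0.3-min
standard errors on recovered interval means and a few-percent binomial
error on classification agreement.

## Known limitations

* The onset rule is a declared proxy for a visual call; it is validated
  only against the simulator (the underlying study read events by eye and
  states no numeric criterion).
* Arrest-to-onset gaps shorter than the estimator resolution (~0.2 min)
  cannot be ordered reliably; a few percent of recovered timelines invert
  arrest and onset by a fraction of a frame.
* Drift correction is rigid xy only — no z-drift, rotation or non-rigid
  deformation.
* The group classifier's volume cutoffs are simulator-calibrated; on real
  data they should be re-derived from a reference population (e.g. lower
  granular layer cells in the same stack) before use.
* Whether the vesicle correlation should be computed on one optical
  section or a sub-volume is not fixed by the assay; the ROI z-range
  parameter leaves the choice to the user (full volume by default, since
  vesicles move in 3D).
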