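# cornitrack

Event staging of keratinocyte cornification in 3D time-lapse two-photon
imaging.

In live-imaged epidermal-equivalent models, the uppermost granular cells
turn into corneocytes through a stereotyped sequence: their acidic
vesicles abruptly stop moving, the cell begins to expand in z, reaches a
maximum expansion, collapses flat, and a few minutes later nuclear dye
leaks radially out of the nuclear region. cornitrack quantifies this
sequence per cell from calibrated `(T, C, Z, Y, X)` fluorescence stacks:

* **vesicle arrest** from the frame-pair Pearson correlation of the
  vesicle channel inside a cell ROI — moving vesicles decorrelate
  consecutive frames, arrested ones drive r towards 1;
* **onset, maximum expansion and flattening** from a per-cell thickness
  series (relative-threshold z-profile of the cytoplasm channel, with
  sub-frame refinement of each event time);
* **DNA leakage** from the intensity of a perinuclear ring on the nucleus
  channel;
* **mitochondrial morphology groups** (small/punctate through
  large/elongated, groups 1–4) from Otsu-segmented 3D components of the
  mitochondria channel, cross-tabulated against the 4-hour flattening
  outcome;
* **cohort statistics**: interval means ± SD, two-sided Wilcoxon rank-sum
  comparisons between conditions (exact by enumeration when legal),
  onset events per hour, and a CSV/JSON/PNG report surface.

Preprocessing covers rigid xy drift estimation (windowed phase
correlation, sub-pixel) and correction with a validity mask, optional
median/Gaussian denoising, kymographs, and TIFF stack I/O with a JSON
calibration sidecar.

Because the study design this package serves deposits no raw imaging
data, it ships a first-class synthetic generator
(`sim_config()`/`simulate_cohort()`) that renders cornifying granular
cells with complete ground truth — scripted event timelines, diffusing
vesicles frozen at arrest, a z-expanding and collapsing cell body,
post-flattening dye fades, a leakage halo, per-group mitochondrial
primitives, stage drift and shot/read noise — so every detector is
validated by parameter recovery. See the methods vignette
(`vignettes/cornification-staging.Rmd`) for the models, estimator
derivations, defaults and limitations.

## Worked example

Simulate one cornifying cell at the default study conditions (2-min
frames, 0.6-µm z-step) and recover its event timeline:

```r
library(cornitrack)

cfg <- sim_config()                     # default control conditions
set.seed(7)
tl  <- sample_timeline(cfg, 1, force_cornify = TRUE)
ph  <- build_phantom(cfg, list(tl))
r   <- render_stack(ph, cfg)            # stack + ROI + ground truth

rec <- analyze_cell(r$stack, r$rois[[1]])   # register, detect, stage
print(rec)
#> <event_timeline> cell 1
#>   t_arrest           12.88 min
#>   t_onset            13.04 min
#>   t_max_expansion    17.00 min
#>   t_flattened        24.54 min
#>   t_leakage          25.00 min

unlist(tl[c("t_arrest", "t_onset", "t_max_expansion", "t_flattened", "t_leakage")])
#>        t_arrest         t_onset t_max_expansion     t_flattened       t_leakage
#>        12.77295        13.06627        17.36489        24.26315        25.92925
```

The recovered times sit within a fraction of a frame of the scripted
truth. `rec$intervals` carries the four derived intervals
(arrest→onset, onset→max, max→flattening, flattening→leakage, minutes);
over a cohort, `summarize_durations()` gives their mean ± SD and
`build_report()` writes the tabular/graphical summary, e.g.:

```r
res <- run_recovery_cohort(cfg, 25, seed = 11)
summarize_durations(res$recovered, "onset_to_max")
#> <duration_summary> onset_to_max: 8.9 +/- 2.8 min (n = 24)
```

A thin command-line front end over the same functions is installed at
`inst/cli/cornitrack.R` (`simulate`, `register`, `arrest`, `stage`,
`mito`, `report` subcommands).

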