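# dffoct

Processing tools for **dynamic full-field optical coherence tomography
(D-FFOCT)** image time series — the label-free microscopy modality in which
contrast comes from temporal fluctuations of the interferometric signal at
each pixel, reporting on subcellular motility in living samples such as
retinal organoids.

The package covers the full desk-side computational chain, testable without an
instrument:

* **Synthetic phantoms** (`simulate_pixel_series()`,
  `simulate_phantom_stack()`, `simulate_tile_set()`,
  `simulate_stained_zstack()`): interferometric pixel fluctuations generated
  as a baseline plus a cosine fringe with Brownian phase — correlation time
  τ sets a Lorentzian-like spectrum of half-width 1/(2πτ) — plus Gaussian
  camera noise; structured multi-regime stacks, overlapping tile sets and
  stained-nuclei z-stacks, all with exact ground truth and per-pixel
  reproducible seeding.
* **Dynamic metrics** (`compute_dynamic_image()`, `bin_series()`,
  `render_hsb()`): per-pixel one-sided periodogram of the mean-removed
  series; the three contrast metrics

  $\bar f = \frac{\sum_{f>0} f P(f)}{\sum_{f>0} P(f)}, \qquad
  \sigma_f = \sqrt{\tfrac{\sum_{f>0} P(f)(f-\bar f)^2}{\sum_{f>0} P(f)}}, \qquad
  A = \langle \mathrm{sd}_{50}\rangle$

  (PSD mean frequency, PSD frequency spread, mean running standard deviation
  over 50-sample windows); temporal binning of 500 Hz acquisitions in groups
  of 5 (SNR gain √5 for white noise); HSB rendering with hue spanning
  3–13 Hz mean frequency (blue → red).
* **Mosaic stitching** (`plan_grid()`, `register_pair()`,
  `resolve_tile_positions()`, `assemble_mosaic()`): translation-only
  normalized-cross-correlation registration of overlapping stage-scanned
  tiles and feather-blended assembly.
* **Cell counting** (`count_cells()` and the step functions): maximum-
  intensity projection, two-peak histogram thresholding (threshold at the
  fitted-component intersection minimizing misclassified mass), 8-connected
  size filtering (regions > 25 px), and area-based counts using the fixed
  surface-per-cell factors (50 px at ×20, 200 px at ×40 — equivalent circles
  of radius 2.23 µm and 2.07 µm), plus colocalization and pixel-ratio
  quantification.
* **Acquisition timing model** (`acquisition_timing()`,
  `simulate_schedule()`, `pipelined_time()`, `steady_state_period()`,
  `speedup()`): closed forms and a discrete-event simulator for the
  pipelined acquisition → transfer → processing → saving workflow;
  at the measured operating point (512 frames at 100 Hz, 0.79 s, 1.34 s,
  0.53 s) the steady-state period is 5.12 s per image, a ~10× gain over the
  50.5 s sequential reference.

See the methods vignette (`vignettes/dffoct-methods.Rmd`) for the models,
conventions and design decisions.

## Worked example

Simulate a two-regime phantom (a progenitor-like regime targeted at 6.75 Hz
beside a faster 11 Hz regime), compute the three metric planes, and count
synthetic nuclei:

```r
library(dffoct)

lay <- phantom_layout(48, 48, list(
  list(rows = c(1, 48), cols = c(1, 24),
       params = pixel_dynamics("rpc", target_mean_freq_hz = 6.75)),
  list(rows = c(1, 48), cols = c(25, 48),
       params = pixel_dynamics("fast", target_mean_freq_hz = 11))))
stack <- simulate_phantom_stack(lay, n_frames = 512, fs = 100, seed = 42)
stack
#> Interferometric stack: 512 frames x 48 x 48 px @ 100 Hz
#>   intensity range [58799, 61209] counts; truth labels present

metrics <- compute_dynamic_image(stack, metric_config())
metrics
#> Dynamic metrics: 48 x 48 px (512 frames @ 100 Hz)
#>   mean frequency: median 8.93 Hz (IQR 6.83-10.99), 0 no-signal px
#>   amplitude: median 663.4 counts

round(tapply(metrics$mean_frequency_hz, metrics$truth_labels, median), 2)
#>  fast   rpc
#> 10.99  6.83

img <- render_hsb(metrics)      # rows x cols x 3 RGB in [0, 1]

zs <- simulate_stained_zstack(n_cells = 25, cell_area_px = 50,
                              image_size = 200, seed = 7)
count_cells(zs, magnification_config("x20"))
#> Segmentation: threshold 118.1, 25 region(s), total area 1250 px
#>   estimated count: 25 (x20, 50 px/cell)
```

The two regimes separate cleanly in the mean-frequency plane (medians 6.83 Hz
vs 10.99 Hz against targets 6.75 and 11), and the counting pipeline recovers
all 25 planted nuclei from the bimodal projection histogram.

A thin command-line wrapper over the same functions is provided in
`inst/cli/dffoct.R` with subcommands `simulate`, `tiles`, `nuclei`,
`dynamics`, `stitch`, `count` and `schedule`.

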