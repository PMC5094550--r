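# irtnorm

High-precision indexed retention time (iRT) normalization for targeted
analysis of data-independent acquisition (DIA) proteomics, in R.

## What it does, and for whom

In targeted DIA analysis a spectral library supplies, for every peptide
precursor, its fragment ion pattern and a normalized retention time on the
iRT scale — a dimensionless elution coordinate anchored so that a reference
peptide pair maps to iRT 0 and 100. Analysis quality hinges on converting
accurately between a run's retention time (RT, minutes) and iRT: RT → iRT
when building libraries from shotgun runs, iRT → RT when scheduling the
extraction windows of a DIA run. A classical whole-gradient linear
calibration on 11 kit peptides cannot follow local gradient non-linearities;
this package implements the high-precision alternative for computational
proteomics developers and pipeline builders:

* **Segmented regression** (`build_segmented_model`, `predict`): anchors are
  sorted and split into overlapping equal-count bins of
  `max(round(n/40), 20)` points (half overlap, last bin right-aligned); per
  bin a robust **Theil–Sen** line is fitted — slope = median of pairwise
  slopes (y_j − y_i)/(x_j − x_i), intercept = median of y_i − â·x_i — and the
  bin contributes a knot at (median x, fitted y). Knots are joined by line
  segments with linear edge extrapolation. Below `min_anchors` (200 for
  library generation, 50 for DIA) a single global Theil–Sen line is used.
* **iRT scale calibration** (`two_anchor_calibration`,
  `extend_calibration_set`): the exact line mapping the two scale peptides'
  RTs to 0 and 100, and construction of extended anchor databases from
  replicate runs (complete-in-all-runs filter, per-precursor mean/SD, 20
  equal-width RT bins, lowest-SD 80% kept per bin, kit peptides exempt).
* **Dynamic extraction windows** (`build_window_model`, `window_at`):
  sliding bins of `round(n/log2(n))` anchors along iRT summarize the median
  peak width `w` and the 75th percentile `q` of absolute RT residuals; the
  reference points (mean iRT, (w+q)/2) feed the same segmented regression
  (bin size `round(m/10)`), and the emitted full window width is twice its
  prediction. Fewer than 30 anchors → fixed window.
* **Spectral library assembly** (`assemble_library`, `write_library`):
  per-run RT → iRT conversion via the calibration-database overlap, median
  consensus iRT across runs, fragment filtering (300–1800 m/z inclusive,
  ≥3 residues, 3–6 most intense kept), OpenSWATH-style transition-list TSV
  output, and monoisotopic b/y `fragment_mz` validation.
* **Synthetic precision experiments** (`generate_run`, `inject_irt_noise`,
  `evaluate_precision`, `run_precision_experiment`): ground-truth gradient
  warps (a segmented 2 h acetonitrile program and a linear preset), apex
  jitter, 1% uniform outliers, lognormal peak widths, Gaussian iRT-noise
  injection into libraries, and scoring (median |ΔiRT|, median window width,
  apex-in-window coverage).

A command-line interface (`irt_cli()`, wrapper at `inst/cli/irtnorm.R`)
exposes `calibrate`, `build-lib`, `model`, `predict`, `window`, `simulate`,
`inject-noise` and `evaluate` over TSV tables and JSON-serialized models.

## Worked example

Degrade a library's iRT precision and watch the dynamic window widen
linearly while coverage (the fraction of true apexes still inside their
extraction window) collapses:

```r
library(irtnorm)
sds <- c(0, 1, 2, 4, 8, 16)
res <- sapply(sds, function(s) {
  r <- run_precision_experiment(n = 2000, irt_noise_sd = s, seed = 1)$report
  c(delta = r$median_abs_delta_irt, window = r$median_window_width,
    coverage = r$coverage)
})
colnames(res) <- paste0("sd", sds)
round(res, 3)
#>            sd0   sd1   sd2   sd4   sd8   sd16
#> delta    0.093 0.149 0.237 0.418 0.736  1.388
#> window   0.623 1.606 2.674 4.763 8.934 15.733
#> coverage 0.992 0.674 0.569 0.508 0.469  0.451
```

With a precise library (`sd0`) the median window is 0.62 min — about one
chromatographic peak width, since in the zero-residual limit the window
equals the median peak width — and 99% of apexes are covered. The window
grows linearly with the injected iRT noise (regressing the `window` row on
`sds` gives R² > 0.99), and a global linear calibration on the segmented
gradient is beaten by the segmented fit for every seed tried (see the test
suite's 20-seed battery).

## Documentation

See `vignettes/high-precision-irt.Rmd` for the model, its assumptions,
parameter defaults with rationale, what the synthetic generator does and
does not emulate, and numerical edge cases.
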