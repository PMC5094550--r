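Package: irtnorm
Title: High-Precision Indexed Retention Time Normalization for Targeted DIA Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Robust segmented (piecewise-linear) regression between chromatographic
    retention time (RT) and the indexed retention time (iRT) scale for targeted
    analysis of data-independent acquisition (DIA) proteomics. Provides per-bin
    Theil-Sen fitting with overlapping equal-count bins, two-anchor iRT scale
    calibration and construction of extended calibration sets from replicate runs,
    dynamic iRT-dependent extraction-window width estimation, spectral library
    assembly with fragment-ion filtering and consensus iRT, and a synthetic
    chromatographic run generator with ground-truth gradient warps for precision
    experiments. Includes a command-line interface over TSV tables and JSON models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
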