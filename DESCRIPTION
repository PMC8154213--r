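Package: desiscreen
Title: Plate-Based Biocatalyst Screening by DESI Mass Spectrometry Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput biocatalyst screening by
    desorption electrospray ionization (DESI) mass spectrometry imaging of
    reaction spots arrayed on a membrane grid. Reads and writes imzML imaging
    data (optionally with an ion-mobility drift-time dimension), computes
    molecular formula isotopologue envelopes, extracts m/z-channel ion images,
    registers the plate grid, sums per-well region-of-interest intensities with
    background subtraction, fits calibration curves with limit-of-detection
    estimates, removes isotope (M+2) false positives by drift-time gating or
    arithmetic subtraction, renders RGB heat maps, calls hits, and provides
    degenerate-codon library coverage statistics for directed evolution. A
    synthetic-data generator with a ground-truth manifest stands in for the
    instrument.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
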