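Package: tomosta
Title: Subtomogram Averaging with Missing-Wedge-Aware Template Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained workflow engine for cryo-electron tomography
    and subtomogram averaging. Simulates dose-symmetric tilt series of
    density phantoms with CTF modulation and noise, reconstructs tomograms
    by weighted back-projection with Fourier-crop binning, performs
    missing-wedge-aware local-normalized 3D template matching over an
    orientation grid with chunked execution, post-processes
    cross-correlation maps and extracts particle tables, classifies
    particles by multi-reference alignment against noise-trap references,
    computes wedge-compensated averages, and estimates resolution by
    half-set Fourier shell correlation.  Includes MRC2014 volume I/O,
    plain-text particle tables, STAR metadata export, JSON-configured
    resumable pipeline execution with SUCCESS-file semantics, and a live
    reconstruction mode.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
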