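Package: quadstall
Title: RNA G-Quadruplex Thermodynamics and Translation-Stalling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the quantitative analysis of RNA G-quadruplex mediated
    ribosome stalling: two-state van't Hoff fitting of UV melting curves
    (folding enthalpy, melting temperature, free energy at 37 degrees C with
    replicate-based uncertainties), circular dichroism two-state diagnostics
    (parallel-topology signature, isosbestic point, 265/242 nm linearity), a
    first-order kinetic model of stall escape whose rate is exponential in
    quadruplex stability, an exponential model of the cleaved-to-full-length
    protein ratio versus folding free energy, sequence utilities for
    synonymous quadruplex-forming-potential variants (scanning, extinction
    coefficients, peptide masses), and a synthetic-data generator emulating
    the melting, spectral, time-course and band-intensity inputs the pipeline
    consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
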