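Package: msh5
Title: Self-Describing HDF5 Storage for Mass Spectrometry Runs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stores LC-MS/MS runs in plain ("vanilla") HDF5 with every dataset
    annotated by PSI-MS controlled-vocabulary terms, so that generic HDF5
    tooling can discover and read the data without format-specific software.
    Two layouts are provided: a flat ragged-array layout (one variable-length
    row per scan for m/z, intensity, noise and charge) and a hierarchical
    layout that mirrors MSn scan trees as nested groups. Includes an mzML
    reader and minimal writer (base64 / zlib binary-data-array codecs), base
    peak and total-ion chromatogram computation, JSON peak-list export for
    web spectrum viewers, a PSI-MS OBO parser, a synthetic LC-MS/MS run
    generator built on peptide fragment-mass arithmetic, and a command-line
    interface for conversion, inspection and extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rhdf5,
    xml2,
    jsonlite,
    base64enc,
    stats
LinkingTo: Rhdf5lib
SystemRequirements: GNU make
Suggests:
    testthat (>= 3.0.0),
    withr,
    mzR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
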