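Package: mifcontext
Title: Spatial Immune Contexture Analysis for Multiplex Immunofluorescence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for compartment-resolved analysis of multiplex
    immunofluorescence (mIF) cell detections in solid tumors, modelled on
    colorectal cancer. Delineates the tumor center (TC) and the 1 mm
    invasive margin (IM) around the tumor-stroma interface, quantifies
    per-phenotype cell densities (cells/mm2) over representative 1 mm2
    fields, counts CD8+/PD-L1+ proximity events within a configurable
    radius (default 20 micrometres), and computes cohort-relative composite
    scores: the Immunoscore (0-4, from CD3+ and CD8+ densities in TC and
    IM) and a CD8/PD-L1 composite (0-6, from CD8+ density, PD-L1+ density
    and their spatial proximity in both compartments). Includes a
    marked-point-pattern cohort simulator with known ground truth, the
    paired, group-wise and correlation statistics used in immune-contexture
    studies, and a seeded end-to-end pipeline with a reproducible manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
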