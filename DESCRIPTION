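Package: ccdose
Title: Collapsed-Cone Convolution/Superposition Photon Dose Engine and QA Comparison Tools
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A CPU desk-scale superposition/convolution photon dose engine for
    radiotherapy quality assurance: multi-source treatment-head fluence
    modelling through jaws and MLC, polyenergetic TERMA ray tracing with
    heterogeneity-corrected radiological paths and beam hardening,
    collapsed-cone superposition with a cumulative-cumulative
    energy-deposition kernel, density scaling and kernel tilting, and an
    optional heterogeneity-compensated density pre-filter. Ships synthetic
    phantom and plan generators (water cube, lung slab, anthropomorphic
    thorax; square fields, multi-beam and arc plans) and the comparison
    instruments used to validate such engines: 3D gamma analysis with global
    or local normalization and low-dose cutoff, central-axis depth-dose
    extraction, ROI mean dose, and body-surface exclusion masks. Reads and
    writes a DICOM RT Dose subset and a simple self-describing grid format.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: C++17
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
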