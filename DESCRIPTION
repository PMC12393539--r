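Package: ciliovem
Title: Quantitative 3D Morphometry of Ciliogenesis Membrane Intermediates
    from Volume Electron Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for isotropic volume electron microscopy
    (FIB-SEM) label volumes of the mother centriole and its associated
    membranes during primary ciliogenesis. Fits the centriole reference
    frame, locates distal-appendage tips, detects and filters membrane
    components, measures docking distances, C-shape gap angles in
    cylindrical coordinates, and mesh surface areas, classifies each
    centriole into a membrane stage (naked, DAV, CCV, TCV, CV, cilium),
    and aggregates cohorts with group statistics. Includes a synthetic
    voxel-phantom generator with exact analytic ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
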