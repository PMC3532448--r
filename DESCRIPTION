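Package: rgcstim
Title: Biophysical Simulation of Extracellular Electrical Stimulation of
    Retinal Ganglion Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Morphologically detailed, conductance-based (Hodgkin-Huxley type)
    compartmental models of retinal ganglion cells driven by the extracellular
    field of an epiretinal disk electrode. Provides a parametric generator for
    synthetic RGC morphologies (large-field and midget types) and jittered
    mosaics, SWC input/output, an implicit Crank-Nicolson cable solver on
    trees with per-compartment extracellular coupling, disk-electrode field
    closed forms with transfer-resistance scaling and depth-dependent tissue
    inhomogeneity, binary-search stimulation-threshold mapping at single-cell
    level, and population-level activation/identity/recruitment analyses over
    RGC mosaics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    parallel,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
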