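Package: epivertex
Title: Three-Dimensional Vertex Model of the Stratifying Epidermis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulator and analysis toolkit for a three-dimensional vertex
    model of stratified epithelia such as the embryonic mouse epidermis.
    Cells are space-filling polyhedra obtained from a periodic Voronoi
    tessellation; vertices evolve under overdamped Langevin dynamics driven
    by a shape-based energy with volume and surface elasticity plus
    heterotypic interfacial tensions between basement, basal and suprabasal
    compartments.  The package implements oriented basal-cell divisions with
    a prescribed mitotic-plane angle, homeostatic and densifying
    stratification protocols with ghost-cell conversion at the apical
    surface, an in-silico droplet rheometer for calibrating the natural time
    unit, and the accompanying statistics: long-axis orientation
    distributions, division-angle weighting, daughter-separation diffusion
    with subgroup bootstrap errors, and generalized-Maxwell relaxation fits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
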