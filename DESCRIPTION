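Package: vasculogen
Title: Hybrid Cellular Potts Simulation and Morphometry of Embryonic
    Vasculogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates de novo vascular network formation (vasculogenesis) by
    angioblasts that chemotact toward matrix-bound paracrine VEGF. A cellular
    Potts model of motile, deformable cells is coupled to a reaction-diffusion
    system for soluble VEGF, free extracellular-matrix binding sites and
    matrix-bound VEGF. The package also provides a morphometric suite for
    binary vascular patterns (Betti numbers, lacuna geometry, percolation,
    skeleton graphs with merge-corrected nodes, cord widths, fractal dimension
    and lacunarity), scenario runners for sensitivity, diffusivity, chemotaxis
    ratio and cell-density sweeps, and programmatic fixtures of known topology
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    Rcpp,
    igraph,
    yaml,
    jsonlite,
    png,
    tiff,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
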