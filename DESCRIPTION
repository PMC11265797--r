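Package: feltools
Title: Free-Energy Landscape Analysis for Alternating-Access Transporter Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis machinery for mapping the conformational free-energy
    landscape of proton-coupled membrane transporters from enhanced-sampling
    simulation output. Reads PLUMED-style COLVAR time series, evaluates helical
    tip/base gate collective variables on coordinate frames, derives optimized
    orthogonal 2D collective variables by maximizing an entropy-like
    inter-replicate separation metric over principal components, computes 1D and
    2D potentials of mean force by the weighted histogram analysis method (WHAM)
    with Boltzmann-reweighted projections and convergence bands, fits titration
    curves from constant-pH protonation traces to estimate pKa values, and
    assembles absolute binding free energies and thermodynamic cycles with
    Boresch-restraint analytics and propagated errors. A Brownian-dynamics
    synthetic-data module generates all inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
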