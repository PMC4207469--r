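Package: lipidorg
Title: Construction and Lipid-Organization Analysis of Coarse-Grained
    Asymmetric Membrane Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds complex asymmetric coarse-grained (CG) plasma-membrane
    models by editing a template POPC bilayer (random lipid exchange,
    rigid-body superimposition of larger species, cholesterol mapping,
    protein-grid placement, lateral replication) and analyses lipid
    organization in CG membrane trajectories: abundance-corrected fractional
    lipid-lipid interaction matrices, density-based (DBSCAN) nano-cluster
    statistics under periodic boundaries, cholesterol inter-leaflet flip-flop
    kinetics and leaflet occupancy, lateral diffusion coefficients from mean
    square displacements, grid-based correlation between bilayer surface
    height and local composition, lateral radial distribution functions and
    per-residue protein-lipid contacts. A synthetic-membrane generator with
    planted statistical structure (random mixing, planted clusters,
    curvature-coupled composition, Brownian lateral diffusion, inter-leaflet
    exchange) provides recoverable ground truth for every statistic. Reads
    and writes GROMACS GRO coordinate files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
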