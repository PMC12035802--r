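Package: membranemaps
Title: Leaflet-Resolved Bilayer Maps and Release Classification for
    Membrane Simulations with Hexagonal Periodic Cells
Version: 0.1.0
Authors@R:
    person("Maintainer", "Packages", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics trajectories of lipid
    bilayers interacting with polymer nanoparticles. Provides leaflet
    assignment robust to membrane curvature, per-lipid Voronoi areas and
    2D area-per-lipid and thickness raster maps under triclinic and
    hexagonal periodic boundary conditions, deuterium order parameters,
    mass-density profiles along the membrane normal, polymer coil metrics
    (radius of gyration, end-to-end distance, center-of-mass trajectory),
    and k-means classification of small-molecule release from a
    nanoparticle. Includes a synthetic-trajectory generator with planted
    ground truth so every stage can be validated without reference
    trajectories, and a configuration-driven pipeline with a command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
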