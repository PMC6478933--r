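Package: poreclog
Title: Pore Clogging and Ionic Current Blockade Analysis for Nanopore
    Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Post-processing of all-atom molecular dynamics trajectories of
    protein nanopores such as alpha-Hemolysin.  Builds voxel occupancy maps
    of the electrolyte, filters out reentrant electrolyte pockets by
    directional (monotone-z) accessibility to obtain the through-channel,
    derives available cross-section area profiles and a quasi-1D pore
    resistance, and summarizes analyte-induced conductance loss with a
    dimensionless pore-clogging estimator.  Also computes windowed
    displacement ionic currents with species decomposition and current
    blockage, amino-acid physicochemical correlations, and ships a
    synthetic pore + electrolyte trajectory generator with analytic ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
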