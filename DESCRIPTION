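Package: kitddg
Title: Free-Energy Inference of Kinase Mutation Effects from Nonequilibrium Work
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates alchemical free-energy differences from forward and
    reverse nonequilibrium work samples using the Bennett acceptance ratio
    maximum-likelihood estimator and the Crooks crossing construction, with
    bootstrap uncertainties. Assembles leg-level estimates into per-state
    relative stabilities (ddG) and activation ddG values of kinase point
    mutations through thermodynamic cycles, and classifies mutations as
    activating or deactivating. Also computes structural activation metrics
    of the KIT kinase domain on coordinate ensembles (DFG and HDR backbone
    dihedrals, catalytic salt-bridge distances, spine and global backbone
    PCA with projection of external structures), and ships synthetic-data
    generators producing work samples consistent with the Crooks fluctuation
    theorem and toy coordinate ensembles with prescribed dihedrals, distances
    and covariance structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
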