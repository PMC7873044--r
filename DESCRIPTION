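Package: cgcontact
Title: Residue Contact Dynamics of Coarse-Grained Tethered-Domain Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of inter-domain contact dynamics in coarse-grained
    (C-alpha trace) trajectories of multi-domain proteins such as the PICK1
    dimer: residue-residue contact maps, per-pair contact probabilities and
    lifetime statistics, interaction-type classification, Kabsch
    superposition RMSD and radius of gyration, anchor-residue distance
    distributions, and clustering of mobile-domain positions in the frame of
    a rigid reference body. Includes a Metropolis Monte Carlo generator of
    synthetic tethered-domain trajectories (rigid curved reference body,
    mobile compact bodies on flexible linkers, flexible tails, planted
    sticky contacts with known ground truth) so that every analysis stage is
    testable against calibrated expectations without external trajectory
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    bio3d,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
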