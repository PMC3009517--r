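Package: hxskel
Title: Structure Prediction for Helix Skeletons from Low-Resolution Density Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts ranked three-dimensional structures for the helical
    portion of a protein given helix-axis skeletons detected in a 6-10 Angstrom
    resolution density map together with the sequence and its predicted helix
    segments. Enumerates and screens sequence-to-skeleton topologies, builds
    parameterised ideal helix backbones on the skeleton axes, attaches
    simplified side chains, scores models with a multi-well inter-helix
    contact energy, and ranks placements sampled by simulated annealing.
    Includes a synthetic-bundle generator with known ground truth so the
    whole pipeline is testable without density maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    yaml,
    parallel,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
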