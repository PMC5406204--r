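Package: wtmetad
Title: Contact-Map Collective Variables, Well-Tempered Parallel-Tempering
    Metadynamics, and Free-Energy Basin Analysis at Desk Scale
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying protein conformational free-energy
    landscapes with contact-map collective variables: construction of
    state-discriminating contact sets from reference ensembles, evaluation
    of contact-map distance collective variables and their Cartesian
    gradients, a desk-scale well-tempered metadynamics engine with
    parallel tempering (overdamped Langevin dynamics on analytic model
    potentials or coarse bead structures), free-energy-surface
    reconstruction from deposited hills with convergence checks and basin
    extraction, gromos clustering with medoid representatives and
    interaction-occupancy tables, per-atom fluctuation (RMSF/B-factor)
    analysis, and crystal symmetry expansion with residue-level
    crystal-contact maps. Synthetic-data generators produce every fixture
    the pipeline needs, with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
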