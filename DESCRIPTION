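Package: poreperm
Title: Permeation Analysis for Single-File Membrane Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating water and solute permeabilities of narrow
    membrane channels such as aquaporins from particle trajectories in the
    channel frame. Implements density-based free-energy profiles and maps with
    self-consistent exponential averaging and jackknife errors, the collective
    diffusion estimator of the osmotic permeability, permeation-event counting
    for the diffusion permeability, a kinetic solute-permeability estimator
    built from boundary crossing rates and splitting probabilities, a
    one-dimensional adaptive-weight-histogram free-energy sampler, and
    structural statistics (hydrogen bonds, gating dihedrals, monomer quality
    filters). A seeded overdamped Langevin simulator of single-file pores
    provides synthetic trajectories with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
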