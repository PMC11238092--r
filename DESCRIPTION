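Package: condensim
Title: Coarse-Grained Simulation of Chromatin-Templated BRD4 Condensation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A coarse-grained Brownian-dynamics simulator and analysis toolkit
    for chromatin-templated biomolecular condensation. Builds bead-spring
    systems of nucleosome chains with acetylatable histone tails, two-blob
    BRD4 proteins and multivalent Corelet oligomerization platforms;
    integrates them with WCA sterics, FENE bonds and Flory-Krigbaum
    blob attractions; measures valence-resolved phase behaviour from
    direct-coexistence slab simulations; quantifies nucleation kinetics
    (first-passage times, rates, delay times, on- versus off-chromatin
    pathways); and implements microscopy-style puncta statistics on
    synthetic images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    EBImage,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
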