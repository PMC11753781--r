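Package: fdgmap
Title: Kinetic Modelling and Group Statistics for Dynamic [18F]FDG Brain PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise two-tissue-compartment kinetic modelling of dynamic
    [18F]FDG PET with an image-derived, partial-volume-corrected input
    function; parametric mapping of the glucose-transport ratio CE/CP;
    voxel-wise and volume-of-interest group statistics with p-value maps;
    a 3-sigma responder classifier for calcium-imaging and firing-rate
    traces; behavioral metrics (conditioned-place-preference score,
    two-bottle preference, locomotor AUC); and seeded synthetic-data
    generators so the whole pipeline can be exercised without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    Rcpp,
    minpack.lm,
    deSolve,
    RNifti,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
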