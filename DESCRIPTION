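Package: memscatter
Title: Membrane Bilayer Structure from Neutron Scattering and Spin-Label EPR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward models and fitting routines for characterizing
    cholesterol/phospholipid bilayers by three complementary techniques:
    multi-contrast neutron reflectometry of supported bilayers (volume-fraction
    slab models, Abeles reflectivity, simultaneous co-refinement with credible
    intervals and SLD probability maps), small-angle neutron scattering of
    vesicle suspensions (lamellar-stack paracrystal model in absolute units),
    and 9-GHz nitroxide spin-label EPR lineshapes (partial tensor averaging
    under an order parameter, MOMD powder averaging, fast-motion linewidths).
    Includes lipid-mixture composition bookkeeping with volume-weighted
    scattering-length-density mixing and seeded synthetic-data generators for
    all three techniques.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    pracma,
    lhs,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
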