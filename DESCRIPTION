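Package: trabmech
Title: Trabecular Bone Morphometry, Voxel Micro-Finite-Element
    Compression, and Structure-Mechanics Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Regional analysis of trabecular bone from 3-D micro-CT
    volumes. Computes the standard histomorphometric parameters (BV/TV,
    Tb.N, Tb.Th, Tb.Sp, BS/BV, Tb.Pf, BMD) per region of interest,
    converts gray values to density and elastic modulus with a power-law
    material map, runs displacement-controlled voxel-hexahedron
    micro-finite-element compression with stress, strain and von Mises
    field output, reduces experimental stress-strain records to Young's
    modulus, 0.2 percent offset yield, maxima and facet-angle allowable
    stress, and links microstructure to mechanics with factorial ANOVA
    (partial eta-squared, simple effects) and linear or ridge
    regression. Ships a synthetic phantom and curve generator with known
    ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    RNifti,
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
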