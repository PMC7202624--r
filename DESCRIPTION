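Package: pcleQuant
Title: Quantification of Alveolar Elastin Structure in Probe-Based
    Confocal Laser Endomicroscopy Images
Version: 0.1.0
Authors@R:
    person("pcleQuant", "Developers", email = "pclequant@example.org",
           role = c("aut", "cre"))
Description: Fully automatic quantification of alveolar elastin networks
    imaged by probe-based confocal laser endomicroscopy (pCLE). Provides
    trainable pixel classification (multi-scale filter bank, random
    undersampling, correlation-based feature selection, information-gain-
    ratio ranking, random forest), physical-unit mask post-processing
    (merging of holes separated by thin walls, filling of small holes),
    skeleton-based structural connectivity (holes per millimetre of
    skeleton), local thickness statistics (median and standard deviation),
    cohort-level nonparametric group comparison with Bonferroni
    correction, and a synthetic phantom generator with known ground truth
    so the entire pipeline can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    png,
    deldir,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
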