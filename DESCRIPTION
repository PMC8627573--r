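Package: ctenofa
Title: Comparative Lipidomics of Ctenophore Fatty Acids Across Depth and
    Temperature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of fatty acid profiles in marine
    ectotherms sampled across depth and temperature gradients. Implements
    GC-MS relative quantitation from external-standard calibration curves
    (including coelution-aware quantitation-ion selection), per-specimen
    lipidome summary statistics (double bond index, mean chain length,
    saturation-class, odd-chain and fatty-alcohol totals), and
    phylogenetically generalized least-squares regression under an
    Ornstein-Uhlenbeck correlation structure with maximum-likelihood
    selection-strength profiling, conspecific individuals attached to the
    species tree as terminal polytomies, environmental slicing of the specimen
    set, and Holm familywise error control. A synthetic-data generator
    produces trees, habitat profiles, compositional profiles and GC-MS
    fixtures with known ground truth for end-to-end validation and
    operating-characteristic simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
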