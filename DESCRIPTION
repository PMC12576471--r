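Package: bniscreen
Title: Screening Root-Exudate Metabolomes for Biological Nitrification
    Inhibition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for linking plant root-exudate metabolite profiles to
    biological nitrification inhibition (BNI) of ammonia-oxidizing bacteria
    and archaea. Quantifies nitrification-inhibition bioassays (ammonia
    oxidation inhibition percentage, EC50 under sigmoidal and slope-based
    response models), preprocesses GC-MS and LC-MS abundance tables
    (weight normalization, abundance balancing, volcano contrasts, Venn
    membership, PCA, chemical-class aggregation), screens metabolites
    against per-strain inhibition with Spearman correlation, builds
    thresholded partial-least-squares association networks, and performs
    combinatorial metabolite selection with a genetic algorithm whose
    fitness is the canonical correlation (linear or deep) between a
    metabolite triplet and inhibition activity. Includes mass utilities
    (molecular-formula parsing, monoisotopic mass, adduct ion m/z, ppm
    mass accuracy) and a seed-reproducible synthetic-study generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse,
    withr,
    xml2
Config/testthat/edition: 3
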