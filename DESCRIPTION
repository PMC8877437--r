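Package: biotransnet
Title: Discovering Microbial Biotransformations from Paired Metabolomic
    and Metagenomic Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrates a Spearman-correlation association network between
    molecular and microbial features, a tandem mass spectrometry molecular
    network, and a mass-delta biotransformation rule base to extract
    "golden triangle" candidates: a microbe that is negatively correlated
    with a substrate, positively correlated with a product, where substrate
    and product are spectrally similar and differ by the mass of a known
    chemical transformation. Includes readers for feature tables and MGF
    spectra, parent-mass dereplication against compound databases, network
    merging across cohorts (e.g. gut versus food), and a synthetic paired
    cohort generator with planted biotransformations for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
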