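Package: convscan
Title: Genome-Wide Detection of Convergent Amino Acid Substitutions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for scanning protein-coding orthogroups for
    molecular convergence in lineages that share a derived phenotype, such
    as insects adapted to cardiac glycosides. Provides alignment and
    sequence quality-control filters, single-copy ortholog delineation
    from gene trees, maximum-likelihood marginal ancestral sequence
    reconstruction under empirical amino-acid models, detection of
    parallel and convergent substitutions with a foreground-exclusivity
    rule, likelihood-ratio-test and enrichment post-processing, and a
    sequence-evolution simulator that generates fully ground-truthed
    inputs (including planted convergent sites and quality-control
    contaminants) so every stage can be validated and calibrated against
    a neutral null without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
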