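Package: faoclassify
Title: Oxidant-Preference Classification of Flavoprotein Amine
    Oxidoreductases from Kinetics, Operon Signposts and Ancestral States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Distinguishes dehydrogenases from oxidases in the flavoprotein
    amine oxidoreductase (FAO) superfamily. Provides a mass-action simulator
    for flavin reoxidation by dioxygen or cytochrome c, exponential fitting of
    stopped-flow absorbance traces with bimolecular rate-constant extraction
    and pseudo-first-order bias diagnostics, a rule-based oxidant-preference
    classifier, a genomic screen for twin-arginine (TAT) signal peptides and
    adjacent c-type cytochrome genes with sequence deduplication, equal-rates
    multistate Markov (Mk) ancestral-state reconstruction of operon
    configurations on a phylogeny, and seeded synthetic-data generators for
    every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    deSolve,
    minpack.lm,
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
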