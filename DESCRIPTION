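Package: gvaccordion
Title: Accordion-Model Comparative Genomics of Giant Viruses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying gene gain and loss in closely related giant
    virus (Megavirales) genomes under an accordion-like model of evolution,
    in which duplications, lateral gene transfers and mobile-element
    insertions are balanced by gene losses and excisions. Provides a
    genome-evolution simulator with a ground-truth event log, positional
    homology (synteny) detection via collinear anchor chaining, inference of
    per-branch genomic events by copy-number parsimony on a phylogeny with
    an equal-parsimony ambiguity rule, marginal ancestral reconstruction of
    concatenated marker genes under the Jukes-Cantor model, and the summary
    statistics of the accordion analysis: per-genome event tables, the
    events-per-kb molecular-clock regression, mobile-element fractions, and
    paralog-family and terminal-hotspot statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
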