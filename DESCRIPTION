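Package: bfoga
Title: Multi-Objective Multiple Sequence Alignment by a Bacterial
    Foraging and Genetic Hybrid Optimizer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Evolves multiple sequence alignments with a hybrid of
    bacterial foraging optimization (chemotaxis, swarming, reproduction,
    elimination-dispersal) and genetic operators (crowded tournament
    selection, single-point crossover, mutation).  Candidate alignments
    are scored on three objectives -- column similarity, affine or
    position-specific ("variable") gap penalty, and non-gap percentage --
    and ranked by Pareto non-dominated sorting with crowding distance.
    Includes sum-of-pairs and total-column benchmark scoring against
    reference alignments, a Wilcoxon matched-pair method comparison,
    bundled BLOSUM and PAM substitution matrices, a synthetic
    homologous-family simulator with known true alignments, and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    seqinr,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
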