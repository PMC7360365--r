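Package: glycompart
Title: Controlled Glycan Synthesis by Promiscuous Enzymes in Golgi Compartments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the synthesis of branched glycan oligomers by promiscuous
    glycosyltransferase (GTase) enzymes partitioned across Golgi compartments.
    Oligomers are rooted trees of typed monomers joined at numbered carbons;
    enzymes belong to three promiscuity classes (context-free,
    branch-sensitive, root-sensitive). The package builds reaction and
    linkage networks for enzymatic compartments, diagnoses the three causes
    of glycan microheterogeneity (truncated, runaway and divergent
    reactions), simulates compartment series as continuous-time Markov
    processes with Shannon-entropy quantification of output variability, and
    plans the minimum number of compartments needed for byproduct-free
    synthesis of a target oligomer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
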