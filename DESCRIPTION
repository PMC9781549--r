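Package: gh13sub
Title: Subfamily Delineation for the alpha-Amylase Family GH13 from
    Conserved Sequence Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to delineate candidate subfamilies of the alpha-amylase
    family GH13 from protein sequences alone. Curates candidate sets by the
    three classical membership criteria (homologous N-terminal domain, the
    full complement of conserved sequence regions, and an intact Asp/Glu/Asp
    catalytic triad), locates the seven GH13 conserved sequence regions plus
    the tryptophan pair by reference-anchored profile matching, scores the
    diagnostic sequence signature of the GH13_46 group (MPDxN fifth region,
    aromatic end of region II, glutamate after the proton donor, WW stretch),
    computes alignment conservation and sequence-logo statistics, and builds
    neighbor-joining trees with bootstrap support. A labelled synthetic
    sequence generator makes every stage testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
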