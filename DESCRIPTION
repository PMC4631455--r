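Package: protstab
Title: Design of Thermostable Multiple-Point Protein Mutants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing thermostable multiple-point protein mutants
    by combining evolution-based and energy-based evidence. Generates
    back-to-consensus substitution candidates from multiple sequence
    alignments (simple-consensus and frequency-ratio rules), ingests and
    averages per-structure folding free-energy change (ddG) predictions from
    external calculators, applies conservation-grade, correlated-mutation and
    salt-bridge exclusion filters, tests candidate pairs for antagonistic
    epistasis, and greedily assembles additive multiple-point designs.
    Includes a curation and precision/false-positive-rate benchmarking
    protocol for experimental stability datasets, and seeded synthetic-data
    generators (alignments, ddG tables, toy structures) so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
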