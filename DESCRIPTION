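Package: seqdivdiag
Title: Sequence Diversity Diagrams for Comparative Analysis of Multiple
    Sequence Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds Sequence Diversity Diagrams: a single-figure comparison of
    two or more sets of aligned protein or nucleotide sequences. Residue
    frequencies at adjacent alignment positions are encoded as Sankey-style
    ribbons on a fixed grid of positions by residue functional groups, with
    per-sample semi-transparent colors so overlapping flows blend optically,
    and a configurable low-frequency filter. Includes per-column Shannon
    entropy and sequence-logo information content, a synthetic aligned-data
    generator with planted conservation and subgroup structure, deterministic
    SVG output with PNG/PDF export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    yaml,
    optparse,
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    xml2,
    png,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
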