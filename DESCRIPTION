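Package: m6ARhythms
Title: Diel Rhythms of m6A RNA Methylation Machinery in Seagrasses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative inventory of N6-methyladenosine (m6A) writer and
    eraser gene families via bidirectional-best-hit ortholog/paralog networks
    with a paralog-network-maximising E-value cutoff, together with a diel
    (24-h) rhythm analysis of RNA-methylation gene expression and global m6A
    levels: -dCT quantification from RT-qPCR threshold cycles, ELISA
    standard-curve quantification of m6A percent, and a two-way crossed-design
    PERMANOVA/ANOVA inferential layer with permutation and Monte-Carlo
    p-values, SNK post-hoc contrasts and assumption diagnostics. Includes
    seeded synthetic-data generators with retrievable ground truth so the
    whole pipeline is testable end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    Biostrings,
    car,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
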