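Package: mucinscan
Title: Mucin Sequence Architecture, Frameshift Repair and Stress-Phenotype Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the architecture of insect mucin and
    peritrophin proteins and for the phenotype statistics used alongside them.
    Scans proteins with variable-gap residue-class motifs (PROSITE-style
    patterns such as P[ED][ED][ST][ST][ST] and the six-cysteine chitin-binding
    type-2 / peritrophin-A motifs), detects and segments tandem PTS repeat
    regions with sequence-logo summaries, classifies proteins against
    serine/threonine composition and repeat-occupancy mucin criteria with a
    hydropathy-based signal-peptide heuristic, locates protein queries in
    genomic DNA by six-frame local alignment and proposes minimal
    N-insertions that repair broken reading frames, and provides
    nonparametric two-group contrasts (exact Mann-Whitney with ties),
    Fisher's exact test, correlations and survival summaries. Seeded
    generators simulate mucin-like proteins, frameshifted coding sequences
    and two-strain phenotype tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
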