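Package: ddloop
Title: Simulation and Analysis of Partial TRBD1-TRBD2 Rearrangements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying partial D1-D2 rearrangements in the T-cell
    receptor beta (TRB) locus. Provides a mechanistic two-synapse V(D)J
    recombination simulator (coding joints and signal joints under the 12/23
    rule, exonucleolytic trimming, nontemplated TdT insertions, clone-size
    skew), an anchor-based junction caller with germline decomposition and
    short/long classification, repertoire statistics (two-component
    junction-length mixture fits, insertion/deletion summaries, clonotype
    publicity across samples, position frequency matrices), conservative
    k-mer detection of D1-D2-J2 and V-D1-D2-J2 structures, and excision-circle
    signal-joint calling.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
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
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
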