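Package: nbetascan
Title: Scanning and Subcellular-Fate Prediction for the N-Beta Secretion Motif
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locating the eleven-residue hydrophilic N-beta
    secretion motif (consensus X-X-X-E-S/G-G-S-S/E-S-E-P) in protein
    sequences and predicting the subcellular fate of the carrying protein
    (secreted, cytoplasmic, mitochondrial candidate or ER-retained) from
    position-specific residue rules, motif placement, net charge and
    C-terminal retention signals. Includes dataset-level positional
    statistics (quartile distribution with a chi-square goodness-of-fit
    test, localisation-evidence categories and their cross-tabulation),
    per-position frequency/information-content summaries for sequence
    logos, and a seeded synthetic-proteome generator with planted motif
    variants plus a built-in panel of GFP-fusion constructs with known
    experimental outcomes.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
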