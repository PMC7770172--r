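Package: pairfold
Title: RNA Secondary Structure Prediction with Pseudoknots via Attention
    Networks and Hard-Constraint Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts RNA secondary structures, including pseudoknots, from
    sequence alone. A transformer-style attention encoder and a pairwise
    convolutional decoder produce a symmetric N x N base-pair score matrix,
    which a hard-constraint optimization stage (canonical A-U/G-C/G-U pairs,
    minimum hairpin loop of three bases, at most one partner per base)
    converts into a valid pairing matrix by penalized gradient descent.
    Includes readers and writers for BPSEQ, CT, FASTA and extended
    dot-bracket notation, sensitivity/PPV/F1 evaluation in both exact
    base-pair (2-D) and per-base (1-D) modes, a synthetic structure and
    sequence generator for download-free testing, and a small training loop
    with analytic backpropagation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
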