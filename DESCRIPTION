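Package: ssfactors
Title: Multi-Factor Feature Analysis for Protein Secondary Structure
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds the four per-residue feature factors used in classical
    protein secondary structure prediction (sequence one-hot, PSI-BLAST
    position-specific scoring matrices, physicochemical property scales,
    and corpus-fitted structural propensity "trend" factors), assembles
    them into sliding-window residue vectors, trains four classifier
    families (support vector machine, random forest, k-nearest neighbour,
    Gaussian naive Bayes) on them, and quantifies per-factor importance,
    factor ablation effects, and prediction quality with Q3/Q8 accuracy
    and segment overlap (Sov) scores. Includes a seeded Markov-chain
    corpus simulator so the whole analysis runs without external data,
    and readers and writers for FASTA, FASTA-like label files and
    PSI-BLAST ASCII PSSM files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    class,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
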