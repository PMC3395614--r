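Package: orevo
Title: Functional Evolution of Odorant Receptor Orthologs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares the evolution of odorant-receptor (OR) coding sequences
    with the evolution of their in vitro function. Provides pairwise sequence
    metrics on codon alignments (Jukes-Cantor nucleotide distance, Grantham
    amino-acid property distance over the open reading frame or a binding-site
    subset, and Nei-Gojobori dN/dS), normalization and agonist calling for
    luciferase screens against a 42-odor panel, three-parameter logistic
    dose-response fitting with extra-sum-of-squares comparison and
    hyper/hypo-functional classification of receptor pairs, sequence-versus-
    function statistics (functional distance 1 - R, Spearman correlations,
    common-ligand rates, Wilcoxon rank-sum comparisons), k-means selection of
    a chemically diverse odor panel, and seeded simulators that generate every
    input format with known ground truth.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
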