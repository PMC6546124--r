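Package: bdfam
Title: Birth-and-Death Dynamics of Gene Families on Phylogenies
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying birth-and-death evolution of multigene
    families across a set of sequenced genomes. Computes per-clade branch-length
    statistics on gene phylogenies (cumulative branch length, normalized
    cumulative branch length, cumulative patristic distance), classifies gene
    lineages as phylogenetically stable or unstable from ortholog
    presence/absence, reconstructs gain and loss events on a species tree under
    Dollo parsimony together with ancestral repertoire sizes, post-processes
    branch-site selection tests (likelihood-ratio statistics, chi-squared tail
    probabilities, Holm-Bonferroni correction), and compares stable versus
    unstable lineages with two-sample t-tests. Includes a seeded
    duplication-loss simulator that generates gene trees, copy-number matrices
    and true event logs along a species tree, so every stage of the pipeline
    can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
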