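Package: orthoselect
Title: Genome-Scale Positive Selection Scans from Orthologous Gene Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for detecting positive (diversifying)
    selection across protein-coding gene families. From per-species CDS and
    peptide FASTA files it predicts one-to-one orthologous gene clusters by
    reciprocal-best-hit protein similarity, builds protein-guided in-frame
    codon alignments and neighbor-joining gene trees, fits Goldman-Yang codon
    substitution models (site models M0-M8a, branch and branch-site models)
    by maximum likelihood, and reports likelihood-ratio tests with
    Benjamini-Hochberg false discovery rate control together with per-site
    posterior probabilities of positive selection. A codon sequence simulator
    with known selection regimes is included for validation and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    parallel,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
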