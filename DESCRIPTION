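Package: patternTransfer
Title: Latent Expression Pattern Discovery and Cross-Species Transfer by
    Non-Negative Matrix Factorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers latent gene-expression programs in bulk RNA-seq
    matrices by non-negative matrix factorization (multi-restart
    multiplicative updates, with a split-gene consensus mode), classifies
    the resulting patterns by tissue, physiological-state or sample
    specificity to choose the pattern count, extracts pattern-marker
    genes, transfers learned gene weights into new datasets and species
    through one-to-one ortholog maps with group-level t-tests, and scores
    pattern gene weights for gene-set enrichment with a positive-only
    preranked permutation test. Ships a synthetic multi-species torpor
    data generator with known planted structure, readers and writers for
    the standard file dialects (expression TSV, OMA standalone ortholog
    output, Trinity gene_trans_map, GMT), and an end-to-end pipeline
    driver with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
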