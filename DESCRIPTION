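Package: hapsweep
Title: Haplotype-Based Selection Scans Linked to Mixed-Model GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline connecting a mixed-model genome-wide
    association scan of a quantitative trait in an inbred panel to
    haplotype-based signatures of partial selective sweeps. Implements
    extended haplotype homozygosity (EHH) and the integrated haplotype
    score (iHS) with frequency-bin standardization, window-max empirical
    P values over fixed genomic windows, and a circular-shift permutation
    test for enrichment of association peaks in iHS tails. Ships a
    founder-mosaic haplotype simulator with injected partial sweeps and
    linked phenotypes (kinship-structured polygenic background,
    flower-level replicates, batch artifacts) so the whole chain is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
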