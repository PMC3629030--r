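Package: cgassoc
Title: Candidate-Gene Association Genetics for Quantitative Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for candidate-gene association genetics in
    outcrossing plant populations: nucleotide-diversity characterization of a
    resequenced gene (segregating sites, pi, Watterson's theta, Nei-Gojobori
    synonymous/nonsynonymous site partitioning), linkage-disequilibrium
    structure from unphased genotypes (two-locus EM, r-squared, decay fitting,
    haplotype blocks), Q+K mixed-linear-model single-marker association with
    Ritland marker-based kinship and Storey q-values, sliding-window haplotype
    trend regression with permutation tests, gene-action decomposition
    (additive/dominant/overdominant), and validation in an F1 full-sib cross
    (Mendelian segregation tests and single-marker ANOVA). Includes a
    synthetic-data generator (coalescent haplotypes, Balding-Nichols
    structured genotypes with tunable LD decay, phenotypes with planted QTL
    and polygenic background, F1 crosses) so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr
Config/testthat/edition: 3
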