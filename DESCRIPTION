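Package: pancent
Title: Centromeric Satellite Repeat, Higher-Order Repeat and CENH3
    Enrichment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting plant centromeres built from tandem
    satellite repeats (such as the 156-bp and 157-bp CentBd/CentBs families
    of Brachypodium). Implements consensus-anchored decomposition of
    satellite arrays into monomers, paired-end read merging and
    satellite-fragment screening, identity and exact-duplication
    statistics, 5-mer frequency PCA with hierarchical clustering of repeat
    families, CENH3 ChIP/Input log2 enrichment tracks with centromere
    calling and metaprofiles, within-monomer nucleosome phasing, a
    simplified higher-order repeat (HOR) miner, LTR retrotransposon
    insertion-time dating, and a fully seeded synthetic centromere
    generator with ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    Rcpp,
    S4Vectors,
    utils,
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
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
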