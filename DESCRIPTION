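Package: acripr
Title: Analysis of ac4C Epitranscriptomes from acRIP-seq Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for N4-acetylcytidine (ac4C) epitranscriptome
    analysis from paired acRIP/input sequencing coverage over transcripts.
    Calls ac4C-enriched peaks with a Poisson enrichment test and
    Benjamini-Hochberg correction, applies replicate-consensus and
    synaptosome-database reliability filters, aggregates transcript-level
    fold enrichment and pseudocount fold changes, classifies memory-induced
    (MISA) and NAT10-dependent (NASA) synaptic ac4C transcripts, profiles
    peak summits over 5'UTR/CDS/3'UTR metagenes, performs ZOOPS k-mer motif
    enrichment with hypergeometric tests, and ships a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
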