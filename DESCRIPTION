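Package: varprior
Title: Longitudinal Variant Prioritization Across Selectively Bred Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prioritizing transcripts that have accumulated
    functionally consequential variants across temporally ordered,
    selectively bred lines (e.g. 1957, 1978 and modern Ross 308 broiler
    chickens). Provides per-transcript burden metrics (nonsynonymous SNP
    density, mean SIFT score, deleterious-variant counts), five combinatorial
    prioritization strategies with nearest-rank percentile semantics and a
    minimum-strategy combination filter, hypergeometric gene-set enrichment
    of SNP-dense genes with Benjamini-Hochberg correction, copy-number
    variant filtering and cross-line sharing by reciprocal overlap, and
    construction of coverage- and platform-filtered concatenated SNP
    alignments for phylogenetics. A synthetic-data generator with planted
    ground truth makes the whole pipeline testable without external genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    jsonlite,
    ggplot2,
    withr,
    generics,
    stats,
    utils,
    IRanges,
    S4Vectors,
    vcfR,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
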