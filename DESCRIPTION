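Package: polycutr
Title: Percentile Normalization and Comparative Analysis of CUT&RUN
    Chromatin Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for comparing Polycomb-dependent histone-modification
    landscapes between developmental timepoints from binned CUT&RUN
    coverage tracks. Implements percentile-based track normalization
    (local-maxima detection, recurrent-artifact blacklisting, scaling by
    the ratio of 99th-percentile maxima), interval-algebra classification
    of chromatin loci (co-occupied vs PRC1-only, bivalent vs
    H3K4me3-only promoters), length-scaled and metagene signal
    quantification, and the statistical layer (two-sample
    Kolmogorov-Smirnov tests, blacklist-filtered Pearson correlation,
    empirical-Bayes moderated-t differential abundance with
    Benjamini-Hochberg control). A synthetic-data module generates
    coverage tracks, peak sets, gene models and count matrices with
    known ground truth so every stage is testable without sequencing
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
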