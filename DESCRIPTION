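Package: sangermeth
Title: Per-Site DNA Methylation from Bisulfite Sanger Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies per-site CpG and non-CpG (CpH) DNA methylation from
    direct bisulfite Sanger sequencing chromatograms using the C/T (or G/A)
    peak-height ratio, with in-silico bisulfite conversion of reference
    regions, site enumeration and labelling, conversion-efficiency QC,
    uninformative-site filtering and non-CpG methylation discovery.
    Includes a nonparametric cohort-statistics layer (Mann-Whitney,
    Kruskal-Wallis, Spearman screens with region-wise Bonferroni families)
    and a copula-based synthetic-cohort generator with boundary-inflated
    beta marginals for end-to-end validation of the whole pipeline, built
    around the regulatory regions of the alpha-synuclein (SNCA) gene.
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
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    Biostrings,
    rtracklayer
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
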