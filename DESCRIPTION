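Package: lpiscreen
Title: Quantification of Colony-Array Chemical-Genomic Screens via the
    Logarithmic Phenotypic Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies high-throughput chemical-genomic screens of arrayed
    gene-deletion collections grown as 1536-colony plates. Converts per-colony
    growth time series into doubling times, removes systematic plate-position
    effects using interleaved control colonies, computes the Logarithmic
    Phenotypic Index (LPI) per strain and condition, calls sensitive and
    resistant mutants with a one-sample t-test under Benjamini-Hochberg false
    discovery control combined with a strong-effect threshold, and provides
    gene-set overlap statistics (Venn decomposition, hypergeometric tests).
    Includes a synthetic screen generator emulating the plate design, logistic
    colony growth, smooth spatial bias, replicate structure and curve
    corruption the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
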