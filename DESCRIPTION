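Package: enrich2d
Title: 1D and 2D Annotation Enrichment for Quantitative Omics Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Non-parametric, rank-based enrichment analysis for annotation
    terms (GO terms, pathways, complexes, domains, chromosomes) in
    quantitative proteomics and matched multi-omics data. The 1D test asks
    whether the members of a term are systematically shifted within the
    distribution of a single quantitative column using the two-sample
    Wilcoxon-Mann-Whitney test; the 2D test generalises this to the joint
    distribution of two omics dimensions (e.g. protein ratio versus mRNA
    ratio) via a two-group MANOVA on coordinate-wise ranks. Each significant
    term receives a directional position score in [-1, 1] per dimension.
    Includes Benjamini-Hochberg FDR control, GMT and categorical-column
    annotation parsing with protein-group-aware term selection, parsimonious
    protein grouping with razor-peptide assignment, matching of protein
    groups to probe-level transcriptome and CGH data, synthetic data
    generators with planted signals, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ggplot2,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
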