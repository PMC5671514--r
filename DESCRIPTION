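Package: primirna
Title: Annotation, Quantification and Differential Expression of
    pri-miRNA Gene Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Annotates primary microRNA (pri-miRNA) transcript gene models
    from reference hairpin coordinates and assembled transcript
    predictions, classifying each model into positional groups relative to
    protein-coding and non-coding genes (intergenic, near-gene, hairpin- or
    model-overlapping a coding gene, overlapping a non-coding gene).
    Quantifies the merged annotation from SAM/BAM alignments with
    largest-overlap read assignment, primary-alignment and mapping-quality
    filters; tests two-group differential expression with an exact
    negative-binomial conditional test under fixed-BCV or estimated
    dispersion with Benjamini-Hochberg FDR; and evaluates per-group
    expression shifts and cross-experiment agreement. A synthetic-data
    generator with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
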