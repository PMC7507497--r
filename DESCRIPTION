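Package: agoxtools
Title: Readthrough-Region Conservation, dsRNA Enrichment and Nucleolar
    Image Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects putative translational-readthrough regions (the mRNA
    interval between the annotated stop codon and the next in-frame stop),
    scores them by averaged per-base conservation, and analyses
    multi-species alignments of such regions for nonsense substitutions
    and frame-preserving indels. Calls transcripts enriched or depleted in
    a dsRNA pulldown relative to total RNA-seq by standardized residuals
    from the fold-change regression, intersects calls across conditions,
    and compares G/C composition of the call sets. Quantifies nucleolar
    versus nucleoplasmic signal intensity and per-cell foci counts from
    3D image stacks. A synthetic-data module generates every input with
    known ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    EBImage,
    GenomicRanges,
    IRanges,
    S4Vectors,
    graphics,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tiff,
    tools,
    utils
Suggests:
    DESeq2,
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
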