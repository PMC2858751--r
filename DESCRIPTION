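Package: utrx
Title: Detection of 3' UTR Extensions from 3'-Biased Expression Microarrays
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens 3'-biased expression microarray data for probe sets that
    report 3' untranslated region (UTR) extensions beyond annotated transcript
    ends. Pairs each transcript's most-3' ("primary") probe set with the
    nearest downstream unannotated co-oriented probe set, filters pairs by an
    above-noise expression threshold and by Pearson correlation of their
    expression profiles across tissues, and estimates false-positive rates
    with random-pair and cross-chromosome empirical null models. Predicted
    extensions are characterized by phylogenetic conservation against matched
    random region sets (normal Z-statistic), gapped IUPAC motif scanning for
    polyadenylation and stability elements, microRNA seed-site counting, and
    confirmation by 3'-end sequence tags. A synthetic data generator emulates
    multi-tissue expression compendia with planted extensions so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    BiocGenerics,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
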