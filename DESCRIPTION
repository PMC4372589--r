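Package: deepsage
Title: Tag-Based Digital Gene Expression (DeepSAGE) Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete, reproducible pipeline for DeepSAGE-style digital
    gene expression profiling: simulation of CATG-anchored 21-nt tag
    libraries with known ground truth, clean-tag filtering of raw 49-bp
    reads, virtual-tag mapping onto a reference transcriptome with at most
    one mismatch, tags-per-million normalization, differential expression
    calling with the Audic-Claverie exact test under FDR and fold-change
    thresholds, hypergeometric pathway enrichment, sequencing-saturation
    and inter-library correlation QC, and 2^-ddCt relative quantification
    of qRT-PCR validation data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
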