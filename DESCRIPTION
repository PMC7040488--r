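Package: cernetr
Title: Competing Endogenous RNA Network Inference from Whole-Transcriptome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers miRNA-mRNA-lncRNA competing endogenous RNA (ceRNA)
    networks from bulk whole-transcriptome time-course experiments.
    Provides small-RNA clean-tag filtering, FPKM/TPM normalization and
    2^-ddCt relative quantification, fold-change plus Welch-t differential
    expression screening with Benjamini-Hochberg correction, canonical
    seed-match miRNA target prediction (6mer/7mer-A1/7mer-m8/8mer) with
    n-way predictor intersection, negative Pearson co-expression screening,
    hypergeometric gene-set enrichment, and assembly and Cytoscape-compatible
    export of the resulting typed network. A synthetic-data generator with
    planted ground truth (expression matrices, transcript sequences, gene
    sets, and adapter-flanked small-RNA reads) makes every stage testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
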