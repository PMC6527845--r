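Package: cmapminer
Title: Literature and Expression Mining for Disease Gene-Drug Connectivity Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds disease-centred gene and drug catalogues from literature
    corpora and microarray expression compendia. Scans abstracts with
    dictionary lexicons and scores gene-disease and drug-disease associations
    by weighted sentence co-occurrence counts; reannotates microarray probes
    from BLAT PSL alignments to coding genes or lncRNAs with coding priority;
    quantile-normalizes and log2-transforms expression matrices and collapses
    probes to genes; performs moderated-t differential expression per dataset
    and integrates datasets with robust rank aggregation; and combines
    abstract-level gene-drug co-occurrence with drug-target expression
    correlation into a regularized log-odds connectivity score. Seeded
    synthetic-data generators emulate every input with ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
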