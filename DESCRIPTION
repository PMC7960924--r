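Package: crypticSplice
Title: Prioritization and In Silico Validation of Deep-Intronic Splice
    Variants
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies candidate deep-intronic splice-disrupting variants
    in rare-disease cohorts from SpliceAI-annotated VCFs. Filters variants
    by population frequency, splice-gain/loss delta scores, gene-panel
    membership and distance from exon-intron junctions; pairs alleles under
    gene-specific inheritance models (dominant, recessive, X-linked);
    reconstructs the predicted aberrant transcript (pseudo-exon inclusion,
    exon elongation, acceptor shift) with reading-frame, premature-stop and
    nonsense-mediated-decay consequences; and designs the minigene reporter
    construct, with predicted RT-PCR product sizes, that would validate each
    candidate in vitro. Ships a deterministic synthetic-cohort simulator and
    a bundled worked-example cohort so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: VariantAnnotation, Genetics, SplicedAlignment, Sequencing
RoxygenNote: 7.3.3
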