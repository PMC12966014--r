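Package: KaryoTrace
Title: Ancestral Karyotype Reconstruction, Subgenome Dominance and
    Polyploidy Dating from Gene-Order Synteny
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative-genomics toolkit for tracing descendant genomes
    back to an ancestral crucifer-style karyotype. Detects syntenic
    ortholog pairs from homology plus gene order, chains them into
    syntenic fragments under a gene-count/physical-distance consolidation
    rule, projects ancestral genomic blocks onto descendant chromosomes,
    counts block copies, compares block associations and infers
    chromosome fusion and rearrangement events. Includes subgenome
    partitioning by gene density with retention and homoeolog expression
    dominance statistics, Nei-Gojobori (1986) synonymous-rate estimation
    with kernel-density peak detection for polyploidy dating, an anchored
    PSPG-motif scan with expression-metabolite correlation screening for
    glycosyltransferase candidates, and a seedable forward simulator of
    karyotype evolution that produces every input the pipeline consumes
    together with ground truth for parameter-recovery tests.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
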