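Package: haplocap
Title: Capture-Probe Design, Read Binning, Annotation and Evaluation for
    Homologous Haplotype Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for targeted long-read haplotyping of highly homologous,
    repeat-rich gene clusters such as the human KIR region. Implements
    repeat-aware greedy selection of 120-base hybridization capture probes
    over reference haplotypes, k-mer based on/off-target read classification
    and per-locus binning, annotation of assembled haplotigs from
    capture-probe alignment signatures with exon/intron boundary placement by
    16-base junction markers under escalating mismatch tolerance, and
    assembly evaluation (phased coverage, concordance and LG-style contiguity
    metrics) from PAF or SAM alignments. A synthetic diploid haplotype
    simulator with full ground truth makes the whole workflow testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    methods
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
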