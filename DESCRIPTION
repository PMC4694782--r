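Package: p53response
Title: Integrated Analysis of p53 Binding and p53-Dependent Transcription
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the joint analysis of transcription-factor ChIP-seq
    peaks and stress-induced transcription, centred on the p53 response to
    ionizing radiation. Implements dimeric position-weight-matrix scanning
    with a variable 0-15 nt spacer between decameric half sites, exact
    match p-values by dynamic programming, ZOOPS-EM de novo motif
    discovery, background-subtracted peak enrichment, strand-aware
    promoter / enhancer / unmarked-distal classification of binding sites
    against chromatin-mark peak sets, RPKM quantification, a simplified
    negative-binomial differential-expression test with a
    genotype-dependence rule, Fisher gene-set enrichment, and the
    integration of motif class with regulatory mode that defines a core
    transcriptional response. A synthetic-data module generates toy
    genomes with planted response elements, peak calls, chromatin
    annotation, and count matrices with known ground truth so the whole
    pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
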