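Package: dsbstrand
Title: Strand-Resolved Signal Analysis at DNA Double-Strand Breaks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing strand-specific sequencing signal around
    sequence-specific DNA double-strand breaks (DSBs). Classifies break
    sites by transcriptional context (transcription-coupled versus silent;
    promoter, 5' region, gene body; exonic/intronic), resolves stranded
    coverage into the resected (5'-terminated) and 3'-overhang strands on
    both sides of a break, orients signal by gene direction or hybrid
    dominance, computes damage-aware TSS-metagene scale factors and
    spike-in factors, builds anchor-centred profile matrices with paired
    Wilcoxon and boxplot conventions, and estimates RNA polymerase II
    elongation rates from DRB/TT-seq transcription-wave time courses by
    smoothing-spline wave-peak calling and linear regression. Ships a
    fully seeded synthetic-data generator that emulates qDRIP-seq,
    END-seq, RPA ChIP-seq, RNAPII ChIP-seq and DRB/TT-seq tracks with
    known ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
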