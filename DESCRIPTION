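Package: snoclash
Title: Interaction Calling and Classification for snoRNA CLASH/FLASH Chimeric Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls and classifies RNA-RNA interactions of box C/D snoRNAs from
    chimeric (hybrid) reads produced by crosslinking-and-proximity-ligation
    experiments (CLASH/FLASH). Parses hyb-format chimera tables, predicts the
    intermolecular duplex between the two read fragments, filters interactions
    for stability (predicted folding energy) and reproducibility (overlapping
    independent reads), and classifies each snoRNA-target interaction as a
    strict or weak 2'-O-methylation guide, ancillary, blocking, or structural
    using box C/D guide geometry (the +5 rule upstream of box D/D').
    Downstream annotation places target fragments on mRNA features
    (CDS/UTR/intron), host-intron cis interactions, and intron branch-point
    windows. A seed-deterministic synthetic-data generator produces
    ground-truth-labelled references, chimeras and single reads so the whole
    pipeline is testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
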