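Package: circlass
Title: Classification of Circular RNA Junctions from Chimeric RNA-Seq Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies circular-junction-spanning reads from
    total RNA-seq chimeric alignments. Circular chimeric reads (CCRs) are
    selected from aligner chimeric-junction records, clustered into loci
    associated with circRNA production (LACs), and classified by a cascade
    into exonic circRNAs (via an iterative exon-boundary labelling strategy
    over prioritized exon lists), lariat-derived intronic circRNAs, intron
    circles, and sub-exonic circRNAs from mono-exonic genes. Read-level
    junction-sequence analysis merges alignment-shift-equivalent loci into
    circularization events. A synthetic-data module generates a toy genome,
    annotation, and chimeric read evidence with a truth table so the whole
    pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
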