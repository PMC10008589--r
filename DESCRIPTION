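Package: dartvadar
Title: Design and Quantification of ADAR-Activatable RNA Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for engineering autocatalytic ADAR-based RNA sensors.
    Enumerates and ranks editable CCA target sites on annotated transcripts,
    designs antisense sensor windows carrying a central in-frame UAG stop
    codon (including all-stop and single-nucleotide-variant discrimination
    modes), assembles and validates single-transcript closed-loop and
    open-loop expression constructs with MS2 hairpin placement and AAV size
    budgeting, quantifies per-position A-to-G editing from amplicon reads
    (SAM or FASTQ), and computes geometric-mean fold-change statistics from
    per-cell fluorescence tables. A seed-deterministic simulator generates
    triggers, amplicon reads, and cytometry-style intensity tables so the
    full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    Rsamtools,
    rtracklayer,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
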