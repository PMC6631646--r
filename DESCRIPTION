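Package: vicscan
Title: Bicistronic Victorivirus Genome Annotation and Translation-Strategy Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates victorivirus-like bicistronic genomes (5'UTR / capsid
    ORF / inter-ORF bridge / RdRp ORF / 3'UTR), scans the ORF junction and
    5'UTR for translational recoding signals (slippery heptamers for -1
    ribosomal frameshifting, AUGA/UAAUG stop-restart facilitators, conserved
    UTR motifs), detects stem-loops and H-type pseudoknots with a documented
    heuristic score, models the candidate protein products implied by each
    translation strategy with average molecular masses, and adjudicates
    between strategies from peptide-mass-fingerprint evidence via in-silico
    tryptic digestion and frame-indexed peptide mapping. Includes a synthetic
    genome generator with exact truth layouts so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
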