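Package: ribortc
Title: Quantification of Stop-Codon Readthrough from Ribosome Profiling, with
    Companion Drug-Screen and Growth-Curve Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify translational readthrough at a premature
    termination codon (PTC) and at canonical stop codons from aligned
    ribosome-profiling footprints: transcript coordinate handling from
    GTF annotation, genome-to-transcript projection of alignments, P-site
    offset calibration with 3-nt periodicity quality control, in-frame
    coverage profiles, a length-normalised PTC readthrough ratio, and a
    metagene stop-codon readthrough ratio. Also implements an NCI-60-style
    GI50 differential-sensitivity screen for TP53-nonsense-mutant cell
    lines and logistic confluence growth-curve fitting with rates reported
    at the control's critical point. Ships seeded synthetic-data
    generators (footprints with ground truth, GI50 matrices with planted
    hits, logistic confluence curves) so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
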