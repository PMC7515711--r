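Package: carp
Title: Combined Analysis of RNA-seq and PRO-seq for Post-Transcriptional Regulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deconvolves post-transcriptional from transcriptional gene
    regulation by jointly modeling steady-state RNA-seq and nascent
    transcription (PRO-seq) counts with a negative-binomial generalized
    linear model and testing a condition-by-assay interaction via
    likelihood-ratio tests. Supports exon/intron split analysis (intronic
    reads as the transcription proxy) and translational-efficiency
    contrasts from ribosome profiling. Includes miRNA seed-match target
    site scanning (8mer, 7mer-m8, 7mer-A1 and G-bulged sites) with local
    AU context scoring, partitioning of genes into direct/indirect target
    classes, quantification of mRNA decay versus translational repression,
    motif and target-site enrichment testing with exact position-weight
    matrix score thresholds, a closed-form model of miRNA accumulation
    kinetics, and a negative-binomial simulator with planted
    transcriptional, post-transcriptional and translational effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
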