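Package: kmerTF
Title: Plant Transcription Factor Family Classification from Protein k-mer
    Frequencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identification and family-level classification of plant
    transcription factor (TF) protein sequences. Sequences are encoded as
    relative k-mer frequency vectors over the 20-letter amino-acid alphabet,
    reduced by one-way ANOVA F-statistic feature selection, and scored by an
    ensemble of per-family binary feed-forward neural classifiers whose
    outputs are combined either by max voting or by a stacking
    meta-classifier. A confidence threshold rejects low-scoring sequences as
    "unknown", which separates non-TF proteins from TF family members.
    Includes a synthetic corpus generator with implanted family motifs for
    fully reproducible benchmarking, evaluation under micro/macro/weighted
    averaging, threshold sweeps, and a Mann-Whitney U comparison of
    per-family score vectors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
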