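Package: tfcoop
Title: Predicting Cooperative Transcription Factor Pairs from Target
    Overlap and Nucleosome Co-Depletion
Version: 0.1.0
Authors@R:
    person("Avery", "Lindqvist", email = "avery.lindqvist@example.org",
           role = c("aut", "cre"))
Description: Infers cooperative transcription factor (TF) pairs in yeast by
    combining two sources of evidence: the significance of the overlap
    between the two TFs' target-gene sets (hypergeometric test) and the
    significance of nucleosome co-depletion at the two TFs' binding sites
    in shared-target promoters (one-sided Fisher exact test). Each pair is
    assigned a cooperativity score, -log10(P_overlap) - log10(P_nu), and
    pairs above a score threshold are reported as predicted cooperative
    pairs. Ships readers for documented-regulation tables, binding-site
    tables with posterior probabilities, nucleosome-occupancy interval
    tracks and protein-protein interaction edge lists; benchmark-based
    evaluation indices (PPI-partner overlap, benchmark enrichment,
    precision/recall); a synthetic-data generator with planted cooperative
    pairs; and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
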