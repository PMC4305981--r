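#' Run the scoring pipeline on in-memory inputs
#'
#' Convenience wrapper chaining [filter_tfbs()], [build_best_site_index()],
#' [define_targets()] and [score_all_pairs()].
#'
#' @param regulation a `RegulationTable` (or `NULL`).
#' @param tfbs a `TFBSTable` (or `NULL`).
#' @param track a `NucleosomeTrack`.
#' @param posterior_threshold minimum site posterior; default 0.3.
#' @param total_genes gene-universe size `N`; default 6576.
#' @param disable_nucleosome ablate the nucleosome term; see
#'   [score_all_pairs()].
#' @return a ranked `PairResultTable`.
#' @export
score_pipeline <- function(regulation, tfbs, track,
                           posterior_threshold = 0.3, total_genes = 6576L,
                           disable_nucleosome = FALSE) {
  best <- build_best_site_index(filter_tfbs(tfbs, posterior_threshold))
  targets <- define_targets(regulation, best, total_genes = total_genes)
  score_all_pairs(targets, best, track,
                  disable_nucleosome = disable_nucleosome)
}
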