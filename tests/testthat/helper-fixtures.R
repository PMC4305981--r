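# Shared in-code fixtures: a hand-checkable four-gene world and small file
# writers. All built at test time; nothing binary on disk.

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Two TFs, four genes on one chromosome; gene promoters are 1 kb blocks.
# TFA and TFB both bind G1..G4 (set A = all four genes when targets agree);
# nucleosome intervals are laid out so the per-gene occupancy states of
# (TFA, TFB) are exactly (0,0), (1,0), (0,1), (1,1) for G1..G4.
tiny_world <- function() {
  genes <- c("G1", "G2", "G3", "G4")
  prom <- (seq_along(genes) - 1L) * 1000L
  site_a <- prom + 100L       # TFA site at offset 100, width 10
  site_b <- prom + 300L       # TFB site at offset 300, width 10
  tfbs <- tfbs_table(
    tf = rep(c("TFA", "TFB"), each = 4L),
    chrom = "chr1",
    start = c(site_a, site_b),
    end = c(site_a, site_b) + 10L,
    strand = "+",
    posterior = rep(0.9, 8L),
    gene = rep(genes, 2L)
  )
  regulation <- regulation_table(tf = rep(c("TFA", "TFB"), each = 4L),
                                 gene = rep(genes, 2L))
  # occupied: TFA site of G2, G4; TFB site of G3, G4
  occ_start <- c(site_a[c(2L, 4L)], site_b[c(3L, 4L)])
  track <- nucleosome_track(chrom = rep("chr1", 4L), start = occ_start,
                            end = occ_start + 10L)
  best <- build_best_site_index(filter_tfbs(tfbs, 0.3))
  targets <- define_targets(regulation, best, total_genes = 10L)
  list(genes = genes, tfbs = tfbs, regulation = regulation, track = track,
       best = best, targets = targets)
}

run_synth <- function(dataset, ...) {
  score_pipeline(dataset$regulation, dataset$tfbs, dataset$track,
                 total_genes = dataset$config$n_genes, ...)
}
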