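## Synthetic data with planted cooperative TF pairs.
##
## The generator states a small regulatory world: each gene owns a disjoint
## promoter on one synthetic chromosome; each TF targets background genes at
## a fixed rate; planted pairs share a fixed fraction of their targets and
## their sites at shared targets are co-depleted of nucleosomes at a fixed
## rate. Every target relationship emits both a documented-regulation record
## and a binding site (unless dropped to exercise the documented-only path),
## and occupancy is materialized as nucleosome intervals that exactly cover
## the occupied sites. Sites of different TFs occupy disjoint slots within a
## promoter, so one site's nucleosome can never shadow another site.

#' Configuration for the synthetic-data generator
#'
#' Defaults state the simulated world: 600 genes with 1 kb promoters, 20
#' TFs, 3 planted cooperative pairs, a 5% background target rate (~30
#' targets per TF), 60% target sharing within planted pairs, 70% background
#' nucleosome occupancy per site, 80% co-depletion at planted pairs' shared
#' targets, and site posteriors uniform on [0.3, 1] (all pass the default
#' posterior filter). Setting `planted_shared_fraction = 0` (and, for
#' symmetry, `planted_codepletion_rate = 1 - background_occupancy_rate`)
#' removes all planted signal, giving the generator's null.
#'
#' @param n_genes number of genes.
#' @param n_tfs number of TFs (each gets a dedicated site slot per
#'   promoter; `n_tfs * site_width` must fit in `promoter_length`).
#' @param n_planted_pairs number of planted cooperative pairs, built from
#'   disjoint TFs (at most `n_tfs / 2`).
#' @param background_target_rate per-TF probability that a gene is a target.
#' @param planted_shared_fraction fraction of a planted pair's targets that
#'   the two TFs share.
#' @param promoter_length bases per gene promoter.
#' @param background_occupancy_rate probability a site is
#'   nucleosome-occupied.
#' @param planted_codepletion_rate probability that both planted-pair sites
#'   at a shared target are depleted (otherwise occupancy falls back to
#'   independent background draws).
#' @param posterior_min,posterior_max range of the uniform posterior
#'   distribution for emitted sites.
#' @param tfbs_dropout fraction of targets whose binding site is withheld,
#'   leaving documented regulation as the only evidence.
#' @param ppi_shared_partners common PPI partners given to each planted
#'   pair's two TFs.
#' @param ppi_noise_edges random TF-gene PPI edges added as noise.
#' @param site_width binding-site width in bases.
#' @param seed integer random seed.
#' @return a validated `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_genes = 600L, n_tfs = 20L,
                             n_planted_pairs = 3L,
                             background_target_rate = 0.05,
                             planted_shared_fraction = 0.6,
                             promoter_length = 1000L,
                             background_occupancy_rate = 0.7,
                             planted_codepletion_rate = 0.8,
                             posterior_min = 0.3, posterior_max = 1.0,
                             tfbs_dropout = 0,
                             ppi_shared_partners = 5L,
                             ppi_noise_edges = n_tfs,
                             site_width = 10L,
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
              n_planted_pairs = as.integer(n_planted_pairs),
              background_target_rate = background_target_rate,
              planted_shared_fraction = planted_shared_fraction,
              promoter_length = as.integer(promoter_length),
              background_occupancy_rate = background_occupancy_rate,
              planted_codepletion_rate = planted_codepletion_rate,
              posterior_min = posterior_min, posterior_max = posterior_max,
              tfbs_dropout = tfbs_dropout,
              ppi_shared_partners = as.integer(ppi_shared_partners),
              ppi_noise_edges = as.integer(ppi_noise_edges),
              site_width = as.integer(site_width),
              seed = as.integer(seed))
  rates <- c(cfg$background_target_rate, cfg$planted_shared_fraction,
             cfg$background_occupancy_rate, cfg$planted_codepletion_rate,
             cfg$tfbs_dropout)
  if (anyNA(rates) || any(rates < 0) || any(rates > 1)) {
    stop("synthetic_config: all rates must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$posterior_min < 0 || cfg$posterior_max > 1 ||
      cfg$posterior_min > cfg$posterior_max) {
    stop("synthetic_config: posterior range must satisfy 0 <= min <= max <= 1",
         call. = FALSE)
  }
  if (cfg$n_planted_pairs * 2L > cfg$n_tfs) {
    stop("synthetic_config: n_planted_pairs must be at most n_tfs / 2",
         call. = FALSE)
  }
  if (cfg$n_tfs * cfg$site_width > cfg$promoter_length) {
    stop(sprintf(
      "synthetic_config: infeasible geometry: %d TFs x %d bp sites exceed the %d bp promoter",
      cfg$n_tfs, cfg$site_width, cfg$promoter_length), call. = FALSE)
  }
  class(cfg) <- "SyntheticConfig"
  cfg
}

pad_ids <- function(prefix, n) {
  sprintf(paste0(prefix, "%0", max(2L, nchar(n)), "d"), seq_len(n))
}

#' Generate a synthetic dataset with planted cooperative pairs
#'
#' See [synthetic_config()] for the simulated world. Fully reproducible from
#' `config$seed`; when `out_dir` is given, the four input files plus the
#' ground truth and the config are written in exactly the dialects the
#' package readers expect, byte-identically across runs with the same seed.
#'
#' @param config a `SyntheticConfig`.
#' @param out_dir optional directory; created if missing. Files written:
#'   `regulation.tsv`, `tfbs.bed`, `nucleosome.bed`, `ppi.tsv`,
#'   `truth.tsv`, `config.json`.
#' @return a list: `config`, `regulation` (`RegulationTable`), `tfbs`
#'   (`TFBSTable`), `track` (`NucleosomeTrack`), `ppi` (`PPINetwork`),
#'   `truth` (data frame `tf1`, `tf2`), `promoters`, and `paths` when
#'   `out_dir` was given.
#' @export
simulate_dataset <- function(config = synthetic_config(), out_dir = NULL) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)

  genes <- pad_ids("G", config$n_genes)
  tfs <- pad_ids("TF", config$n_tfs)
  chrom <- "chrS"
  prom_start <- (seq_len(config$n_genes) - 1L) * config$promoter_length
  promoters <- data.frame(gene = genes, chrom = chrom, start = prom_start,
                          end = prom_start + config$promoter_length,
                          stringsAsFactors = FALSE)

  planted <- if (config$n_planted_pairs > 0L) {
    cbind(seq(1L, by = 2L, length.out = config$n_planted_pairs),
          seq(2L, by = 2L, length.out = config$n_planted_pairs))
  } else {
    matrix(integer(), 0L, 2L)
  }
  is_planted_tf <- logical(config$n_tfs)
  is_planted_tf[as.vector(planted)] <- TRUE

  ## Target sets as gene-index vectors, planted sharing first.
  target_idx <- vector("list", config$n_tfs)
  shared_idx <- vector("list", max(1L, config$n_planted_pairs))
  expected_targets <- max(1L, round(config$n_genes *
                                      config$background_target_rate))
  for (j in seq_len(config$n_planted_pairs)) {
    n_shared <- round(config$planted_shared_fraction * expected_targets)
    shared <- if (n_shared > 0L) sort(sample.int(config$n_genes, n_shared))
              else integer()
    shared_idx[[j]] <- shared
    extra_rate <- config$background_target_rate *
      (1 - config$planted_shared_fraction)
    for (tf_i in planted[j, ]) {
      extra <- which(rbinom(config$n_genes, 1L, extra_rate) == 1L)
      target_idx[[tf_i]] <- sort(union(shared, extra))
    }
  }
  for (tf_i in which(!is_planted_tf)) {
    target_idx[[tf_i]] <- which(rbinom(config$n_genes, 1L,
                                       config$background_target_rate) == 1L)
  }

  ## One row per (TF, target gene), fixed order: TF index, then gene index.
  rel <- data.frame(tf_i = rep(seq_len(config$n_tfs), lengths(target_idx)),
                    gene_i = unlist(target_idx))
  ## Occupancy: background per site, then planted co-depletion overrides.
  rel$occupied <- rbinom(nrow(rel), 1L, config$background_occupancy_rate)
  for (j in seq_len(config$n_planted_pairs)) {
    for (g in shared_idx[[j]]) {
      rows <- which(rel$gene_i == g & rel$tf_i %in% planted[j, ])
      if (runif(1L) < config$planted_codepletion_rate) {
        rel$occupied[rows] <- 0L
      }
    }
  }
  rel$has_site <- if (config$tfbs_dropout > 0) {
    runif(nrow(rel)) >= config$tfbs_dropout
  } else {
    rep(TRUE, nrow(rel))
  }
  rel$posterior <- round(runif(nrow(rel), config$posterior_min,
                               config$posterior_max), 6L)

  regulation <- regulation_table(tfs[rel$tf_i], genes[rel$gene_i])

  site_start <- prom_start[rel$gene_i] + (rel$tf_i - 1L) * config$site_width
  emit <- rel$has_site
  tfbs <- tfbs_table(tf = tfs[rel$tf_i[emit]], chrom = chrom,
                     start = site_start[emit],
                     end = site_start[emit] + config$site_width,
                     strand = "+", posterior = rel$posterior[emit],
                     gene = genes[rel$gene_i[emit]])

  occ_rows <- emit & rel$occupied == 1L
  track <- nucleosome_track(chrom = rep(chrom, sum(occ_rows)),
                            start = site_start[occ_rows],
                            end = site_start[occ_rows] + config$site_width)

  ## PPI: planted pair edges, shared partners, and random TF-gene noise.
  ppi_a <- character(); ppi_b <- character()
  for (j in seq_len(config$n_planted_pairs)) {
    t1 <- tfs[planted[j, 1L]]; t2 <- tfs[planted[j, 2L]]
    ppi_a <- c(ppi_a, t1)
    ppi_b <- c(ppi_b, t2)
    if (config$ppi_shared_partners > 0L) {
      partners <- genes[sort(sample.int(config$n_genes,
                                        config$ppi_shared_partners))]
      ppi_a <- c(ppi_a, rep(t1, length(partners)), rep(t2, length(partners)))
      ppi_b <- c(ppi_b, partners, partners)
    }
  }
  if (config$ppi_noise_edges > 0L) {
    ppi_a <- c(ppi_a, tfs[sample.int(config$n_tfs, config$ppi_noise_edges,
                                     replace = TRUE)])
    ppi_b <- c(ppi_b, genes[sample.int(config$n_genes,
                                       config$ppi_noise_edges,
                                       replace = TRUE)])
  }
  ppi <- ppi_network(ppi_a, ppi_b)

  truth <- if (config$n_planted_pairs > 0L) {
    cp <- canonical_pair(tfs[planted[, 1L]], tfs[planted[, 2L]])
    data.frame(tf1 = cp[, 1L], tf2 = cp[, 2L], stringsAsFactors = FALSE)
  } else {
    data.frame(tf1 = character(), tf2 = character(),
               stringsAsFactors = FALSE)
  }

  out <- list(config = config, regulation = regulation, tfbs = tfbs,
              track = track, ppi = ppi, truth = truth,
              promoters = promoters)
  if (!is.null(out_dir)) {
    out$paths <- write_synthetic_dataset(out, out_dir)
  }
  out
}

write_synthetic_dataset <- function(dataset, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list(
    regulation = file.path(out_dir, "regulation.tsv"),
    tfbs = file.path(out_dir, "tfbs.bed"),
    nucleosome = file.path(out_dir, "nucleosome.bed"),
    ppi = file.path(out_dir, "ppi.tsv"),
    truth = file.path(out_dir, "truth.tsv"),
    config = file.path(out_dir, "config.json")
  )
  reg <- dataset$regulation
  writeLines(paste(reg$tf, reg$gene, sep = "\t"), paths$regulation)
  tfbs <- dataset$tfbs
  writeLines(paste(tfbs$chrom, tfbs$start, tfbs$end, tfbs$tf,
                   sprintf("%.6f", tfbs$posterior), tfbs$strand, tfbs$gene,
                   sep = "\t"), paths$tfbs)
  iv <- dataset$track$intervals
  writeLines(paste(iv$chrom, iv$start, iv$end, sep = "\t"),
             paths$nucleosome)
  edges <- dataset$ppi$edges
  writeLines(paste(edges$a, edges$b, sep = "\t"), paths$ppi)
  writeLines(paste(dataset$truth$tf1, dataset$truth$tf2, sep = "\t"),
             paths$truth)
  cfg <- unclass(dataset$config)
  jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths
}

#' Fraction of planted pairs recovered in the top of a ranking
#'
#' @param results a ranked `PairResultTable` (highest score first).
#' @param truth data frame of planted pairs (`tf1`, `tf2`).
#' @param top_k how deep into the ranking to look.
#' @return fraction of planted pairs among the top `top_k` ranked pairs
#'   (1 when there are no planted pairs).
#' @export
recovery_check <- function(results, truth, top_k) {
  stopifnot(is.data.frame(results), is.data.frame(truth))
  if (!nrow(truth)) return(1)
  top <- utils::head(results, top_k)
  top_keys <- pair_key(top$tf1, top$tf2)
  mean(pair_key(truth$tf1, truth$tf2) %in% top_keys)
}
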