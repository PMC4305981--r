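## Target assignment: from documented regulation and posterior-filtered
## binding sites to per-TF target-gene sets and the per-(TF, gene) best site.

#' Filter binding sites by posterior probability
#'
#' Keeps exactly the sites whose posterior probability is greater than or
#' equal to the threshold (inclusive comparison).
#'
#' @param sites a `TFBSTable`.
#' @param posterior_threshold number in `[0, 1]`; default 0.3.
#' @return the filtered `TFBSTable`.
#' @export
filter_tfbs <- function(sites, posterior_threshold = 0.3) {
  stopifnot(is.data.frame(sites))
  if (!is.numeric(posterior_threshold) || length(posterior_threshold) != 1L ||
      is.na(posterior_threshold) || posterior_threshold < 0 ||
      posterior_threshold > 1) {
    stop("posterior_threshold must be a single number in [0, 1]",
         call. = FALSE)
  }
  out <- sites[sites$posterior >= posterior_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the best binding site per (TF, gene)
#'
#' When several sites of the same TF are assigned to the same gene, only the
#' most confident one (highest posterior probability) is kept. Ties on
#' posterior are broken by smallest start coordinate, then lexicographic
#' chromosome name, so the selection is deterministic and independent of the
#' input row order.
#'
#' @param sites a `TFBSTable`, already posterior-filtered (the filter is not
#'   re-applied here; apply [filter_tfbs()] first so a sub-threshold site can
#'   never win).
#' @return a `BestSiteIndex` data frame: one row per (TF, gene), columns as
#'   in the input.
#' @export
build_best_site_index <- function(sites) {
  stopifnot(is.data.frame(sites))
  o <- order(sites$tf, sites$gene, -sites$posterior, sites$start,
             sites$chrom)
  out <- sites[o, , drop = FALSE]
  keep <- !duplicated(paste(out$tf, out$gene, sep = "\r"))
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("BestSiteIndex", class(sites))
  out
}

#' Define each TF's target-gene set
#'
#' A gene is a target of a TF if it is documented as regulated by that TF,
#' or if its promoter carries a (best, posterior-passing) binding site of
#' that TF — the union of the two evidence sources. TFs seen in either
#' source are retained even when their target set is empty.
#'
#' @param regulation a `RegulationTable`, or `NULL`.
#' @param best_sites a `BestSiteIndex` (see [build_best_site_index()]), or
#'   `NULL`.
#' @param total_genes size `N` of the gene universe used by the
#'   hypergeometric overlap test; default 6576 (yeast genome). Must be at
#'   least the number of distinct genes observed.
#' @return a `TargetGeneSets` object: named list `targets` (TF -> character
#'   vector of genes, sorted) plus `total_genes`.
#' @export
define_targets <- function(regulation = NULL, best_sites = NULL,
                           total_genes = 6576L) {
  tf <- character()
  gene <- character()
  if (!is.null(regulation)) {
    tf <- c(tf, regulation$tf)
    gene <- c(gene, regulation$gene)
  }
  if (!is.null(best_sites)) {
    tf <- c(tf, best_sites$tf)
    gene <- c(gene, best_sites$gene)
  }
  universe <- unique(gene)
  total_genes <- as.integer(total_genes)
  if (is.na(total_genes) || total_genes < length(universe)) {
    stop(sprintf(
      "total_genes (%d) is smaller than the number of distinct genes observed (%d)",
      total_genes, length(universe)), call. = FALSE)
  }
  targets <- lapply(split(gene, factor(tf, levels = sort(unique(tf)))),
                    function(g) sort(unique(g)))
  structure(list(targets = targets, total_genes = total_genes),
            class = "TargetGeneSets")
}

#' @export
print.TargetGeneSets <- function(x, ...) {
  sizes <- lengths(x$targets)
  cat(sprintf(
    "TargetGeneSets: %d TFs, gene universe N = %d, target-set sizes %s..%s (median %s)\n",
    length(sizes), x$total_genes,
    if (length(sizes)) min(sizes) else NA, if (length(sizes)) max(sizes) else NA,
    if (length(sizes)) stats::median(sizes) else NA))
  invisible(x)
}

#' Enumerate all unordered TF pairs
#'
#' @param tfs a `TargetGeneSets` object or a character vector of TF
#'   identifiers (at least 2).
#' @return a data frame with columns `tf1`, `tf2` holding all
#'   `k * (k - 1) / 2` unordered pairs in a deterministic (lexicographic)
#'   order, each pair canonically ordered.
#' @export
enumerate_pairs <- function(tfs) {
  if (inherits(tfs, "TargetGeneSets")) tfs <- names(tfs$targets)
  tfs <- sort(unique(norm_id(tfs)))
  if (length(tfs) < 2L) {
    stop("need at least 2 TFs to enumerate pairs", call. = FALSE)
  }
  idx <- combn(length(tfs), 2L)
  data.frame(tf1 = tfs[idx[1L, ]], tf2 = tfs[idx[2L, ]],
             stringsAsFactors = FALSE)
}

#' Assign binding sites to genes by upstream promoter windows
#'
#' Optional helper for inputs whose seventh column is absent or untrusted:
#' re-derives the gene assignment of each site from a promoter table. A site
#' is assigned to a gene when the site midpoint falls inside the gene's
#' promoter interval (0-based half-open). Not used by the default pipeline,
#' which trusts the assignment shipped in the TFBS file.
#'
#' @param sites a `TFBSTable` (the `gene` column is overwritten).
#' @param promoters data frame with columns `gene`, `chrom`, `start`, `end`
#'   (0-based half-open promoter intervals, non-overlapping).
#' @return a `TFBSTable` restricted to sites that fall in some promoter.
#' @export
assign_genes_by_window <- function(sites, promoters) {
  stopifnot(is.data.frame(sites), is.data.frame(promoters),
            all(c("gene", "chrom", "start", "end") %in% names(promoters)))
  mid <- (sites$start + sites$end) %/% 2L
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(mid + 1L, mid + 1L))
  prom_gr <- GenomicRanges::GRanges(promoters$chrom,
                                    IRanges::IRanges(promoters$start + 1L,
                                                     promoters$end))
  hits <- GenomicRanges::findOverlaps(site_gr, prom_gr, select = "first")
  keep <- !is.na(hits)
  out <- sites[keep, , drop = FALSE]
  out$gene <- norm_id(promoters$gene[hits[keep]])
  rownames(out) <- NULL
  out
}
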