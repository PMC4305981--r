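## Cooperativity core: hypergeometric target-overlap significance, nucleosome
## occupancy states, the 2x2 co-depletion contingency table and its one-sided
## Fisher exact tail, the combined cooperativity score, all-pairs scoring,
## thresholded prediction, and network export.
##
## All tail probabilities are computed in log space from log-gamma binomial
## coefficients (lchoose), so p-values far below double-precision underflow
## are still reported as finite log10 values and scores stay finite.

log_sum_exp <- function(x) {
  x <- x[x > -Inf]
  if (!length(x)) return(-Inf)
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

## log10 of sum_{i = m}^{min(n1, n2)} C(n1, i) C(N - n1, n2 - i) / C(N, n2).
log10_hyper_tail <- function(n1, n2, m, total) {
  lo <- max(m, n1 + n2 - total, 0L)
  hi <- min(n1, n2)
  if (lo > hi) {
    stop("hypergeometric tail: lower summation bound exceeds support",
         call. = FALSE)
  }
  ## Tail covering the whole support sums to exactly 1.
  if (lo <= max(0L, n1 + n2 - total)) return(0)
  i <- lo:hi
  lp <- log_sum_exp(lchoose(n1, i) + lchoose(total - n1, n2 - i)) -
    lchoose(total, n2)
  min(lp, 0) / log(10)
}

#' Significance of target-gene overlap (hypergeometric tail)
#'
#' Probability of observing `m` or more shared target genes between two TFs
#' with `n1` and `n2` targets drawn from a universe of `total_genes` genes:
#' \deqn{P_{overlap} = \sum_{i=m}^{\min(N_1, N_2)}
#'   \frac{\binom{N_1}{i} \binom{N - N_1}{N_2 - i}}{\binom{N}{N_2}}.}
#' Computed in log space; `m = 0` sums the whole distribution and returns 1.
#'
#' @param n1,n2 target-set sizes of the two TFs.
#' @param m number of common target genes, `0 <= m <= min(n1, n2)`.
#' @param total_genes gene-universe size `N`; default 6576.
#' @return a list with `p` (probability, 0 if underflowed) and `log10p`
#'   (always finite, `<= 0`).
#' @export
overlap_pvalue <- function(n1, n2, m, total_genes = 6576L) {
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  m <- as.integer(m); total_genes <- as.integer(total_genes)
  if (anyNA(c(n1, n2, m, total_genes)) || n1 < 0L || n2 < 0L || m < 0L) {
    stop("overlap_pvalue: n1, n2, m must be non-negative integers",
         call. = FALSE)
  }
  if (m > min(n1, n2)) {
    stop(sprintf("overlap_pvalue: m (%d) exceeds min(n1, n2) = %d",
                 m, min(n1, n2)), call. = FALSE)
  }
  if (n1 > total_genes || n2 > total_genes) {
    stop("overlap_pvalue: target-set sizes exceed the gene universe",
         call. = FALSE)
  }
  l10 <- log10_hyper_tail(n1, n2, m, total_genes)
  list(p = 10^l10, log10p = l10)
}

#' Nucleosome occupancy state of a binding site
#'
#' A site is *occupied* (state 1) if any of its positions is covered by an
#' occupied nucleosome interval on the same chromosome, and *depleted*
#' (state 0) if no position is — including when the site's chromosome is
#' absent from the track. Intervals are 0-based half-open, so an interval
#' ending exactly where the site starts does not overlap it.
#'
#' @param site a single-row `TFBSTable` (or any list with `chrom`, `start`,
#'   `end`).
#' @param track a `NucleosomeTrack`.
#' @return integer, 1 (occupied) or 0 (depleted).
#' @export
occupancy_state <- function(site, track) {
  occupancy_states(data.frame(chrom = as.character(site$chrom[1L]),
                              start = as.integer(site$start[1L]),
                              end = as.integer(site$end[1L]),
                              stringsAsFactors = FALSE),
                   track)[1L]
}

#' Vectorized occupancy states for a site table
#'
#' @param sites data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param track a `NucleosomeTrack`.
#' @param quiet suppress the note emitted when sites lie on chromosomes
#'   absent from the track.
#' @return integer vector of 0/1 states, one per row of `sites`.
#' @export
occupancy_states <- function(sites, track, quiet = FALSE) {
  stopifnot(inherits(track, "NucleosomeTrack"), is.data.frame(sites))
  if (!nrow(sites)) return(integer())
  unknown <- setdiff(unique(sites$chrom), unique(track$intervals$chrom))
  if (length(unknown) && !quiet) {
    message(sprintf(
      "occupancy: %d site(s) on chromosome(s) absent from the track (%s); treated as depleted",
      sum(sites$chrom %in% unknown), paste(unknown, collapse = ", ")))
  }
  site_gr <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$start + 1L, end = sites$end))
  hits <- suppressWarnings(
    GenomicRanges::countOverlaps(site_gr, track$granges))
  as.integer(hits > 0L)
}

#' Build the co-depletion contingency table for a TF pair
#'
#' Set `A` holds the common target genes of the pair whose promoters carry a
#' best binding site for *both* TFs. Each gene in `A` falls in exactly one
#' cell of a 2x2 table according to the occupancy states
#' `(S(TFBS1), S(TFBS2))`:
#' `a` = both depleted, `b` = TF1 occupied / TF2 depleted,
#' `c` = TF1 depleted / TF2 occupied, `d` = both occupied.
#'
#' @param tf1,tf2 TF identifiers (distinct).
#' @param targets a `TargetGeneSets`.
#' @param best_sites a `BestSiteIndex`.
#' @param track a `NucleosomeTrack`.
#' @return list with `set_a` (character vector of genes) and `table`
#'   (named integer vector `a`, `b`, `c`, `d`).
#' @export
build_contingency <- function(tf1, tf2, targets, best_sites, track) {
  tf1 <- norm_id(tf1); tf2 <- norm_id(tf2)
  if (tf1 == tf2) stop("build_contingency: tf1 and tf2 must differ",
                       call. = FALSE)
  common <- intersect(targets$targets[[tf1]], targets$targets[[tf2]])
  occ <- best_sites$occupied
  if (is.null(occ)) occ <- occupancy_states(best_sites, track, quiet = TRUE)
  key <- paste(best_sites$tf, best_sites$gene, sep = "\r")
  s1 <- occ[match(paste(tf1, common, sep = "\r"), key)]
  s2 <- occ[match(paste(tf2, common, sep = "\r"), key)]
  in_a <- !is.na(s1) & !is.na(s2)
  set_a <- common[in_a]
  s1 <- s1[in_a]; s2 <- s2[in_a]
  tab <- c(a = sum(s1 == 0L & s2 == 0L), b = sum(s1 == 1L & s2 == 0L),
           c = sum(s1 == 0L & s2 == 1L), d = sum(s1 == 1L & s2 == 1L))
  list(set_a = sort(set_a), table = as.integer(tab) |> setNames(names(tab)))
}

#' Significance of nucleosome co-depletion (one-sided Fisher exact tail)
#'
#' Given the 2x2 table of occupancy states over set `A`, returns the
#' probability of a co-depletion count at least as large as `a` under fixed
#' margins:
#' \deqn{P_{nu} = \sum_{i=a}^{\min(a+b,\,a+c)}
#'   \frac{\binom{a+b}{i} \binom{c+d}{a+c-i}}{\binom{a+b+c+d}{a+c}}.}
#' This is the enrichment (upper) tail of the Fisher exact test, favoring
#' large `a`. An empty table (all cells 0) returns 1 by convention, as does
#' `a = 0` (the sum then spans the whole support): absence of data never
#' manufactures significance.
#'
#' @param a,b,c,d non-negative cell counts; alternatively pass a named
#'   vector/list as `a` (as produced by [build_contingency()]).
#' @return a list with `p` and `log10p` as in [overlap_pvalue()].
#' @export
codepletion_pvalue <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.null(b) && length(a) == 4L) {
    tab <- as.integer(unlist(a))
    a <- tab[1L]; b <- tab[2L]; c <- tab[3L]; d <- tab[4L]
  }
  cells <- as.integer(c(a, b, c, d))
  if (anyNA(cells) || any(cells < 0L)) {
    stop("codepletion_pvalue: cells must be non-negative integers",
         call. = FALSE)
  }
  a <- cells[1L]; b <- cells[2L]; c <- cells[3L]; d <- cells[4L]
  n <- a + b + c + d
  if (n == 0L) return(list(p = 1, log10p = 0))
  lo <- max(a, (a + c) - (c + d), 0L)
  hi <- min(a + b, a + c)
  if (lo <= max(0L, (a + c) - (c + d))) return(list(p = 1, log10p = 0))
  i <- lo:hi
  lp <- log_sum_exp(lchoose(a + b, i) + lchoose(c + d, (a + c) - i)) -
    lchoose(n, a + c)
  l10 <- min(lp, 0) / log(10)
  list(p = 10^l10, log10p = l10)
}

#' Combined cooperativity score
#'
#' `score = -log10(P_overlap) - log10(P_nu)`. Accepts either probabilities
#' or (preferably) log10 values, so scores remain finite when a p-value
#' underflows double precision.
#'
#' @param p_overlap,p_nu probabilities in `(0, 1]`; ignored when the
#'   corresponding log10 argument is given.
#' @param log10_p_overlap,log10_p_nu log10 p-values (`<= 0`).
#' @return non-negative numeric score.
#' @export
cooperativity_score <- function(p_overlap = NULL, p_nu = NULL,
                                log10_p_overlap = NULL, log10_p_nu = NULL) {
  as_log10 <- function(p, lp, what) {
    if (!is.null(lp)) {
      if (any(lp > 1e-9)) stop(sprintf("%s: log10 p-value must be <= 0", what),
                               call. = FALSE)
      return(pmin(lp, 0))
    }
    if (is.null(p) || any(is.na(p)) || any(p <= 0) || any(p > 1)) {
      stop(sprintf("%s: probability must lie in (0, 1]", what),
           call. = FALSE)
    }
    log10(p)
  }
  l1 <- as_log10(p_overlap, log10_p_overlap, "p_overlap")
  l2 <- as_log10(p_nu, log10_p_nu, "p_nu")
  -(l1 + l2)
}

#' Score every unordered TF pair
#'
#' Runs the full per-pair computation: target-overlap significance,
#' contingency table over set `A`, co-depletion significance, and the
#' combined score; then ranks pairs by score (descending), breaking ties by
#' canonical pair name so the output is deterministic. Pairs with no common
#' targets are retained with `P_overlap = 1`, and a degenerate set `A`
#' contributes `P_nu = 1` (score contribution 0).
#'
#' @param targets a `TargetGeneSets` (see [define_targets()]).
#' @param best_sites a `BestSiteIndex`.
#' @param track a `NucleosomeTrack`.
#' @param disable_nucleosome logical; when `TRUE`, the nucleosome term is
#'   ablated (`P_nu` forced to 1) and the score reduces to
#'   `-log10(P_overlap)`. The contingency cells are still reported.
#' @return a `PairResultTable`: one row per unordered pair with columns
#'   `tf1, tf2, n1, n2, m, p_overlap, a, b, c, d, p_nu, score` plus
#'   `log10_p_overlap`, `log10_p_nu`.
#' @export
score_all_pairs <- function(targets, best_sites, track,
                            disable_nucleosome = FALSE) {
  stopifnot(inherits(targets, "TargetGeneSets"))
  pairs <- enumerate_pairs(targets)
  total <- targets$total_genes
  gene_sets <- targets$targets
  bs <- best_sites
  bs$occupied <- occupancy_states(bs, track, quiet = TRUE)

  n_pairs <- nrow(pairs)
  n1 <- integer(n_pairs); n2 <- integer(n_pairs); m <- integer(n_pairs)
  cells <- matrix(0L, n_pairs, 4L,
                  dimnames = list(NULL, c("a", "b", "c", "d")))
  l10_ov <- numeric(n_pairs); l10_nu <- numeric(n_pairs)
  for (k in seq_len(n_pairs)) {
    t1 <- pairs$tf1[k]; t2 <- pairs$tf2[k]
    g1 <- gene_sets[[t1]]; g2 <- gene_sets[[t2]]
    n1[k] <- length(g1); n2[k] <- length(g2)
    m[k] <- length(intersect(g1, g2))
    l10_ov[k] <- log10_hyper_tail(n1[k], n2[k], m[k], total)
    ct <- build_contingency(t1, t2, targets, bs, track)
    cells[k, ] <- ct$table
    l10_nu[k] <- if (disable_nucleosome) 0 else
      codepletion_pvalue(ct$table)$log10p
  }
  out <- data.frame(
    tf1 = pairs$tf1, tf2 = pairs$tf2, n1 = n1, n2 = n2, m = m,
    p_overlap = 10^l10_ov,
    a = cells[, "a"], b = cells[, "b"], c = cells[, "c"], d = cells[, "d"],
    p_nu = 10^l10_nu,
    score = -(l10_ov + l10_nu),
    log10_p_overlap = l10_ov, log10_p_nu = l10_nu,
    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$tf1, out$tf2), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("PairResultTable", "data.frame")
  out
}

#' Predict cooperative TF pairs by score threshold
#'
#' Pairs whose cooperativity score is strictly greater than the threshold
#' are predicted as cooperative, in rank order.
#'
#' @param results a `PairResultTable` from [score_all_pairs()].
#' @param score_threshold numeric; default 120.
#' @return the predicted subset of `results`, rank order preserved.
#' @export
predict_pairs <- function(results, score_threshold = 120) {
  stopifnot(is.data.frame(results), "score" %in% names(results))
  out <- results[results$score > score_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export predicted pairs as a network edge list
#'
#' Writes a TSV with one edge per predicted pair and an optional
#' `shared_categories` attribute: the intersection of the two TFs'
#' annotation categories (joined with `";"`, empty when none are shared).
#'
#' @param predicted data frame with columns `tf1`, `tf2`.
#' @param path output file path.
#' @param annotations optional named list mapping TF identifier to a
#'   character vector of category names.
#' @return `path`, invisibly.
#' @export
export_network <- function(predicted, path, annotations = NULL) {
  stopifnot(is.data.frame(predicted))
  shared <- character(nrow(predicted))
  if (!is.null(annotations)) {
    names(annotations) <- norm_id(names(annotations))
    for (k in seq_len(nrow(predicted))) {
      cats <- intersect(annotations[[predicted$tf1[k]]] %||% character(),
                        annotations[[predicted$tf2[k]]] %||% character())
      shared[k] <- paste(cats, collapse = ";")
    }
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("tf1\ttf2\tshared_categories", con)
  if (nrow(predicted)) {
    writeLines(paste(predicted$tf1, predicted$tf2, shared, sep = "\t"), con)
  }
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
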