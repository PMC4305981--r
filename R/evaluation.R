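## Evaluation: PPI-partner overlap significance (index 1), benchmark
## enrichment (index 3), precision/recall, evidence-line summaries for the
## annotated prediction table, and a pluggable functional-similarity hook
## (index 2's measure itself is out of scope; only the plumbing ships).

#' PPI-partner overlap significance for one TF pair
#'
#' Measures how significantly two TFs share protein-protein interaction
#' partners: `N1` and `N2` are their partner-set sizes, `m` the shared
#' partner count, and the p-value is the hypergeometric tail of
#' [overlap_pvalue()] over a universe of `total_genes` proteins. Returns
#' `-log10(P)`; a TF absent from the network has an empty partner set and
#' scores 0.
#'
#' @param tf1,tf2 TF identifiers.
#' @param ppi a `PPINetwork`.
#' @param total_genes protein-universe size; default 6575.
#' @return non-negative score `-log10(P)`.
#' @export
ppi_partner_overlap_score <- function(tf1, tf2, ppi, total_genes = 6575L) {
  p1 <- ppi_partners(ppi, tf1)
  p2 <- ppi_partners(ppi, tf2)
  if (length(p1) > total_genes || length(p2) > total_genes) {
    stop("ppi_partner_overlap_score: partner sets exceed the protein universe",
         call. = FALSE)
  }
  m <- length(intersect(p1, p2))
  -log10_hyper_tail(length(p1), length(p2), m, as.integer(total_genes))
}

#' Performance index 1: mean PPI-partner overlap score
#'
#' The mean of [ppi_partner_overlap_score()] over a list of predicted pairs.
#'
#' @param predicted data frame with columns `tf1`, `tf2` (non-empty).
#' @param ppi a `PPINetwork`.
#' @param total_genes protein-universe size; default 6575.
#' @return list with `mean` and `per_pair` (numeric vector).
#' @export
index1 <- function(predicted, ppi, total_genes = 6575L) {
  stopifnot(is.data.frame(predicted))
  if (!nrow(predicted)) {
    stop("index1: empty prediction list", call. = FALSE)
  }
  per_pair <- mapply(ppi_partner_overlap_score, predicted$tf1,
                     predicted$tf2,
                     MoreArgs = list(ppi = ppi, total_genes = total_genes),
                     USE.NAMES = FALSE)
  list(mean = mean(per_pair), per_pair = per_pair)
}

#' Performance index 3: benchmark-overlap significance
#'
#' Significance of the overlap between a predicted pair list and a benchmark
#' set of known cooperative pairs, over a universe of `universe_size`
#' candidate pairs (default 17205 = choose(186, 2)). The 2x2 table
#' (in-both / predicted-only / benchmark-only / neither) is tested with the
#' one-sided Fisher enrichment tail of [codepletion_pvalue()]; the score is
#' `-log10(P)`.
#'
#' Benchmark pairs involving TFs outside `tf_universe` (when given) are
#' dropped with a message, since such pairs are unreachable by the method.
#'
#' @param predicted data frame with columns `tf1`, `tf2`.
#' @param benchmark a `BenchmarkSet` (or any `tf1`/`tf2` data frame).
#' @param universe_size number of candidate pairs; default 17205.
#' @param tf_universe optional character vector of TF identifiers defining
#'   the method's universe.
#' @return list with `score` (`-log10(P)`), `p`, `table` (named `a..d`),
#'   and `n_benchmark_used`.
#' @export
index3 <- function(predicted, benchmark, universe_size = 17205L,
                   tf_universe = NULL) {
  stopifnot(is.data.frame(predicted), is.data.frame(benchmark))
  pk <- unique(pair_key(predicted$tf1, predicted$tf2))
  bk <- unique(pair_key(benchmark$tf1, benchmark$tf2))
  if (!is.null(tf_universe)) {
    tf_universe <- norm_id(tf_universe)
    keep <- benchmark$tf1 %in% tf_universe & benchmark$tf2 %in% tf_universe
    bk_keep <- unique(pair_key(benchmark$tf1[keep], benchmark$tf2[keep]))
    if (length(bk_keep) < length(bk)) {
      message(sprintf(
        "index3: dropping %d benchmark pair(s) with TFs outside the prediction universe",
        length(bk) - length(bk_keep)))
    }
    bk <- bk_keep
  }
  universe_size <- as.integer(universe_size)
  n_union <- length(union(pk, bk))
  if (universe_size < n_union) {
    stop(sprintf(
      "index3: universe_size (%d) smaller than the %d distinct pairs observed",
      universe_size, n_union), call. = FALSE)
  }
  a <- length(intersect(pk, bk))
  tab <- c(a = a, b = length(pk) - a, c = length(bk) - a,
           d = universe_size - n_union)
  pv <- codepletion_pvalue(tab)
  list(score = -pv$log10p, p = pv$p, table = tab,
       n_benchmark_used = length(bk))
}

#' Precision and recall against a benchmark set
#'
#' Unordered-pair matching: `precision = |P & B| / |P|`,
#' `recall = |P & B| / |B|`.
#'
#' @inheritParams index3
#' @param tf_universe optional TF universe; benchmark pairs outside it are
#'   dropped from the recall denominator (with a message), mirroring
#'   [index3()].
#' @return list with `precision`, `recall`, `n_overlap`.
#' @export
precision_recall <- function(predicted, benchmark, tf_universe = NULL) {
  stopifnot(is.data.frame(predicted), is.data.frame(benchmark))
  if (!nrow(benchmark)) stop("precision_recall: empty benchmark set",
                             call. = FALSE)
  if (!nrow(predicted)) stop("precision_recall: empty prediction list",
                             call. = FALSE)
  pk <- unique(pair_key(predicted$tf1, predicted$tf2))
  bk <- unique(pair_key(benchmark$tf1, benchmark$tf2))
  if (!is.null(tf_universe)) {
    tf_universe <- norm_id(tf_universe)
    keep <- benchmark$tf1 %in% tf_universe & benchmark$tf2 %in% tf_universe
    bk2 <- unique(pair_key(benchmark$tf1[keep], benchmark$tf2[keep]))
    if (length(bk2) < length(bk)) {
      message(sprintf(
        "precision_recall: dropping %d benchmark pair(s) outside the prediction universe",
        length(bk) - length(bk2)))
    }
    bk <- bk2
    if (!length(bk)) stop("precision_recall: no benchmark pairs left in universe",
                          call. = FALSE)
  }
  n_overlap <- length(intersect(pk, bk))
  list(precision = n_overlap / length(pk), recall = n_overlap / length(bk),
       n_overlap = n_overlap)
}

#' Summarize the evidence lines of an annotated prediction table
#'
#' Each row of the annotation table (shape of [load_table1_fixture()]) can
#' carry up to three lines of evidence: citations of other prediction
#' methods, a physical PPI between the two TFs, and shared functional
#' (MIPS) categories. Rows with no method citation are *novel* predictions.
#'
#' @param rows data frame with columns `method_citations` (list),
#'   `has_ppi` (`"yes"`/`"unknown"`), `mips_categories` (list).
#' @return list of counts: `n_rows`, `n_consistent_with_existing`,
#'   `n_novel`, `n_all_three_lines`, `n_two_lines`, `n_one_line`,
#'   `n_zero_lines`, `novel_with_ppi_and_mips`.
#' @export
summarize_evidence <- function(rows) {
  stopifnot(is.data.frame(rows),
            all(c("method_citations", "has_ppi", "mips_categories") %in%
                  names(rows)))
  has_cit <- lengths(rows$method_citations) > 0L
  has_ppi <- rows$has_ppi == "yes"
  has_mips <- lengths(rows$mips_categories) > 0L
  n_lines <- has_cit + has_ppi + has_mips
  list(
    n_rows = nrow(rows),
    n_consistent_with_existing = sum(has_cit),
    n_novel = sum(!has_cit),
    n_all_three_lines = sum(n_lines == 3L),
    n_two_lines = sum(n_lines == 2L),
    n_one_line = sum(n_lines == 1L),
    n_zero_lines = sum(n_lines == 0L),
    novel_with_ppi_and_mips = sum(!has_cit & has_ppi & has_mips)
  )
}

#' Pluggable functional-similarity index (plumbing only)
#'
#' Applies a caller-supplied pair-scoring function to every predicted pair
#' and returns the mean — the shape of a functional-similarity performance
#' index. No semantic-similarity measure ships with the package; only a
#' trivial provider for testing, [constant_similarity_provider()].
#'
#' @param provider function of two TF identifiers returning a single number.
#' @param predicted non-empty data frame with columns `tf1`, `tf2`.
#' @return list with `mean` and `per_pair`.
#' @export
functional_similarity_hook <- function(provider, predicted) {
  stopifnot(is.function(provider), is.data.frame(predicted))
  if (!nrow(predicted)) {
    stop("functional_similarity_hook: empty prediction list", call. = FALSE)
  }
  per_pair <- vapply(seq_len(nrow(predicted)), function(k) {
    tryCatch(as.numeric(provider(predicted$tf1[k], predicted$tf2[k])),
             error = function(e) {
               stop(sprintf("similarity provider failed on pair (%s, %s): %s",
                            predicted$tf1[k], predicted$tf2[k],
                            conditionMessage(e)), call. = FALSE)
             })
  }, numeric(1L))
  list(mean = mean(per_pair), per_pair = per_pair)
}

#' @rdname functional_similarity_hook
#' @param value the constant returned for every pair.
#' @export
constant_similarity_provider <- function(value = 1) {
  force(value)
  function(tf1, tf2) value
}

#' Full evaluation report for a predicted pair list
#'
#' Convenience wrapper combining [index1()], [index3()] and
#' [precision_recall()] into one report (used by the CLI `evaluate`
#' subcommand).
#'
#' @param predicted data frame with columns `tf1`, `tf2`.
#' @param ppi optional `PPINetwork`.
#' @param benchmark optional `BenchmarkSet`.
#' @param ppi_universe protein-universe size for index 1; default 6575.
#' @param pair_universe pair-universe size for index 3; default 17205.
#' @param tf_universe optional TF universe for benchmark restriction.
#' @return list with whichever of `index1_mean`, `per_pair_index1`,
#'   `index3_score`, `precision`, `recall` the inputs allow.
#' @export
evaluate_predictions <- function(predicted, ppi = NULL, benchmark = NULL,
                                 ppi_universe = 6575L,
                                 pair_universe = 17205L,
                                 tf_universe = NULL) {
  out <- list(n_predicted = nrow(predicted))
  if (!is.null(ppi)) {
    i1 <- index1(predicted, ppi, total_genes = ppi_universe)
    out$index1_mean <- i1$mean
    out$per_pair_index1 <- i1$per_pair
  }
  if (!is.null(benchmark)) {
    i3 <- index3(predicted, benchmark, universe_size = pair_universe,
                 tf_universe = tf_universe)
    pr <- precision_recall(predicted, benchmark, tf_universe = tf_universe)
    out$index3_score <- i3$score
    out$precision <- pr$precision
    out$recall <- pr$recall
  }
  out
}
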