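test_that("ppi_partner_overlap_score matches the closed-form single-term tail", {
  # identical 5-partner sets in a 100-protein universe: the tail is the
  # single term 1 / choose(100, 5)
  edges_a <- paste0("P", 1:5)
  ppi <- ppi_network(a = c(rep("TFA", 5L), rep("TFB", 5L)),
                     b = c(edges_a, edges_a))
  got <- ppi_partner_overlap_score("TFA", "TFB", ppi, total_genes = 100L)
  expect_equal(got, oracle_log10_choose(100, 5), tolerance = 1e-10)

  # disjoint partner sets -> m = 0 -> score 0
  ppi2 <- ppi_network(a = c("TFA", "TFA", "TFB"), b = c("P1", "P2", "P3"))
  expect_equal(ppi_partner_overlap_score("TFA", "TFB", ppi2, 100L), 0)

  # TF absent from the network -> empty partner set -> score 0
  expect_equal(ppi_partner_overlap_score("TFA", "GHOST", ppi2, 100L), 0)
})

test_that("index1 is the arithmetic mean of per-pair scores", {
  ppi <- ppi_network(a = c(rep("TFA", 3L), rep("TFB", 3L)),
                     b = rep(paste0("P", 1:3), 2L))
  pairs1 <- data.frame(tf1 = "TFA", tf2 = "TFB")
  s <- ppi_partner_overlap_score("TFA", "TFB", ppi, 50L)
  expect_equal(index1(pairs1, ppi, 50L)$mean, s)

  pairs2 <- data.frame(tf1 = c("TFA", "TFA"), tf2 = c("TFB", "GHOST"))
  expect_equal(index1(pairs2, ppi, 50L)$mean, s / 2)

  pairs0 <- data.frame(tf1 = c("X", "Y"), tf2 = c("U", "V"))
  expect_equal(index1(pairs0, ppi, 50L)$mean, 0)

  expect_error(index1(pairs0[0L, ], ppi, 50L), "empty")
})

test_that("index3 scores benchmark overlap on a 45-pair toy universe", {
  # 10 TFs -> 45 unordered pairs; benchmark = 5 of them
  tfs <- paste0("T", sprintf("%02d", 1:10))
  all_pairs <- enumerate_pairs(tfs)
  bench <- all_pairs[1:5, ]

  full <- index3(bench, bench, universe_size = 45L)
  expect_equal(unname(full$table), c(5L, 0L, 0L, 40L))

  # a perfect 5-pair list beats every same-length list with fewer hits
  scores <- vapply(0:5, function(k) {
    pred <- rbind(bench[seq_len(k), ], all_pairs[5L + seq_len(5L - k), ])
    index3(pred, bench, universe_size = 45L)$score
  }, numeric(1L))
  expect_true(all(diff(scores) > 0))  # strictly increasing in overlap
  expect_equal(scores[[6L]], full$score)
  # the exact maximal score: P = 1 / choose(45, 5)
  expect_equal(full$score, oracle_log10_choose(45, 5), tolerance = 1e-10)

  # zero overlap: no enrichment, P near 1
  none <- index3(all_pairs[6:10, ], bench, universe_size = 45L)
  expect_equal(none$table[["a"]], 0L)
  expect_equal(none$p, 1)

  # benchmark pairs outside the TF universe are dropped with a message
  expect_message(
    r <- index3(bench, rbind(bench, data.frame(tf1 = "ZZ", tf2 = "ZY")),
                universe_size = 45L, tf_universe = tfs),
    "dropping 1")
  expect_equal(r$n_benchmark_used, 5L)

  expect_error(index3(all_pairs, bench, universe_size = 10L), "universe_size")
})

test_that("precision_recall matches set arithmetic and ignores ordering", {
  bench <- data.frame(tf1 = c("A", "C", "E", "G"), tf2 = c("B", "D", "F", "H"))
  same <- precision_recall(bench, bench)
  expect_equal(c(same$precision, same$recall), c(1, 1))

  none <- precision_recall(data.frame(tf1 = "X", tf2 = "Y"), bench)
  expect_equal(c(none$precision, none$recall), c(0, 0))

  half <- precision_recall(bench[1:2, ], bench)
  expect_equal(c(half$precision, half$recall), c(1, 0.5))

  # invariant under pair order and within-pair TF order
  shuffled <- data.frame(tf1 = c("D", "b", "H", "F"),
                         tf2 = c("c", "A", "G", "e"))
  sh <- precision_recall(shuffled, bench)
  expect_equal(c(sh$precision, sh$recall), c(1, 1))

  expect_error(precision_recall(bench[0L, ], bench), "empty prediction")
  expect_error(precision_recall(bench, bench[0L, ]), "empty benchmark")
})

test_that("summarize_evidence counts are conserved on random annotation tables", {
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(5:30, 1L)
    rows <- data.frame(rank = seq_len(n))
    rows$method_citations <- replicate(n, if (runif(1) < 0.5) character()
                                       else "B1", simplify = FALSE)
    rows$has_ppi <- sample(c("yes", "unknown"), n, replace = TRUE)
    rows$mips_categories <- replicate(n, if (runif(1) < 0.5) character()
                                      else c("x", "y"), simplify = FALSE)
    ev <- summarize_evidence(rows)
    expect_equal(ev$n_consistent_with_existing + ev$n_novel, n)
    expect_equal(ev$n_all_three_lines + ev$n_two_lines + ev$n_one_line +
                   ev$n_zero_lines, n)
    expect_lte(ev$novel_with_ppi_and_mips, ev$n_novel)
  }
})

test_that("functional similarity hook averages providers and names failures", {
  pred <- data.frame(tf1 = c("A", "B"), tf2 = c("X", "Y"))
  expect_equal(functional_similarity_hook(constant_similarity_provider(1),
                                          pred)$mean, 1)
  expect_equal(functional_similarity_hook(function(a, b) nchar(a), pred)$mean,
               1)
  bomb <- function(a, b) if (b == "Y") stop("boom") else 0.5
  expect_error(functional_similarity_hook(bomb, pred), "\\(B, Y\\)")
  expect_error(functional_similarity_hook(constant_similarity_provider(1),
                                          pred[0L, ]), "empty")
})
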