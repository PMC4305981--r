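test_that("overlap_pvalue matches hand-derived and oracle values", {
  # m = 0 sums the whole distribution
  expect_equal(overlap_pvalue(5, 5, 0, 20)$p, 1)
  expect_equal(overlap_pvalue(0, 3, 0, 10)$p, 1)

  # 2 shared of 2+2 in a 4-gene universe: enumeration gives 1/6
  expect_equal(overlap_pvalue(2, 2, 2, 4)$p, 1 / 6, tolerance = 1e-12)
  expect_equal(oracle_overlap_p(2, 2, 2, 4), 1 / 6)

  # complete 50-gene overlap in the yeast-sized universe: the tail is the
  # single term 1 / choose(6576, 50); checked against a log10 product that
  # never touches lgamma
  got <- overlap_pvalue(50, 50, 50, 6576)$log10p
  expect_equal(got, -oracle_log10_choose(6576, 50), tolerance = 1e-10)

  expect_error(overlap_pvalue(2, 3, 4, 10), "exceeds min")
  expect_error(overlap_pvalue(11, 3, 1, 10), "universe")
})

test_that("overlap_pvalue equals brute-force enumeration on random small cases", {
  set.seed(11)
  for (rep in 1:60) {
    N <- sample(2:11, 1L)
    n1 <- sample.int(N, 1L)
    n2 <- sample.int(N, 1L)
    m <- sample(0:min(n1, n2), 1L)
    expect_equal(overlap_pvalue(n1, n2, m, N)$p,
                 oracle_overlap_p(n1, n2, m, N), tolerance = 1e-12,
                 info = sprintf("n1=%d n2=%d m=%d N=%d", n1, n2, m, N))
  }
})

test_that("overlap_pvalue is non-increasing in m at fixed n1, n2, N", {
  for (case in list(c(5L, 7L, 20L), c(10L, 10L, 30L), c(3L, 9L, 12L))) {
    p <- vapply(0:min(case[1L], case[2L]), function(m)
      overlap_pvalue(case[1L], case[2L], m, case[3L])$log10p, numeric(1L))
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("occupancy_state follows half-open overlap semantics", {
  track <- nucleosome_track("chr1", 105L, 250L)
  site <- list(chrom = "chr1", start = 100L, end = 110L)
  expect_equal(occupancy_state(site, track), 1L)

  track2 <- nucleosome_track("chr1", 110L, 250L)
  expect_equal(occupancy_state(site, track2), 0L)

  expect_message(
    s <- occupancy_states(data.frame(chrom = "chrX", start = 100L,
                                     end = 110L), track),
    "absent")
  expect_equal(s, 0L)
})

test_that("build_contingency places genes in the stated cells", {
  w <- tiny_world()
  ct <- build_contingency("TFA", "TFB", w$targets, w$best, w$track)
  expect_equal(ct$set_a, c("G1", "G2", "G3", "G4"))
  expect_equal(unname(ct$table), c(1L, 1L, 1L, 1L))
  expect_equal(sum(ct$table), length(ct$set_a))

  # single gene, both sites depleted -> a = 1
  ct1 <- build_contingency("TFA", "TFB",
                           define_targets(regulation_table(c("TFA", "TFB"),
                                                           c("G1", "G1")),
                                          NULL, total_genes = 10L),
                           w$best, w$track)
  expect_equal(unname(ct1$table["a"]), 1L)
  expect_equal(sum(ct1$table), 1L)

  # a common target documented-only for one TF (no best site) leaves set A
  reg <- regulation_table(c("TFA", "TFB"), c("G9", "G9"))
  best_a_only <- build_best_site_index(tfbs_table(
    tf = "TFA", chrom = "chr1", start = 0L, end = 10L, posterior = 0.9,
    gene = "G9"))
  targets <- define_targets(reg, best_a_only, total_genes = 10L)
  ct2 <- build_contingency("TFA", "TFB", targets, best_a_only, w$track)
  expect_equal(length(ct2$set_a), 0L)
  expect_equal(sum(ct2$table), 0L)

  expect_error(build_contingency("TFA", "TFA", w$targets, w$best, w$track),
               "differ")
})

test_that("codepletion_pvalue matches hand-derived and oracle values", {
  expect_equal(codepletion_pvalue(3, 1, 1, 3)$p, 17 / 70, tolerance = 1e-12)
  expect_equal(oracle_fisher_p(3, 1, 1, 3), 17 / 70)

  # a = 0 spans the whole support
  for (tab in list(c(0, 4, 2, 7), c(0, 0, 3, 3), c(0, 5, 0, 0))) {
    expect_equal(codepletion_pvalue(tab[1], tab[2], tab[3], tab[4])$p, 1)
  }
  expect_equal(codepletion_pvalue(0, 0, 0, 0)$p, 1)
  expect_error(codepletion_pvalue(-1, 0, 0, 0), "non-negative")
})

test_that("codepletion_pvalue equals enumeration and is transpose-symmetric", {
  set.seed(13)
  for (rep in 1:50) {
    cells <- as.integer(rmultinom(1L, sample(1:11, 1L), rep(0.25, 4L)))
    a <- cells[1L]; b <- cells[2L]; c <- cells[3L]; d <- cells[4L]
    expect_equal(codepletion_pvalue(a, b, c, d)$p, oracle_fisher_p(a, b, c, d),
                 tolerance = 1e-12,
                 info = paste(cells, collapse = ","))
    # swapping the off-diagonal cells (margin swap) leaves the tail unchanged
    expect_equal(codepletion_pvalue(a, b, c, d)$log10p,
                 codepletion_pvalue(a, c, b, d)$log10p, tolerance = 1e-12)
  }
})

test_that("codepletion term normalizes to 1 over the full support", {
  set.seed(17)
  for (rep in 1:25) {
    cells <- as.integer(rmultinom(1L, sample(2:12, 1L), rep(0.25, 4L)))
    a <- cells[1L]; b <- cells[2L]; c <- cells[3L]; d <- cells[4L]
    n <- a + b + c + d; r <- a + b; k <- a + c
    i <- max(0L, k - (n - r)):min(r, k)
    total <- sum(exp(lchoose(r, i) + lchoose(n - r, k - i) - lchoose(n, k)))
    expect_equal(total, 1, tolerance = 1e-12)
  }
})

test_that("codepletion_pvalue is non-increasing in a at fixed margins", {
  # margins (r1, r2) x (k, n-k) fixed at n = 12, r = 6, k = 6
  p <- vapply(0:6, function(a)
    codepletion_pvalue(a, 6L - a, 6L - a, a)$log10p, numeric(1L))
  expect_true(all(diff(p) <= 1e-12))
})

test_that("cooperativity_score combines log10 terms and validates inputs", {
  expect_equal(cooperativity_score(p_overlap = 1e-100, p_nu = 1e-30), 130)
  expect_equal(cooperativity_score(p_overlap = 1, p_nu = 1), 0)
  expect_equal(cooperativity_score(p_overlap = 1e-7, p_nu = 1e-3),
               cooperativity_score(p_overlap = 1e-3, p_nu = 1e-7))
  expect_equal(cooperativity_score(log10_p_overlap = -412.3,
                                   log10_p_nu = -20), 432.3)
  expect_error(cooperativity_score(p_overlap = 0, p_nu = 0.5), "p_overlap")
  expect_error(cooperativity_score(p_overlap = 0.5, p_nu = 1.5), "p_nu")
})

test_that("score_all_pairs ranks deterministically and honors the ablation flag", {
  w <- tiny_world()
  res <- score_all_pairs(w$targets, w$best, w$track)
  expect_equal(nrow(res), 1L)  # 2 TFs -> 1 pair
  expect_equal(res$m, 4L)
  expect_equal(res$a + res$b + res$c + res$d, 4L)
  expect_equal(res$score, -(res$log10_p_overlap + res$log10_p_nu))

  abl <- score_all_pairs(w$targets, w$best, w$track,
                         disable_nucleosome = TRUE)
  expect_equal(abl$p_nu, 1)
  expect_equal(abl$score, -abl$log10_p_overlap)

  # pairs with m = 0 are retained with P_overlap = 1
  reg <- regulation_table(c("A", "B"), c("G1", "G2"))
  tg <- define_targets(reg, NULL, total_genes = 10L)
  empty_best <- build_best_site_index(w$tfbs[0L, ])
  res0 <- score_all_pairs(tg, empty_best, w$track)
  expect_equal(res0$m, 0L)
  expect_equal(res0$p_overlap, 1)
  expect_equal(res0$score, 0)
})

test_that("scoring is invariant under input row permutations and TF label swap", {
  d <- simulate_dataset(synthetic_config(n_genes = 120L, n_tfs = 6L,
                                         n_planted_pairs = 2L, seed = 5L))
  ref <- run_synth(d)
  set.seed(1)
  perm <- d
  perm$tfbs <- d$tfbs[sample.int(nrow(d$tfbs)), ]
  perm$regulation <- d$regulation[sample.int(nrow(d$regulation)), ]
  expect_equal(as.data.frame(run_synth(perm)), as.data.frame(ref))

  # per-pair invariance under swapping tf1/tf2: relabel the two TFs of the
  # top pair with names that reverse their sort order
  top <- ref[1L, ]
  swap <- c(setNames("ZZZZ", top$tf1), setNames("AAAA", top$tf2))
  relabel <- function(x) ifelse(x %in% names(swap), swap[x], x)
  d2 <- d
  d2$tfbs$tf <- relabel(d2$tfbs$tf)
  d2$regulation$tf <- relabel(d2$regulation$tf)
  res2 <- run_synth(d2)
  row2 <- res2[res2$tf1 == "AAAA" & res2$tf2 == "ZZZZ", ]
  expect_equal(row2$score, top$score)
  expect_equal(row2$p_nu, top$p_nu)
  expect_equal(c(row2$n1, row2$n2), c(top$n2, top$n1))
  expect_equal(c(row2$b, row2$c), c(top$c, top$b))
  expect_equal(row2$m, top$m)
})

test_that("predict_pairs uses a strict threshold and preserves rank order", {
  res <- data.frame(tf1 = c("A", "B", "C"), tf2 = c("X", "Y", "Z"),
                    score = c(130, 120, 119))
  expect_equal(nrow(predict_pairs(res, 120)), 1L)
  expect_equal(nrow(predict_pairs(res, 0)), 3L)
  expect_equal(nrow(predict_pairs(res, 200)), 0L)
  expect_equal(predict_pairs(res, 119.5)$tf1, c("A", "B"))
})

test_that("export_network writes one edge per pair with shared categories", {
  pred <- data.frame(tf1 = c("A", "B"), tf2 = c("X", "Y"))
  path <- tempfile(fileext = ".tsv")
  export_network(pred, path,
                 annotations = list(A = c("cycle", "meta"), X = "cycle",
                                    B = "meta"))
  lines <- readLines(path)
  expect_length(lines, 3L)
  expect_equal(lines[2L], "A\tX\tcycle")
  expect_equal(lines[3L], "B\tY\t")  # no shared category -> empty attribute

  export_network(pred[0L, ], path)
  expect_length(readLines(path), 1L)
})
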