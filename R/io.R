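## Data model: identifier policy, domain containers, and file I/O.
##
## All genomic intervals are 0-based half-open (BED convention) in files and
## in the data frames held in memory; conversion to the 1-based closed
## convention happens only at the GenomicRanges boundary inside
## `nucleosome_track()` and `occupancy_states()`.

#' Normalize a TF or gene identifier
#'
#' Identifiers are matched case-insensitively throughout the package; the
#' single normalization policy is: trim whitespace, then upper-case.
#'
#' @param x character vector of identifiers.
#' @return normalized character vector.
#' @export
norm_id <- function(x) toupper(trimws(as.character(x)))

#' Canonical form of an unordered identifier pair
#'
#' Returns the pair with members normalized and sorted so that
#' `canonical_pair(x, y)` and `canonical_pair(y, x)` are identical.
#' Vectorized over both arguments.
#'
#' @param x,y character vectors of identifiers.
#' @return a two-column character matrix with columns `tf1`, `tf2`
#'   (`tf1 <= tf2` lexicographically).
#' @export
canonical_pair <- function(x, y) {
  x <- norm_id(x)
  y <- norm_id(y)
  cbind(tf1 = pmin(x, y), tf2 = pmax(x, y))
}

## Key used for set operations on unordered pairs.
pair_key <- function(x, y) {
  cp <- canonical_pair(x, y)
  paste(cp[, 1L], cp[, 2L], sep = "\r")
}

## -- low-level TSV scanning with line-number diagnostics ---------------------

## Readers report malformed rows by their physical line number, which
## read.delim cannot do once blank/comment lines are skipped.
parse_tsv <- function(path, min_fields, what, header = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("%s: file not found: %s", what, path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(lines, "#"))
  if (header && length(keep)) keep <- keep[-1L]
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < min_fields)
  if (length(bad)) {
    stop(sprintf(
      "%s: line %d: expected at least %d tab-separated fields, found %d",
      what, keep[bad[1L]], min_fields, nf[bad[1L]]
    ), call. = FALSE)
  }
  list(fields = fields, line_no = keep)
}

tsv_column <- function(parsed, i) {
  vapply(parsed$fields, `[[`, character(1L), i)
}

check_nonempty <- function(x, parsed, what, column) {
  bad <- which(!nzchar(x))
  if (length(bad)) {
    stop(sprintf("%s: line %d: empty %s identifier",
                 what, parsed$line_no[bad[1L]], column), call. = FALSE)
  }
  invisible(x)
}

parse_number <- function(x, parsed, what, column) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out))
  if (length(bad)) {
    stop(sprintf("%s: line %d: %s is not a number: '%s'",
                 what, parsed$line_no[bad[1L]], column, x[bad[1L]]),
         call. = FALSE)
  }
  out
}

## -- RegulationTable ---------------------------------------------------------

#' Construct a documented-regulation table
#'
#' A `RegulationTable` is a deduplicated set of (TF, gene) pairs recording
#' literature-curated regulation evidence. Identifiers are normalized with
#' [norm_id()].
#'
#' @param tf,gene character vectors of equal length.
#' @return a `RegulationTable` data frame with columns `tf`, `gene` and
#'   attributes `n_read` (rows supplied) and `n_duplicates` (rows dropped).
#' @export
regulation_table <- function(tf = character(), gene = character()) {
  stopifnot(length(tf) == length(gene))
  tf <- norm_id(tf)
  gene <- norm_id(gene)
  if (any(!nzchar(tf)) || any(!nzchar(gene))) {
    stop("regulation table: identifiers must be non-empty", call. = FALSE)
  }
  key <- paste(tf, gene, sep = "\r")
  keep <- !duplicated(key)
  out <- data.frame(tf = tf[keep], gene = gene[keep],
                    stringsAsFactors = FALSE)
  attr(out, "n_read") <- length(tf)
  attr(out, "n_duplicates") <- sum(!keep)
  class(out) <- c("RegulationTable", "data.frame")
  out
}

#' Read a TF-gene documented-regulation table
#'
#' Expects a TSV with at least two columns: TF identifier and gene
#' identifier (YEASTRACT-style export). Duplicate pairs are dropped.
#'
#' @param path file path.
#' @param header logical; skip a header line.
#' @return a `RegulationTable`; see [regulation_table()].
#' @export
read_regulation <- function(path, header = FALSE) {
  p <- parse_tsv(path, 2L, "regulation table", header = header)
  tf <- check_nonempty(norm_id(tsv_column(p, 1L)), p, "regulation table", "TF")
  gene <- check_nonempty(norm_id(tsv_column(p, 2L)), p, "regulation table",
                         "gene")
  regulation_table(tf, gene)
}

#' @export
print.RegulationTable <- function(x, ...) {
  cat(sprintf("RegulationTable: %d TF-gene records (%d TFs, %d genes)\n",
              nrow(x), length(unique(x$tf)), length(unique(x$gene))))
  invisible(x)
}

## -- TFBS table --------------------------------------------------------------

#' Construct a table of TF binding sites
#'
#' Each record is a located binding site with a posterior probability and an
#' assigned gene (the gene whose promoter holds the site). Coordinates are
#' 0-based half-open.
#'
#' @param tf,chrom,gene character vectors.
#' @param start,end integer vectors, `0 <= start < end`.
#' @param strand character vector in `+`, `-`, `.`.
#' @param posterior numeric vector in `[0, 1]`.
#' @return a `TFBSTable` data frame with columns
#'   `tf`, `chrom`, `start`, `end`, `strand`, `posterior`, `gene`.
#' @export
tfbs_table <- function(tf = character(), chrom = character(),
                       start = integer(), end = integer(),
                       strand = rep(".", length(tf)),
                       posterior = numeric(), gene = character()) {
  n <- length(tf)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(strand) == 1L && n != 1L) strand <- rep(strand, n)
  if (length(posterior) == 1L && n != 1L) posterior <- rep(posterior, n)
  stopifnot(length(chrom) == n, length(start) == n, length(end) == n,
            length(strand) == n, length(posterior) == n, length(gene) == n)
  tf <- norm_id(tf)
  gene <- norm_id(gene)
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end)) || any(start < 0L) ||
      any(start >= end)) {
    stop("TFBS table: coordinates must satisfy 0 <= start < end",
         call. = FALSE)
  }
  if (any(is.na(posterior)) || any(posterior < 0) || any(posterior > 1)) {
    stop("TFBS table: posterior probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  if (any(!nzchar(gene)) || any(!nzchar(tf))) {
    stop("TFBS table: TF and gene identifiers must be non-empty",
         call. = FALSE)
  }
  if (any(!strand %in% c("+", "-", "."))) {
    stop("TFBS table: strand must be one of '+', '-', '.'", call. = FALSE)
  }
  out <- data.frame(tf = tf, chrom = as.character(chrom), start = start,
                    end = end, strand = strand, posterior = posterior,
                    gene = gene, stringsAsFactors = FALSE)
  class(out) <- c("TFBSTable", "data.frame")
  out
}

#' Read a TF binding-site table (BED6+1)
#'
#' Columns: chrom, start, end, name (= TF), score (= posterior probability),
#' strand, and a seventh column giving the assigned gene. Coordinates are
#' 0-based half-open per the BED convention.
#'
#' @inheritParams read_regulation
#' @return a `TFBSTable`; see [tfbs_table()].
#' @export
read_tfbs <- function(path, header = FALSE) {
  p <- parse_tsv(path, 7L, "TFBS table", header = header)
  chrom <- tsv_column(p, 1L)
  start <- parse_number(tsv_column(p, 2L), p, "TFBS table", "start")
  end <- parse_number(tsv_column(p, 3L), p, "TFBS table", "end")
  tf <- check_nonempty(norm_id(tsv_column(p, 4L)), p, "TFBS table", "TF")
  posterior <- parse_number(tsv_column(p, 5L), p, "TFBS table", "posterior")
  strand <- tsv_column(p, 6L)
  gene <- check_nonempty(norm_id(tsv_column(p, 7L)), p, "TFBS table", "gene")
  bad <- which(start >= end)
  if (length(bad)) {
    stop(sprintf("TFBS table: line %d: start (%d) must be < end (%d)",
                 p$line_no[bad[1L]], as.integer(start[bad[1L]]),
                 as.integer(end[bad[1L]])), call. = FALSE)
  }
  bad <- which(posterior < 0 | posterior > 1)
  if (length(bad)) {
    stop(sprintf("TFBS table: line %d: posterior %g outside [0, 1]",
                 p$line_no[bad[1L]], posterior[bad[1L]]), call. = FALSE)
  }
  tfbs_table(tf = tf, chrom = chrom, start = start, end = end,
             strand = strand, posterior = posterior, gene = gene)
}

## -- NucleosomeTrack ---------------------------------------------------------

#' Construct a nucleosome occupancy track
#'
#' Holds the genomic intervals occupied by nucleosomes, per chromosome, in
#' 0-based half-open coordinates. Queries on chromosomes absent from the
#' track report no overlap.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, `start < end`, 0-based half-open.
#' @return a `NucleosomeTrack` object.
#' @export
nucleosome_track <- function(chrom = character(), start = integer(),
                             end = integer()) {
  n <- length(chrom)
  stopifnot(length(start) == n, length(end) == n)
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end)) || any(start < 0L) ||
      any(start >= end)) {
    stop("nucleosome track: intervals must satisfy 0 <= start < end",
         call. = FALSE)
  }
  intervals <- data.frame(chrom = as.character(chrom), start = start,
                          end = end, stringsAsFactors = FALSE)
  o <- order(intervals$chrom, intervals$start, intervals$end)
  intervals <- intervals[o, , drop = FALSE]
  rownames(intervals) <- NULL
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end)
  )
  structure(list(intervals = intervals, granges = gr),
            class = "NucleosomeTrack")
}

#' Read a nucleosome occupancy track (BED3)
#'
#' @inheritParams read_regulation
#' @return a `NucleosomeTrack`; see [nucleosome_track()].
#' @export
read_nucleosome_track <- function(path, header = FALSE) {
  p <- parse_tsv(path, 3L, "nucleosome track", header = header)
  chrom <- tsv_column(p, 1L)
  start <- parse_number(tsv_column(p, 2L), p, "nucleosome track", "start")
  end <- parse_number(tsv_column(p, 3L), p, "nucleosome track", "end")
  bad <- which(start >= end)
  if (length(bad)) {
    stop(sprintf("nucleosome track: line %d: start must be < end",
                 p$line_no[bad[1L]]), call. = FALSE)
  }
  nucleosome_track(chrom, start, end)
}

#' @export
print.NucleosomeTrack <- function(x, ...) {
  cat(sprintf("NucleosomeTrack: %d occupied intervals on %d chromosome(s)\n",
              nrow(x$intervals), length(unique(x$intervals$chrom))))
  invisible(x)
}

## -- PPINetwork --------------------------------------------------------------

#' Construct a protein-protein interaction network
#'
#' Undirected edge set; `(x, y)` and `(y, x)` are the same edge. Self-loops
#' are kept as loaded, but [ppi_partners()] never reports a protein as its
#' own partner.
#'
#' @param a,b character vectors of protein identifiers.
#' @return a `PPINetwork` object.
#' @export
ppi_network <- function(a = character(), b = character()) {
  stopifnot(length(a) == length(b))
  cp <- canonical_pair(a, b)
  keep <- !duplicated(paste(cp[, 1L], cp[, 2L], sep = "\r"))
  edges <- data.frame(a = cp[keep, 1L], b = cp[keep, 2L],
                      stringsAsFactors = FALSE)
  structure(list(edges = edges), class = "PPINetwork")
}

#' Read a PPI edge list (two-column TSV)
#'
#' @inheritParams read_regulation
#' @return a `PPINetwork`; see [ppi_network()].
#' @export
read_ppi <- function(path, header = FALSE) {
  p <- parse_tsv(path, 2L, "PPI edge list", header = header)
  a <- check_nonempty(norm_id(tsv_column(p, 1L)), p, "PPI edge list",
                      "protein")
  b <- check_nonempty(norm_id(tsv_column(p, 2L)), p, "PPI edge list",
                      "protein")
  ppi_network(a, b)
}

#' Interaction partners of a protein
#'
#' @param ppi a `PPINetwork`.
#' @param id protein identifier (normalized internally).
#' @return character vector of partners; empty if the protein is absent.
#'   The protein itself is never included (self-loops are ignored here).
#' @export
ppi_partners <- function(ppi, id) {
  stopifnot(inherits(ppi, "PPINetwork"))
  id <- norm_id(id)
  e <- ppi$edges
  partners <- c(e$b[e$a == id], e$a[e$b == id])
  sort(unique(partners[partners != id]))
}

#' @export
print.PPINetwork <- function(x, ...) {
  cat(sprintf("PPINetwork: %d undirected edges, %d proteins\n",
              nrow(x$edges), length(unique(c(x$edges$a, x$edges$b)))))
  invisible(x)
}

## -- BenchmarkSet ------------------------------------------------------------

#' Construct a benchmark set of known cooperative TF pairs
#'
#' Unordered, deduplicated pairs; self-pairs are dropped with a warning.
#'
#' @param tf1,tf2 character vectors of TF identifiers.
#' @param complex_ids,complex_names optional per-pair annotation strings
#'   (several values joined with `";"`), e.g. protein-complex catalog IDs.
#' @return a `BenchmarkSet` data frame with columns `tf1`, `tf2`,
#'   `complex_ids`, `complex_names`.
#' @export
benchmark_set <- function(tf1, tf2, complex_ids = NA_character_,
                          complex_names = NA_character_) {
  stopifnot(length(tf1) == length(tf2))
  cp <- canonical_pair(tf1, tf2)
  df <- data.frame(tf1 = cp[, 1L], tf2 = cp[, 2L],
                   complex_ids = rep_len(as.character(complex_ids),
                                         nrow(cp)),
                   complex_names = rep_len(as.character(complex_names),
                                           nrow(cp)),
                   stringsAsFactors = FALSE)
  self <- df$tf1 == df$tf2
  if (any(self)) {
    warning(sprintf("benchmark set: dropping %d self-pair(s)", sum(self)),
            call. = FALSE)
    df <- df[!self, , drop = FALSE]
  }
  df <- df[!duplicated(paste(df$tf1, df$tf2, sep = "\r")), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("BenchmarkSet", "data.frame")
  df
}

#' Read a TF-pair list (two-column TSV) as a benchmark set
#'
#' @inheritParams read_regulation
#' @return a `BenchmarkSet`; see [benchmark_set()].
#' @export
read_pairs <- function(path, header = FALSE) {
  p <- parse_tsv(path, 2L, "pair list", header = header)
  tf1 <- check_nonempty(norm_id(tsv_column(p, 1L)), p, "pair list", "TF")
  tf2 <- check_nonempty(norm_id(tsv_column(p, 2L)), p, "pair list", "TF")
  benchmark_set(tf1, tf2)
}

## -- packaged fixtures -------------------------------------------------------

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "tfcoop")
  if (!nzchar(path)) {
    stop(sprintf("packaged fixture not found: %s", file), call. = FALSE)
  }
  path
}

#' Load the packaged 27-pair prediction annotation table
#'
#' The packaged fixture annotates 27 predicted cooperative TF pairs, ranked
#' by cooperativity score, with three lines of supporting evidence:
#' citations of other prediction methods, the existence of a physical PPI
#' between the two TFs, and shared functional-catalog (MIPS) categories.
#' Cells recorded as `--` in the source are encoded as empty/unknown, not as
#' negative evidence.
#'
#' @return a data frame with 27 rows and columns `rank`, `tf1`, `tf2`,
#'   `method_citations` (list of character vectors), `has_ppi`
#'   (`"yes"`/`"unknown"`), `mips_categories` (list of character vectors).
#' @export
load_table1_fixture <- function() {
  path <- fixture_path("predicted_pairs_annotation.tsv")
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                   colClasses = "character")
  need <- c("rank", "tf1", "tf2", "method_citations", "has_ppi",
            "mips_categories")
  if (!all(need %in% names(df))) {
    stop("prediction annotation fixture is corrupt: missing columns",
         call. = FALSE)
  }
  out <- data.frame(rank = as.integer(df$rank),
                    tf1 = norm_id(df$tf1), tf2 = norm_id(df$tf2),
                    stringsAsFactors = FALSE)
  split_list <- function(x, sep) {
    lapply(x, function(s) {
      if (!nzchar(s)) character() else trimws(strsplit(s, sep,
                                                       fixed = TRUE)[[1L]])
    })
  }
  out$method_citations <- split_list(df$method_citations, ",")
  out$has_ppi <- ifelse(df$has_ppi == "yes", "yes", "unknown")
  out$mips_categories <- split_list(df$mips_categories, ";")
  if (nrow(out) != 27L || !identical(sort(out$rank), 1:27)) {
    stop("prediction annotation fixture is corrupt: expected 27 rows with ranks 1..27",
         call. = FALSE)
  }
  out[order(out$rank), , drop = FALSE]
}

#' Load the packaged 27-pair benchmark set
#'
#' Known cooperative TF pairs compiled from a curated catalog of yeast
#' transcription complexes, used by [index3()] and [precision_recall()].
#'
#' @return a `BenchmarkSet` with 27 unordered pairs; see [benchmark_set()].
#' @export
load_benchmark_fixture <- function() {
  path <- fixture_path("benchmark_pairs.tsv")
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("tf1", "tf2", "complex_ids", "complex_names")
  if (!all(need %in% names(df))) {
    stop("benchmark fixture is corrupt: missing columns", call. = FALSE)
  }
  bm <- benchmark_set(df$tf1, df$tf2, df$complex_ids, df$complex_names)
  if (nrow(bm) != 27L) {
    stop("benchmark fixture is corrupt: expected 27 unordered pairs",
         call. = FALSE)
  }
  bm
}

## -- PairResult I/O ----------------------------------------------------------

pair_result_columns <- c("tf1", "tf2", "n1", "n2", "m", "p_overlap",
                         "a", "b", "c", "d", "p_nu", "score")

#' Write per-pair cooperativity results to TSV
#'
#' Columns: `tf1, tf2, n1, n2, m, p_overlap, a, b, c, d, p_nu, score`,
#' followed by `log10_p_overlap` and `log10_p_nu` so that p-values below
#' double-precision underflow still round-trip exactly. Numeric values are
#' written with 17 significant digits (lossless for doubles).
#'
#' @param results a `PairResultTable` as returned by [score_all_pairs()].
#' @param path output file path.
#' @export
write_pair_results <- function(results, path) {
  stopifnot(is.data.frame(results),
            all(pair_result_columns %in% names(results)))
  cols <- c(pair_result_columns, "log10_p_overlap", "log10_p_nu")
  out <- results[, cols, drop = FALSE]
  num <- vapply(out, is.double, logical(1L))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(out)) {
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  }
  invisible(path)
}

#' Read per-pair cooperativity results written by [write_pair_results()]
#'
#' @param path file path.
#' @return a `PairResultTable` data frame.
#' @export
read_pair_results <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(pair_result_columns %in% names(df))) {
    stop("pair results file: missing required columns", call. = FALSE)
  }
  int_cols <- c("n1", "n2", "m", "a", "b", "c", "d")
  dbl_cols <- setdiff(names(df), c("tf1", "tf2", int_cols))
  df[int_cols] <- lapply(df[int_cols], as.integer)
  df[dbl_cols] <- lapply(df[dbl_cols], as.numeric)
  if (!("log10_p_overlap" %in% names(df))) {
    df$log10_p_overlap <- log10(df$p_overlap)
    df$log10_p_nu <- log10(df$p_nu)
  }
  class(df) <- c("PairResultTable", "data.frame")
  df
}

#' @export
print.PairResultTable <- function(x, n = 6L, ...) {
  cat(sprintf("PairResultTable: %d TF pairs (top score %.3g)\n",
              nrow(x), if (nrow(x)) max(x$score) else NA_real_))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), n))
  invisible(x)
}
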