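---
title: "tfcoop: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tfcoop: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfcoop)
```

## The model

`tfcoop` ranks unordered transcription-factor (TF) pairs by combining two
independent pieces of statistical evidence for cooperativity.

**Step 1 — target sets.** A gene is a target of a TF if it is documented as
regulated by that TF *or* its promoter carries a binding site of that TF
that passes the posterior filter. The two evidence sources are unioned;
neither overrides the other. When a TF has several passing sites assigned
to one gene, only the most confident (highest posterior) site represents
that (TF, gene) relationship downstream.

**Step 2 — overlap significance.** For a pair with target-set sizes $N_1$,
$N_2$, $m$ common targets and a gene universe of size $N$,

$$P_{\mathrm{overlap}} \;=\; \sum_{i=m}^{\min(N_1,N_2)}
\frac{\binom{N_1}{i}\binom{N-N_1}{N_2-i}}{\binom{N}{N_2}},$$

the upper hypergeometric tail: the chance of sharing at least $m$ targets
if the second TF's targets were drawn at random.

**Step 3 — co-depletion significance.** Set $A$ is the subset of common
targets whose promoters carry a best site of *both* TFs. Each gene in $A$
contributes one cell to a 2×2 table according to the nucleosome occupancy
states of the two sites (a site is *occupied* if any of its bases overlaps
an occupied interval; *depleted* otherwise): $a$ = both depleted, $b$ and
$c$ = exactly one occupied, $d$ = both occupied. The one-sided Fisher exact
tail

$$P_{\mathrm{nu}} \;=\; \sum_{i=a}^{\min(a+b,\,a+c)}
\frac{\binom{a+b}{i}\binom{c+d}{a+c-i}}{\binom{a+b+c+d}{a+c}}$$

measures enrichment of simultaneous depletion. It is deliberately
one-sided: co-*occupancy* is not evidence of cooperativity under the
model's accessibility rationale, so the lower tail is never scored.

**Step 4 — score.** The cooperativity score is
$-\log_{10} P_{\mathrm{overlap}} - \log_{10} P_{\mathrm{nu}} \ge 0$. All
pairs are ranked by score, and pairs strictly above a threshold are
reported as predicted cooperative pairs.

Assumptions worth keeping in mind: target evidence is taken at face value
(no weighting by evidence quality); the gene universe is exchangeable under
the null (every gene equally likely a target); occupancy is a static binary
state, ignoring cell-to-cell and condition variability; and the two
p-values are treated as independent when summed in log space, which is
optimistic when binding sites cluster.

## Parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `posterior_threshold` | 0.3 | probability | minimum site confidence; inclusive (`>=`), since the data source's posterior is a site-level probability and the cut is a quality floor, not a strict order statistic |
| `total_genes` (overlap test) | 6576 | genes | yeast genome size used by the overlap null; configurable for other universes (synthetic runs pass their own `n_genes`) |
| `total_genes` (PPI index) | 6575 | proteins | the PPI-partner index conventionally uses its own universe figure; both are configuration values, not inferred from data |
| `score_threshold` | 120 | $-\log_{10}$ units | genome-scale operating point; comparison is strict (`>`) |
| `disable_nucleosome` | `FALSE` | — | ablation switch forcing $P_{\mathrm{nu}} = 1$, reducing the score to the overlap term |

The threshold of 120 is meaningful only at genome scale (thousands of
genes, hundreds of targets per TF); on the 600-gene synthetic world,
planted pairs score ~20, so CLI examples pass lower thresholds explicitly.

## Numerical choices

* **Log space throughout.** Both tails are computed as
  log-sum-exp over `lchoose` terms. P-values are never clamped to zero: a
  pair with $P_{\mathrm{overlap}} = 10^{-300}$ and one with $10^{-500}$
  remain distinguishable, and the results writer emits the `log10` columns
  alongside the probabilities so files round-trip exactly.
* **Base 10.** All $-\log P$ quantities use base 10, so a score difference
  of 1 is a tenfold p-value ratio.
* **Degenerate tables.** An empty set $A$, or any configuration whose tail
  spans the whole support (in particular $a = 0$), yields
  $P_{\mathrm{nu}} = 1$: absence of occupancy data contributes nothing to
  the score rather than manufacturing significance. Likewise pairs with
  $m = 0$ are kept with $P_{\mathrm{overlap}} = 1$, so the ranked list
  always has exactly $k(k-1)/2$ rows.
* **Tie-breaks.** Equal-posterior best sites are resolved by smallest start
  coordinate, then chromosome name; equal scores rank by canonical pair
  name. Both make the output invariant under input row permutation (tested
  by property).
* **Coordinates.** All intervals are 0-based half-open (BED). An occupied
  interval ending exactly where a site starts does not overlap it.
  Conversion to 1-based closed happens only at the GenomicRanges boundary.
* **Identifiers.** Matched case-insensitively, stored upper-case — the
  data sources mix `Swi6`, `SWI6` and `SWI6-MBP1` styles.

## Design decisions that were genuinely open

* **Site→gene assignment is an input.** Binding-site tables arrive with a
  gene column (the upstream database's own promoter assignment); the
  pipeline trusts it rather than recomputing membership from a promoter
  window, because no window definition is canonical. A window-based helper
  (`assign_genes_by_window()`) exists for inputs lacking the column.
* **TF universe = union.** The TF set is the union of TFs seen in the
  regulation and binding-site sources; a TF supported by a single source
  still participates.
* **Filtering precedes best-site selection**, so a sub-threshold site can
  never be selected as a gene's representative site.
* **Benchmark restriction.** Benchmark pairs containing TFs outside the
  prediction universe are dropped (with a message) from the enrichment test
  and the recall denominator: a method cannot be penalized for pairs it
  could never emit. The drop count is reported.
* **Annotation semantics.** In the packaged 27-pair annotation table,
  `--` cells are encoded as *unknown*, not as negative evidence; "novel"
  means "no method citation", and evidence lines are counted as
  citations / PPI-yes / non-empty category list.

## The synthetic world

`synthetic_config()` states a small regulatory world used by the tests and
the acceptance criteria: 600 genes with disjoint 1 kb promoters on one
synthetic chromosome; 20 TFs, each owning a fixed 10 bp slot per promoter;
a 5% background target rate (≈30 targets per TF, matching the order of
magnitude of curated yeast regulons relative to genome size); 3 planted
pairs built from disjoint TFs sharing 60% of their targets; 70% background
nucleosome occupancy per site (yeast promoters are mostly wrapped); and 80%
co-depletion at planted pairs' shared targets. Posteriors are uniform on
[0.3, 1], so every emitted site passes the default filter; a `tfbs_dropout`
switch withholds sites for a fraction of targets to exercise the
documented-regulation-only path.

Occupancy is sampled **per site** and then materialized as intervals that
exactly cover the occupied sites. This makes the contingency cells directly
controllable and keeps sites of different TFs from shadowing each other
(slots are disjoint), at the cost of realism: there is no nucleosome
spacing, no linker statistics, no sequence. Setting
`planted_shared_fraction = 0` removes all planted signal while preserving
each TF's marginal target rate — under that null, conditional on the two
set sizes, the shared-target count is exactly hypergeometric, which is what
the type-I-calibration criterion checks.

A green test on this world establishes that the statistics and the
plumbing are correct and that a strong planted signal is recovered; it does
*not* establish genome-scale performance on real regulation, binding-site
and occupancy snapshots, whose sizes, biases and correlation structure the
generator does not emulate. Genome-scale figures (the 120 threshold, 27
predicted pairs, benchmark indices of the original setting) require the
real data snapshots and are out of scope for the test suite.

## Evaluation indices

* **Index 1** (`index1`): per pair, the significance of the overlap of the
  two TFs' PPI partner sets, using the same hypergeometric tail over a
  protein universe (default 6575); the index is the mean of $-\log_{10} P$
  over the prediction list. TFs absent from the network score 0.
* **Index 3** (`index3`): enrichment of the prediction list against a
  benchmark pair set over the universe of candidate pairs (default 17205),
  one-sided Fisher tail, reported as $-\log_{10} P$.
* **Precision / recall** (`precision_recall`): unordered-pair matching.
* **Index 2** is a functional-similarity measure whose definition lives
  outside this package; `functional_similarity_hook()` ships only the
  plumbing (mean of a caller-supplied pair score), plus a constant provider
  for testing.

## Known limitations

* No multiple-testing correction is applied to the 17205 pair tests; the
  score threshold plays that role implicitly.
* The two score terms are summed as if independent; promoters with many
  sites violate this mildly.
* The co-depletion test conditions on set $A$, which itself depends on the
  posterior filter; very aggressive filtering shrinks $A$ and silently
  weakens the nucleosome term (the sweep subcommand exists to make that
  visible).
* The benchmark set is small (27 pairs) and complex-derived, so recall is
  coarse-grained.
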