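---
title: "Core-genome alignment by partitioned MUM anchoring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core-genome alignment by partitioned MUM anchoring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette describes the model and the algorithmic and numerical choices
behind `corealn`, in the spirit of a methods section: what is computed, under
which assumptions, which knobs matter, and what the bundled validation does
and does not demonstrate.

# The alignment model

## Anchoring on maximal unique matches

A *MUM* over a genome set is an exact match that (a) occurs in every genome,
(b) occurs exactly once in each genome **counting both strands**, and (c) is
not extensible left or right in all genomes simultaneously. Double-strand
uniqueness is deliberate: a match with an inverted duplicate elsewhere in a
genome is ambiguous as an anchor, so it is rejected. A consequence worth
knowing: a short match that happens to reappear reverse-complemented
(including revcomp palindromes overlapping themselves) is not an anchor even
if it is unique on the forward strand.

`find_mums()` builds one generalized suffix array (SA-IS, linear time) over
the forward and reverse-complement strands of all genomes. Contig
separators, and every `N`, are encoded as a sentinel byte; the LCP array is
computed with sentinel-aware equality so matches can never span a contig
boundary or an ambiguous base. MUMs are exactly the windows of *G*
consecutive suffixes (one per genome) whose interior LCP minimum *m*
satisfies `m >= min_length`, exceeds the LCP to both neighbouring suffixes
(uniqueness), and whose preceding characters are not all the same base
(left-maximality). The scan is linear with a monotone deque for the window
minimum. The reference is never flipped: anchors are reported on the
reference forward strand, query strands relative to it.

The default `min_length` is 15 bp with a two-level recursive schedule
(15, then ⌈15·0.6⌉ = 9) — exposed on the CLI because no single threshold
suits every divergence; 15 bp keeps random 500 kbp–5 Mbp genomes from
producing chance anchors, while the 9 bp recursion level recovers anchors
inside variable regions where full-length anchors have been destroyed.

## Collinearity filtering and chaining

Spurious anchors (repeat-induced, or unique matches at non-homologous loci)
are removed per query genome by repeatedly extracting the heaviest strictly
monotone run (weighted by anchor length; increasing positions for `+`
anchors, decreasing for `-`) until the best remaining run is lighter than
`min_run` (default 3× `min_length`). A mislocated anchor that interrupts a
long collinear run ends up in its own sub-threshold run and is dropped;
genuine inverted or translocated blocks survive as heavy runs. Anchors are
then chained greedily in reference order, breaking at strand flips, order
inversions, per-genome gaps above `max_gap` (default 1 kbp) and contig
boundaries; chains lighter than `min_chain` (= `min_run`) are discarded, and
chains are split wherever any genome's gap exceeds a hard cap (10 kbp).

## Reference-anchored columns

The defining property of the combined alignment is that columns represent an
equivalence relation between reference and query positions. `corealn` takes
this as the *construction principle*, not only as a merging convenience:
for every query, one global map "query base → reference position (or
insertion)" is computed up front from the pairwise (reference, query) MUM
chain whose inter-anchor gaps are closed by global Needleman–Wunsch
(match +2, mismatch −4, gap −4; gaps larger than 5 kbp or 2.5·10⁷ DP cells
are left unaligned). Multi-genome anchors and chains then determine only
*which* reference windows are core and each genome's orientation there; the
column content of every LCB row is read off the per-query map. Query bases
the map leaves unassigned become insertion blocks attached to the preceding
reference position, and insertions attached to the same position are merged
across queries by partial-order alignment in roster order.

This design has a property we consider essential for the partitioned mode:
a query's base-to-reference assignment is **identical in every run that
contains the query**, whatever the cohort. Partitioned and nonpartitioned
runs therefore call exactly the same SNP columns wherever both consider a
position core, and stitching partition alignments reduces to concatenating
rows per reference position plus re-merging insertions. The price is that a
multi-genome anchor column is not *forced* to be gapless: in rare
repeat-ambiguous spots the pairwise map may disagree with a cohort anchor,
and the map wins. We accept occasional gap columns inside anchor regions in
exchange for cohort-independent, reproducible columns.

## Partitioning, intersection, trimming, stitching

With *n* queries and partition size *p*, queries are assigned contiguously
in input order to *q* = ⌈*n*/*p*⌉ groups whose sizes differ by at most one
(balanced remainders; a randomized assignment would add nondeterminism for
no measurable benefit). Every group is aligned with the shared reference.
The per-partition reference interval sets are intersected exactly
(`IRanges` under the hood); because interval normalization merges touching
pieces, the intersection is re-split at every source-interval boundary so
that each final core interval lies inside a single LCB of every partition —
the precondition for trimming. Trimming keeps the columns whose *attachment
position* (own position for match columns, preceding reference position for
insertion columns) falls inside the interval; insertions attached at the
interval's left boundary are thereby excluded, which makes trim-then-stitch
associative and unambiguous. With `p = n` the pipeline short-circuits to the
single-cohort run, so nonpartitioned output is exactly the classic
pipeline's.

Partition jobs share nothing; results are byte-identical for any processing
order or worker count. Anti-monotonicity of core size in *p* is *not*
assumed — partitioning can grow or shrink the core depending on breakpoint
structure — it is only measured.

# Statistics and trees

* **SNPs**: one record per column with a non-gap reference base where at
  least one query carries a different base; query gaps and Ns are recorded
  as missing, never as alleles.
* **Weighted reference divergence**: per LCB, ANI to the reference is the
  mean over queries of matches over columns where both have a base (Ns
  excluded from numerator and denominator); LCB weight is its total non-gap
  nucleotide count ("nucleotides", not columns — a column-weighted variant
  is available via `weight_by`); the statistic is 100·(1 − Σw·ANI/Σw).
* **Average core length**: mean over genomes of non-gap characters summed
  over LCBs.
* **Large-indel filter**: LCBs containing a gap run strictly longer than
  300 bp in any row can be removed (`filter_large_indel_lcbs`), reflecting
  that long indels are not core sequence.
* **Trees**: pairwise distances are mismatch proportions over columns where
  both genomes have a base, fed to neighbour joining (`ape::nj`, negative
  branch lengths clamped to 0). At the divergences the validation targets
  (≤ ~6%), uncorrected p-distances are effectively additive and NJ is a
  sound, fast stand-in for likelihood methods.
* **Tree comparison**: normalized RF = |B₁ Δ B₂| / (|B₁| + |B₂|) over
  non-trivial bipartitions, polytomies taken as-is. The weighted variant
  sums |w₁(b) − w₂(b)| over all bipartitions (absent → 0) normalized by
  total internal branch length of both trees; this reading is isolated in
  one function (`normalized_weighted_rf`) so an alternative normalization
  is a one-line swap.

# The synthetic evolver

`evolve()` emulates genome evolution along a random coalescent tree whose
branch lengths are rescaled so the mean root-to-tip path equals the target
divergence (expected substitutions/site). Per branch:

* substitutions follow Jukes–Cantor with per-site gamma rate variability
  (shape 1 by default), heritable via root coordinates;
* small indels at a rate of 0.05 events per substitution (a realistic
  indel-to-SNP ratio for bacteria), geometric lengths with mean 3 bp,
  insertions and deletions equally likely;
* genome-level events at expected counts per root-to-tip lineage:
  inversions 0.3, translocations 0.2, segment losses 0.3, HGT-like novel
  insertions 0.3, geometric segment lengths with mean 500 bp. Duplications
  are folded into HGT-like insertion: inserted material is novel, hence
  non-core by construction — the simulator is nucleotide-level and does not
  model gene structure.

Every base carries a signed root coordinate, so the true core (root
positions surviving in *all* leaves, expressed in reference coordinates) is
exact, as is the realized species tree. Default root length is 500 kbp —
large enough that coalescent-scale internal branches carry several SNPs at
1% divergence, small enough for desk-scale runs; the bundled validation
uses 60 genomes at this size (and 12 for the consistency checks), chosen as
the largest sizes that keep the full suite in the minutes range.

What the simulator does *not* emulate: assembly artifacts and sequencing
error, gene-scale selection, recombination, compositional bias, and real
repeat structure. Passing the validation shows the method recovers
phylogeny and core coordinates under clean rearrangement/indel noise; it
does not certify behaviour on fragmented or contaminated assemblies.

# Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; XMFA and VCF emit 1-based
  inclusive at the I/O boundary only.
* POA uses linear gap penalties (affine is a config hook that errors
  clearly); sequences are added in roster order, making the (order
  dependent) POA deterministic. Consensus is the heaviest-support path,
  ties to smaller node ids.
* Ties in chaining and in the weighted monotone-subsequence selection are
  broken towards the leftmost/reference-earlier element; all pipelines are
  RNG-free, so identical inputs give byte-identical outputs.
* Degenerate inputs: empty alignments print/round-trip as comment-only
  XMFA; an empty interval intersection yields an empty core with a warning
  (exit 1 from the CLI); genomes absent over a window get all-gap rows with
  empty coordinate spans; divergence is undefined (error) on an empty
  alignment while core length is 0.

# Known limitations

* Uniqueness is genome-wide: a single extra (inverted) copy of a conserved
  region suppresses anchors there; the recursive level partially recovers
  such regions but heavily repetitive genomes will yield fragmented cores.
* The pairwise maps tie each query to one best placement; paralogy that
  pairwise chaining resolves differently from the cohort view results in
  missing (gap) rows rather than misplaced bases — conservative, but it can
  understate core size in repeat-rich genomes.
* Insertion merging is per reference position; a long insertion shared by
  queries in different partitions is re-aligned by POA at stitch time,
  which is heuristic (order-dependent) alignment, not a joint optimum.
* `N`-rich assemblies break chains at every ambiguity run, shortening LCBs.
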