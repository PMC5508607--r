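---
title: "Classifying differences between two closely related sequence sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying differences between two closely related sequence sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alndiff)
```

## The problem

When an assembly is compared to a finished genome, or two strains of one
species to each other, the interesting output is not the alignment
itself but a complete, typed inventory of how the two sequence sets
differ: which bases were inserted, deleted or substituted, which events
are copies or collapses of repeats, where large blocks moved, flipped or
changed order, and which parts of the query never aligned at all.
`alndiff` produces that inventory.  Every difference is classified into
one leaf of a fixed taxonomy and reported with coordinates in *both*
systems — on the query and on the reference — so the results can be
loaded into a genome browser over either sequence set or consumed by a
downstream pipeline.

The taxonomy has three levels:

* **global** — `unaligned_sequence`: a query sequence with no retained
  match of at least `min_cluster_len` bases (65 by default);
* **local** — insertions (`simple_insertion`, `duplication`,
  `tandem_duplication`, `inserted_gap`, `unaligned_beginning`,
  `unaligned_end`), deletions (`simple_deletion`, `collapsed_repeat`,
  `collapsed_tandem_repeat`) and substitutions (`substitution`, `gap`);
* **structural** — `translocation` and `relocation` (each with five
  placement subtypes: simple, with insertion, with inserted gap, with
  both, with overlap), `reshuffling` and `inversion`.

One annotation, `circular_genome_start`, is reported but never counted:
it marks the rotated start of a circular genome, which fragments the
alignment without being a biological difference.

## The model: differences from fragment placement

The engine consumes *aligned fragments* — matched query-region /
reference-region pairs with a direction and per-base records of the
substituted, inserted and deleted bases inside them.  Fragments come
either from the built-in anchor aligner (below) or from MUMmer-family
tabular files (`parse_coords()`, `parse_snps()`).

An aligner breaks its alignment wherever a local difference is longer
than its extension distance, and at every structural rearrangement.  The
classification therefore proceeds in four stages, each consuming part of
the fragmentation:

1. **Global.**  Query sequences absent from the retained fragments are
   `unaligned_sequence`.
2. **Within fragments.**  Adjacent per-base records of one kind coalesce
   into runs: a run of inserted bases is one `simple_insertion`, a run
   of substituted bases one `substitution`, and any run whose query side
   is entirely N becomes the corresponding gap type (`gap` when it
   replaces reference bases one-for-one, `inserted_gap` when it adds
   length).  These differences are bounded by the extension distance.
3. **Between fragments (local).**  Nested fragments — whose query or
   reference span lies inside another fragment's span — are discarded
   first; they encode duplications and collapsed repeats whose identity
   resurfaces later as plain insertions/deletions.  Unaligned query ends
   become `unaligned_beginning`/`unaligned_end`.  Then every pair of
   neighbouring query fragments is tested against the merge criteria:
   same reference sequence, same direction (possibly jointly opposite to
   the reference), reference fragments in the order consistent with that
   direction, reference gap at most `max_merge_distance`, and the
   separating region unmapped elsewhere in the same query.  A mergeable
   pair is classified from the *signs of its two gaps* — query gap and
   orientation-consistent reference gap:

   | query gap | ref gap | classification |
   |---|---|---|
   | + | 0 | insertion family (by N content) |
   | 0 | + | `simple_deletion` |
   | 0 | − | `tandem_duplication` (extra adjacent copy) |
   | + | − | `duplication` + insertion family |
   | − | 0 | `collapsed_tandem_repeat` |
   | − | + | `collapsed_repeat` (one copy + spacer lost) |
   | + | + | `substitution`/`gap` when equal; otherwise deletion + insertion family, with all-N query content combining `gap` with `inserted_gap` (enlarged gap) or `simple_deletion` (shortened gap) |
   | − | − | trim the smaller overlap from the right fragment, re-evaluate |

   The pair is then merged into one continuous fragment and the scan
   repeats (leftmost pair first), so chains of local events collapse
   deterministically.  Every emitted length equals its owning span, so
   for each merged fragment the reference-minus-query span difference
   equals the signed sum of its indel lengths — a checkable conservation
   law (`check_conservation()`).
4. **Structural.**  Each surviving neighbour pair is routed to exactly
   one category: different reference sequences → `translocation`; the
   two-fragment suffix/prefix swap of a rotated circular genome →
   `circular_genome_start`; groups of query-consecutive fragments whose
   nearby reference regions (pairwise gaps ≤ `structural_distance`)
   appear out of order → `reshuffling` (the out-of-place members are the
   reshuffled ones, and after overlap truncation the unmapped query and
   reference bases between members are reported as insertions and
   deletions); same-reference pairs separated by at least
   `structural_distance` → `relocation`; everything else (for instance
   an inversion junction) continues the same mapped block.  Subtypes
   follow the junction content on the query: nothing, known bases,
   N runs, both, or a partial overlap of the query fragments.
   Reference-side overlaps between fragments are truncated (the
   fragment later in query order is trimmed) before subtype detection,
   deliberately losing the repeat identity of such inserts.  Finally any
   fragment whose direction opposes the reference is an `inversion` —
   unless *all* fragments of that query are reversed, which is simply a
   reverse-complemented sequence.  The surviving fragments, with
   query-side overlaps trimmed, are the *mapped blocks*: the maximal
   query regions alignable without structural interruption.

## The built-in aligner

The aligner emulates the classical anchor pipeline so that the full tool
runs and is tested without external binaries:

* **Anchors** are maximal exact matches of at least `min_match_len`
  (default 20) bases, found by joining the k-mer tables of the two sets
  and run-length-encoding same-diagonal hits — a maximal match of
  length L contains exactly L−k+1 consecutive diagonal k-mer hits, so
  this recovers maximal matches exactly.  N matches only N.
* **Chaining** joins co-linear anchors whose separation on both
  coordinates is at most `extension_distance` (default 200); junction
  overlaps shorter than the seed length (accidental homology at event
  borders) are trimmed, while larger overlaps — repeat-induced — start
  new fragments.  Gaps between chained anchors are filled by a
  unit-cost alignment whose ties prefer substitutions over indels and
  place indels leftmost; equal-length gaps are compared positionwise.
  Local differences longer than the extension distance break the chain,
  which is what routes them to the between-fragment classifier.
* **Lone-anchor suppression.**  Single-anchor fragments shorter than
  `min_cluster_len` (default 65) are dropped as chance matches, which is
  also what makes short query sequences report as wholly unaligned.
* **Per-query consistent-chain filtering** keeps, per query sequence,
  the fragment chain maximizing the sum of length × identity over
  fragments whose query intervals advance strictly.  Partial overlaps up
  to half the shorter fragment are allowed: a strict non-overlap rule
  would delete one side of every overlap-mediated structural junction
  and make the `with_overlap` subtypes undetectable.  Reference-side
  placement is deliberately unconstrained so rearranged fragments
  survive.  A consequence, shared with the tool chain this emulates, is
  that a duplicated region inserted far from its source loses the
  alternative placement (to nested-fragment filtering or to the chain
  weight) and is reported as a `simple_insertion` — a documented,
  accepted limitation, and the reason `evaluate_recovery()`'s grouped
  matching treats all insertion-like types as compatible.

## Tunable parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `min_match_len` | 20 | bp | anchor seed length |
| `min_cluster_len` | 65 | bp | minimum lone match retained; shorter query sequences report unaligned |
| `extension_distance` | 200 | bp | longest local difference absorbed inside one fragment |
| `min_identity` | 0 | % | fragments below are dropped at ingestion (after chain filtering) |
| `max_merge_distance` | 10000 | bp | largest reference gap explained as a local difference |
| `structural_distance` | 10000 | bp | reference distance at/beyond which a pair is a relocation; grouping radius for reshuffling |
| `circular` | TRUE | — | recognize rotated circular starts |

The two 10 kb distances meet exactly: a reference gap of 10,000 still
merges (a deletion), 10,001 becomes a relocation.

## The simulator and what passing tests mean

`simulate_genome_pair()` reproduces the evaluation design the classifier
is meant for: random genomes (default 100 kb, GC 0.5) carrying
controlled modifications of every taxonomy type, with a machine-readable
truth ledger giving each expected difference in final query coordinates.
Repeat-dependent kinds (collapsed repeats, overlap-mediated junctions)
first plant the needed repeat into the reference.  Default event lengths
are 300–2000 bp — long enough to fragment the alignment — with larger
blocks for inversions (1–5 kb), reshuffled segments (2–8 kb each) and
relocated/translocated regions (tens of kb, beyond the structural
distance); events are separated by at least 5 kb (relaxed once to 2 kb
when a crowded plan cannot be placed).

Two design choices matter when interpreting recovery numbers:

* **Boundary guards.**  Junction-flanking residues are resampled (or
  positions rejected) so that no planted breakpoint carries accidental
  one-base homology with its surroundings.  Without guards, maximal
  exact extension shifts about a quarter of breakpoints by a few bases,
  which exact-mode evaluation counts as wrong despite the correct type.
  The guards make the planted coordinates unambiguous; real genomes, of
  course, are not guarded, so exact-mode recovery on real data will be
  slightly lower for this benign reason.
* **What is not emulated.**  The generator plants isolated, clean
  events into otherwise random (repeat-free) sequence.  Real genomes
  have genuine repeat families, compound and overlapping events, and
  sequencing/assembly noise; passing the simulation suite demonstrates
  the classification logic and coordinate bookkeeping, not robustness
  to every repeat structure.  The documented limitations are inherited
  deliberately: distant duplications surface as simple insertions, and
  simple relocations/translocations followed by duplications cannot
  both be detected at once.

`evaluate_recovery()` scores detection against the ledger in two modes:
`exact` requires identical type (and subtype) and identical spans in
both coordinate systems — a detection shifted by one base is wrong —
while `overlap` requires only a compatible coarse group (all
insertion-like types are interchangeable, likewise deletion-like and
substitution-like) and at least one base of positional overlap.

## Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open everywhere; MUMmer dialects
  and GFF3 (1-based inclusive) are converted only at the I/O boundary.
  Zero-length breakpoint spans are written as one-base anchors flagged
  `zero_length=true`, with the exact spans of both systems carried in
  the `query_coord`/`ref_coord` attributes so parsing is lossless.
* Gap-filling ties prefer substitutions, then leftmost indels; in the
  all-N case this places the inserted-gap portion of an enlarged gap
  before the gap run in alignment terms, but emission is ordered by
  reference coordinate with length-bearing records first, so the
  reported order is gap, then inserted gap.
* Chain-weight ties in the consistent-chain filter take the chain
  starting earlier on the query; equal-weight nested-filter ties keep
  the longer fragment, then the earlier id.
* Double overlaps (query and reference simultaneously) are resolved by
  trimming the smaller overlap from the right fragment and
  re-evaluating — the only reading consistent with the conservation
  law.
* A fragment emptied by overlap truncation is dropped; SNP records
  trimmed out of their fragment are discarded with it.
* Circular-start recognition requires exactly two same-direction
  fragments covering a reference suffix then prefix within
  `extension_distance` of the sequence ends, with a junction gap within
  the same tolerance.
* An equal split of forward and reverse fragments calls the reversed
  ones inverted (deterministic, admittedly arbitrary).

## Problem sizes used by the checks

The packaged tests run the classifier-versus-oracle comparison on 512
generated junction geometries covering every cell of the case table on
both strands, exact-recovery panels of 50 seeds per difference type on
100 kb genomes (subtype variants cycling within their parent type), 100
five-event genomes for routing/ block-disjointness, 20 for conservation,
and 100 random ≤ 3 kb pairs against a brute-force (equality-matrix)
anchor oracle.  `scripts/acceptance.R` recomputes the same quantities at
12 seeds per kind and 40 multi-event genomes and writes them as JSON.

## Worked example

```{r example}
sim <- simulate_genome_pair(
  c("simple_deletion", "inversion", "tandem_duplication"),
  seed = 7, genome_length = 100000)
res <- compare_genomes(sim$ref, sim$query)
res
evaluate_recovery(sim$truth, res$differences, matching = "exact")
```

Writing the browser tracks:

```{r tracks, eval = FALSE}
write_results(res, "out", prefix = "example")
# out/example_local_query.gff3    out/example_local_ref.gff3
# out/example_struct_query.gff3   out/example_struct_ref.gff3
# out/example_blocks_query.gff3   out/example_blocks_ref.gff3
# out/example_summary.txt
```

And aggregating one difference type across many genomes into a per-base
bedGraph track (the value at each reference base is the number of
genomes exhibiting that type there):

```{r bedgraph, eval = FALSE}
aggregate_bedgraph(per_genome_differences, "simple_deletion",
                   seq_lengths(ref), "deletions.bedgraph")
```

## Known limitations

* Duplications whose copies are far apart are reported as simple
  insertions (placement lost to consistent-chain filtering /
  nested-fragment discarding).
* Reference-overlap truncation at structural junctions discards the
  repeat identity of the truncated material by design.
* Reshuffling order comparison ignores fragment directions, as does the
  grouping; directions are only consulted afterwards by inversion
  detection.
* The external-aligner path maps the same thresholds onto `nucmer`,
  `delta-filter -q`, `show-coords -T` and `show-snps -T`, but is only
  exercised when those binaries are present; bit-exact agreement with
  them is not claimed.
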