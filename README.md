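# alndiff

Locate and categorize **every difference between two closely related
DNA sequence sets** — an assembly against a finished genome, or two
strains of one species.  `alndiff` analyses the relative placement of
whole-genome alignment fragments and classifies each difference into a
complete taxonomy, reporting every event with coordinates in *both* the
query and the reference system so results drop straight into a genome
browser or a downstream pipeline.

The taxonomy covers:

* **global** — `unaligned_sequence`;
* **local** — `simple_insertion`, `duplication`, `tandem_duplication`,
  `inserted_gap`, `unaligned_beginning`, `unaligned_end`,
  `simple_deletion`, `collapsed_repeat`, `collapsed_tandem_repeat`,
  `substitution`, `gap`;
* **structural** — `translocation` and `relocation` (five placement
  subtypes each), `reshuffling`, `inversion`;
* plus the `circular_genome_start` annotation for rotated circular
  genomes (reported, never counted).

The heart of the method is a placement-case analysis of neighbouring
fragment pairs.  With `qg` the signed query-side gap and `rg` the
orientation-consistent reference-side gap of a pair, mergeable
fragmentation is classified by sign:

```
(qg>0, rg=0)  insertion family        (qg=0, rg>0)  simple_deletion
(qg=0, rg<0)  tandem_duplication      (qg>0, rg<0)  duplication + insertion
(qg<0, rg=0)  collapsed_tandem_repeat (qg<0, rg>0)  collapsed_repeat
(qg>0, rg>0)  substitution / gap, or deletion + insertion when unequal
(qg<0, rg<0)  trim the smaller overlap and re-evaluate
```

with N-content deciding the gap types.  Remaining fragmentation is
routed to exactly one structural category (translocation, circular
start, reshuffling, relocation, or same-block continuation), overlaps
are truncated, and the surviving fragments become the *mapped blocks* —
query regions alignable without structural interruption.

Fragments come from the built-in anchor aligner (maximal exact matches
→ co-linear chaining with unit-cost gap fill → per-query
length×identity-weighted consistent-chain filtering), or from
MUMmer-family tabular files via `parse_coords()` / `parse_snps()`.

A full simulation engine generates random genomes with controlled
modifications of every type and a machine-readable truth ledger, and
`evaluate_recovery()` scores detection against it exactly or by
overlap.

## Worked example

```r
library(alndiff)

sim <- simulate_genome_pair(
  c("simple_deletion", "inversion", "tandem_duplication"),
  seed = 7, genome_length = 100000)
res <- compare_genomes(sim$ref, sim$query)
res
#> <alndiff_result>
#>   1 query sequence(s) vs 1 reference sequence(s)
#>   3 mapped block(s), 3 difference(s)
#>     tandem_duplication       1
#>     simple_deletion          1
#>     inversion                1

subset(res$differences,
       select = c(diff_type, query_start, query_end, ref_start, ref_end, length))
#>            diff_type query_start query_end ref_start ref_end length
#> 1 tandem_duplication       26530     28436     24624   26530   1906
#> 2    simple_deletion       45467     45467     43561   44133    572
#> 3          inversion       86991     87991     85657   86657   1000

evaluate_recovery(sim$truth, res$differences, matching = "exact")
#>            diff_type n_truth n_correct
#> 1 tandem_duplication       1         1
#> 2    simple_deletion       1         1
#> 3          inversion       1         1
```

The three planted events come back with their exact types and
coordinates: the tandem duplication occupies query bases 26,530–28,436
(an extra copy of reference 24,624–26,530), the 572 bp deletion is a
zero-length breakpoint on the query anchored at 45,467 opposite
reference span 43,561–44,133, and the inverted 1 kb block spans the same
interval in both systems.  The query splits into three mapped blocks at
the inversion:

```r
res$blocks
#>   block_id query_id query_start query_end ref_id ref_start ref_end strand
#> 1        1  query_1           0     86991  ref_1         0   85657      +
#> 2        2  query_1       86991     87991  ref_1     85657   86657      -
#> 3        3  query_1       87991    101334  ref_1     86657  100000      +
```

`write_results(res, "out", "example")` writes six GFF3 tracks (local and
structural differences plus mapped blocks, each in query- and
reference-based coordinates) and a per-type summary;
`aggregate_bedgraph()` collapses one difference type across many genomes
into a per-base bedGraph count.

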