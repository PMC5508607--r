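test_that("nested fragments are discarded on either coordinate system", {
  f <- fragments(query_id = "q", query_start = c(0, 200),
                 query_end = c(1000, 300), ref_id = "r",
                 ref_start = c(0, 2000), ref_end = c(1000, 2100),
                 frag_id = 1:2)
  nf <- filter_nested_fragments(f)
  expect_equal(nf$kept$frag_id, 1L)
  expect_equal(nf$discarded$frag_id, 2L)

  # reference-nested: a duplicated region maps back inside another
  # fragment's reference span
  g <- fragments(query_id = "q", query_start = c(0, 5000),
                 query_end = c(4000, 5200), ref_id = "r",
                 ref_start = c(0, 1000), ref_end = c(4000, 1200),
                 frag_id = 1:2)
  ng <- filter_nested_fragments(g)
  expect_equal(ng$kept$frag_id, 1L)

  # no containment: everything kept
  h <- fragments(query_id = "q", query_start = c(0, 500),
                 query_end = c(400, 900), ref_id = "r",
                 ref_start = c(0, 500), ref_end = c(400, 900),
                 frag_id = 1:2)
  expect_equal(nrow(filter_nested_fragments(h)$kept), 2L)
})

test_that("unaligned query ends are measured from the outermost fragments", {
  q <- sequence_set(c(q = strrep("A", 1000)), "query")
  f <- fragments("q", 0, 880, "r", 0, 880, frag_id = 1)
  d <- detect_unaligned_ends(q, f)
  expect_equal(d$diff_type, "unaligned_end")
  expect_equal(d$length, 120L)
  expect_equal(c(d$query_start, d$query_end), c(880L, 1000L))

  f2 <- fragments("q", 30, 1000, "r", 100, 1070, frag_id = 1)
  d2 <- detect_unaligned_ends(q, f2)
  expect_equal(d2$diff_type, "unaligned_beginning")
  expect_equal(d2$length, 30L)
  expect_equal(c(d2$ref_start, d2$ref_end), c(100L, 100L))
})

test_that("merge criteria gate on reference distance, direction and mapping", {
  cfg <- diff_config()
  a <- fragments("q", 0, 1000, "r", 0, 1000, frag_id = 1)
  near <- fragments("q", 1000, 2000, "r", 1050, 2050, frag_id = 2)
  far <- fragments("q", 1000, 2000, "r", 16000, 17000, frag_id = 2)
  rev1 <- fragments("q", 1000, 2000, "r", 1050, 2050, strand = "-",
                    frag_id = 2)
  expect_true(mergeable(a, near, cfg))
  expect_false(mergeable(a, far, cfg))       # relocation candidate
  expect_false(mergeable(a, rev1, cfg))      # inversion candidate
  # reference gap covered by another fragment of this query: rearranged
  # material, not a deletion
  other <- fragments("q", 3000, 3040, "r", 1010, 1050, frag_id = 9)
  expect_false(mergeable(a, near, cfg, others = rbind(a, near, other)))
})

test_that("classify_pair matches the sequence-diff oracle on sampled cells", {
  set.seed(61)
  for (cell in pair_case_cells()) {
    for (rev in c(FALSE, TRUE)) {
      cs <- make_pair_case(cell, rev)
      d <- classify_pair(cs$a, cs$b, cs$query)
      expect_equal(diffs_to_multiset(d),
                   norm_multiset(seq_diff_oracle(cs$R, cs$Q)),
                   ignore_attr = TRUE,
                   info = paste(cell, if (rev) "rev" else "fwd"))
    }
  }
})

test_that("classify_pair refuses non-mergeable pairs", {
  a <- fragments("q", 0, 1000, "r", 0, 1000, frag_id = 1)
  far <- fragments("q", 1000, 2000, "r", 16000, 17000, frag_id = 2)
  q <- sequence_set(c(q = strrep("A", 2000)), "query")
  expect_error(classify_pair(a, far, q), "merge criteria")
})

test_that("merge_pass collapses mergeable chains and is a fixpoint otherwise", {
  set.seed(62)
  # reference with three deletions in the query: four fragments chain
  # into one, three deletion differences.  Junction bases are guarded so
  # no deletion carries accidental homology at its breakpoints.
  cuts <- list(c(2000, 2300), c(4000, 4400), c(6000, 6500))
  ch0 <- function(s, i) substr(s, i + 1, i + 1)
  repeat {
    refseq <- rand_dna(9000)
    ok <- all(vapply(cuts, function(cc) {
      ch0(refseq, cc[1]) != ch0(refseq, cc[2]) &&
        ch0(refseq, cc[1] - 1) != ch0(refseq, cc[2] - 1)
    }, logical(1)))
    if (ok) break
  }
  qseq <- paste0(substr(refseq, 1, 2000), substr(refseq, 2301, 4000),
                 substr(refseq, 4401, 6000), substr(refseq, 6501, 9000))
  al <- align_genomes(c(r = refseq), c(q = qseq),
                      diff_config(extension_distance = 50))
  mp <- merge_pass(al$fragments, al$snps,
                   sequence_set(c(q = qseq), "query"), diff_config())
  expect_equal(nrow(mp$fragments), 1L)
  dels <- mp$differences[mp$differences$diff_type == "simple_deletion", ]
  expect_equal(nrow(dels), 3L)
  expect_equal(sort(dels$length), c(300L, 400L, 500L))
  expect_equal(sort(dels$ref_start), c(2000L, 4000L, 6000L))

  # no mergeable pairs: output equals input
  f <- fragments(query_id = "q", query_start = c(0, 1000),
                 query_end = c(1000, 2000), ref_id = c("r1", "r2"),
                 ref_start = c(0, 0), ref_end = c(1000, 1000),
                 frag_id = 1:2)
  q2 <- sequence_set(c(q = strrep("A", 2000)), "query")
  mp2 <- merge_pass(f, snp_records(), q2, diff_config())
  expect_equal(mp2$fragments$frag_id, f$frag_id)
  expect_equal(nrow(mp2$differences), 0L)
})

test_that("planted deletions are recovered with exact coordinates", {
  sim <- simulate_genome_pair(rep("simple_deletion", 5), seed = 63,
                              genome_length = 100000,
                              event_length = c(300L, 500L))
  res <- compare_genomes(sim$ref, sim$query)
  ev <- evaluate_recovery(sim$truth, res$differences, "exact")
  expect_equal(ev$n_correct, ev$n_truth)
  expect_equal(sum(res$summary), 5L)
})

test_that("span-length conservation holds per merged fragment", {
  for (seed in 64:66) {
    sim <- simulate_genome_pair(
      c("simple_insertion", "simple_deletion", "tandem_duplication",
        "collapsed_repeat", "gap_enlarged"),
      seed = seed, genome_length = 80000)
    res <- compare_genomes(sim$ref, sim$query)
    cons <- check_conservation(res)
    expect_true(all(cons$ok))
  }
})
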