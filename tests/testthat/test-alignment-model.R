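test_that("sequence sets normalize case and reject bad input", {
  ss <- sequence_set(c(chr1 = "acgtn"), role = "reference")
  expect_equal(ss[["chr1"]], "ACGTN")
  expect_equal(attr(ss, "role"), "reference")
  expect_error(sequence_set(c(chr1 = "ACGU")), "residues")
  expect_error(sequence_set(c(a = "ACGT", a = "ACGT")), "duplicate")
  expect_error(sequence_set(stats::setNames("ACGT", "")), "named")
})

test_that("fragment validation enforces spans, strand and snp consistency", {
  expect_error(fragments("q", 10, 10, "r", 0, 5), "start < end")
  expect_error(fragments("q", 0, 10, "r", 0, 10, strand = "x"), "strand")
  f <- fragments("q", 0, 10, "r", 0, 12)
  s <- snp_records(frag_id = c(1, 1), kind = "deletion",
                   ref_pos = c(4, 5), query_pos = c(4, 4),
                   ref_base = c("A", "C"), query_base = ".")
  expect_true(validate_fragments(f, s))
  s_bad <- snp_records(frag_id = 1, kind = "deletion", ref_pos = 4,
                       query_pos = 4, ref_base = "A", query_base = ".")
  expect_error(validate_fragments(f, s_bad), "net indel")
  expect_error(
    snp_records(frag_id = 1, kind = "insertion", ref_pos = 1,
                query_pos = 1, ref_base = "A", query_base = "T"),
    "gap marker")
})

test_that("pair geometry: contiguous identity pair has zero gaps", {
  a <- fragments("q", 0, 100, "r", 0, 100, frag_id = 1)
  b <- fragments("q", 100, 200, "r", 100, 200, frag_id = 2)
  g <- fragment_pair_geometry(a, b)
  expect_equal(g$query_gap, 0L)
  expect_equal(g$ref_gap, 0L)
  expect_true(g$same_direction)
  expect_true(g$ref_order_consistent)
})

test_that("pair geometry matches coordinates recomputed from a planted deletion", {
  # construct query = reference with a 50 bp block removed, align, and
  # check that the fragment pair implied by the construction yields the
  # expected gaps
  set.seed(421)
  refseq <- rand_dna(500)
  # boundary guards so the fragment split is unambiguous
  while (substr(refseq, 201, 201) == substr(refseq, 251, 251) ||
         substr(refseq, 200, 200) == substr(refseq, 250, 250)) {
    refseq <- rand_dna(500)
  }
  qseq <- paste0(substr(refseq, 1, 200), substr(refseq, 251, 500))
  al <- align_genomes(c(r = refseq), c(q = qseq),
                      diff_config(extension_distance = 10))
  f <- al$fragments[order(al$fragments$query_start), ]
  expect_equal(nrow(f), 2L)
  expect_equal(f$query_end[1], 200L)
  expect_equal(f$ref_start[2], 250L)
  g <- fragment_pair_geometry(f[1, ], f[2, ])
  expect_equal(g$query_gap, 0L)
  expect_equal(g$ref_gap, 50L)
  expect_true(g$ref_order_consistent)
})

test_that("reversed pairs use the reverse-order rule", {
  a <- fragments("q", 0, 100, "r", 200, 300, strand = "-", frag_id = 1)
  b <- fragments("q", 100, 200, "r", 100, 200, strand = "-", frag_id = 2)
  g <- fragment_pair_geometry(a, b)
  expect_equal(g$ref_gap, 0L)
  expect_true(g$ref_order_consistent)
  # oracle: reverse-complement the query and recheck as a forward pair
  # (reflection swaps the roles of a and b)
  ar <- fragments("q", 0, 100, "r", 100, 200, strand = "+", frag_id = 2)
  br <- fragments("q", 100, 200, "r", 200, 300, strand = "+", frag_id = 1)
  gf <- fragment_pair_geometry(ar, br)
  expect_equal(gf$ref_gap, g$ref_gap)
  expect_equal(gf$query_gap, g$query_gap)
  expect_true(gf$ref_order_consistent)
})

test_that("pair geometry is antisymmetric under coordinate reflection", {
  set.seed(11)
  for (i in 1:25) {
    qa <- sort(sample(0:500, 2)); qb <- sort(sample(0:500, 2))
    if (qa[1] > qb[1]) { tmp <- qa; qa <- qb; qb <- tmp }
    if (qa[1] == qb[1] || qa[2] >= qb[2]) next
    ra <- sort(sample(0:500, 2)); rb2 <- sort(sample(0:500, 2))
    if (qa[2] == qa[1] || qb[2] == qb[1] ||
        ra[2] == ra[1] || rb2[2] == rb2[1]) next
    a <- fragments("q", qa[1], qa[2], "r", ra[1], ra[2], frag_id = 1)
    b <- fragments("q", qb[1], qb[2], "r", rb2[1], rb2[2], frag_id = 2)
    g <- fragment_pair_geometry(a, b)
    # reflect both coordinate systems around 600 so b precedes a
    refl <- function(f, id) fragments(
      "q", 600 - f$query_end, 600 - f$query_start,
      "r", 600 - f$ref_end, 600 - f$ref_start, frag_id = id)
    g2 <- fragment_pair_geometry(refl(b, 1), refl(a, 2))
    expect_equal(g2$query_gap, g$query_gap)
    expect_equal(g2$ref_gap, g$ref_gap)
    expect_equal(g2$ref_order_consistent, g$ref_order_consistent)
  }
})

test_that("geometry rejects fragments on different query sequences", {
  a <- fragments("q1", 0, 100, "r", 0, 100, frag_id = 1)
  b <- fragments("q2", 100, 200, "r", 100, 200, frag_id = 2)
  expect_error(fragment_pair_geometry(a, b), "different query")
})

test_that("config validates its thresholds", {
  expect_error(diff_config(min_cluster_len = 0), "positive")
  expect_error(diff_config(min_identity = 150), "0, 100")
  cfg <- diff_config()
  expect_equal(cfg$min_cluster_len, 65L)
  expect_equal(cfg$extension_distance, 200L)
  expect_equal(cfg$max_merge_distance, 10000L)
})
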