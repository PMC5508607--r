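# Global detection (wholly unaligned sequences) and local differences
# inside fragments.

test_that("short and novel query sequences are reported wholly unaligned", {
  set.seed(51)
  refseq <- rand_dna(10000)
  query <- c(q_short = substr(refseq, 101, 140),   # 40 bp copy
             q_full = refseq,
             q_novel = rand_dna(3000))
  res <- compare_genomes(c(ref = refseq), query)
  una <- res$differences[res$differences$diff_type == "unaligned_sequence", ]
  expect_setequal(una$query_id, c("q_short", "q_novel"))
  expect_equal(una$length[una$query_id == "q_short"], 40L)
  # counts partition the query sequences
  expect_equal(nrow(una) + length(unique(res$fragments$query_id)), 3L)
})

test_that("adjacent snp records coalesce into single differences", {
  set.seed(52)
  refseq <- rand_dna(3000)
  ins <- rand_dna(3)
  qseq <- paste0(substr(refseq, 1, 1500), ins, substr(refseq, 1501, 3000))
  # guards for unambiguous placement
  if (substr(ins, 1, 1) == substr(refseq, 1501, 1501) ||
      substr(ins, 3, 3) == substr(refseq, 1500, 1500)) {
    substr(ins, 1, 1) <- setdiff(c("A", "C", "G", "T"),
                                 substr(refseq, 1501, 1501))[1]
    substr(ins, 3, 3) <- setdiff(c("A", "C", "G", "T"),
                                 substr(refseq, 1500, 1500))[1]
    qseq <- paste0(substr(refseq, 1, 1500), ins, substr(refseq, 1501, 3000))
  }
  al <- align_genomes(c(r = refseq), c(q = qseq), diff_config())
  d <- detect_snp_differences(al$fragments, al$snps)
  expect_equal(nrow(d), 1L)
  expect_equal(d$diff_type, "simple_insertion")
  expect_equal(d$length, 3L)
  expect_equal(d$query_start, 1500L)
  expect_equal(d$query_end, 1503L)
  expect_equal(d$ref_start, 1500L)   # zero-length reference anchor
  expect_equal(d$ref_end, 1500L)
})

test_that("an isolated substitution yields a length-1 difference", {
  set.seed(53)
  refseq <- rand_dna(2000)
  qseq <- refseq
  substr(qseq, 1001, 1001) <- setdiff(c("A", "C", "G", "T"),
                                      substr(refseq, 1001, 1001))[1]
  al <- align_genomes(c(r = refseq), c(q = qseq), diff_config())
  d <- detect_snp_differences(al$fragments, al$snps)
  expect_equal(d$diff_type, "substitution")
  expect_equal(d$length, 1L)
  expect_equal(d$ref_start, 1000L)
})

test_that("N runs classify as gap / inserted_gap by reference extent", {
  set.seed(54)
  refseq <- rand_dna(3000)
  # 50 N replacing 50 bases: gap
  q1 <- paste0(substr(refseq, 1, 1000), strrep("N", 50),
               substr(refseq, 1051, 3000))
  al1 <- align_genomes(c(r = refseq), c(q = q1), diff_config())
  d1 <- detect_gap_runs(al1$fragments, al1$snps)
  expect_equal(d1$diff_type, "gap")
  expect_equal(d1$length, 50L)
  expect_equal(c(d1$ref_start, d1$ref_end), c(1000L, 1050L))

  # 80 N replacing 50 bases: gap + inserted_gap, gap first
  q2 <- paste0(substr(refseq, 1, 1000), strrep("N", 80),
               substr(refseq, 1051, 3000))
  al2 <- align_genomes(c(r = refseq), c(q = q2), diff_config())
  d2 <- detect_gap_runs(al2$fragments, al2$snps)
  expect_equal(d2$diff_type, c("gap", "inserted_gap"))
  expect_equal(d2$length, c(50L, 30L))

  # shared N run in both sequences: no difference
  r3 <- paste0(substr(refseq, 1, 1000), strrep("N", 60),
               substr(refseq, 1061, 3000))
  al3 <- align_genomes(c(r = r3), c(q = r3), diff_config())
  d3 <- detect_gap_runs(al3$fragments, al3$snps)
  expect_equal(nrow(d3), 0L)
  expect_equal(nrow(al3$snps), 0L)
})

test_that("within-fragment indel lengths reconcile with span lengths", {
  sim <- simulate_genome_pair(
    c("simple_insertion", "simple_deletion", "substitution"),
    seed = 55, genome_length = 40000, event_length = c(20L, 150L))
  al <- align_genomes(sim$ref, sim$query)
  d <- rbind(detect_snp_differences(al$fragments, al$snps),
             detect_gap_runs(al$fragments, al$snps))
  cfg <- diff_config()
  expect_true(all(d$length <= cfg$extension_distance))
  for (fid in al$fragments$frag_id) {
    fr <- al$fragments[al$fragments$frag_id == fid, ]
    dd <- d[d$frag_group == fid, ]
    net <- sum(dd$length[dd$diff_type %in%
                           c("simple_insertion", "inserted_gap")]) -
      sum(dd$length[dd$diff_type == "simple_deletion"])
    expect_equal((fr$query_end - fr$query_start) -
                   (fr$ref_end - fr$ref_start), net)
  }
})
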