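test_that("genome generation is reproducible and respects composition", {
  g1 <- random_genome(3, c(1000, 2000, 1500), seed = 101)
  g2 <- random_genome(3, c(1000, 2000, 1500), seed = 101)
  expect_identical(unclass(g1), unclass(g2))
  expect_equal(length(g1), 3L)
  expect_equal(unname(seq_lengths(g1)), c(1000L, 2000L, 1500L))

  big <- random_genome(1, 100000, gc = 0.5, seed = 102)
  gc <- mean(chars(big[[1]]) %in% c("G", "C"))
  expect_gte(gc, 0.48)
  expect_lte(gc, 0.52)
})

test_that("modification plans are concrete and reapply deterministically", {
  sim <- simulate_genome_pair(c("simple_insertion", "inversion"),
                              seed = 103, genome_length = 30000)
  ap <- apply_modifications(sim$ref, sim$plan)
  expect_identical(unclass(ap$query), unclass(sim$query))
  expect_equal(ap$truth, sim$truth)
})

test_that("overlapping event placements are rejected with an explanation", {
  ref <- random_genome(1, 5000, seed = 104)
  ev <- function(p0, p1) list(kind = "simple_deletion", seq_id = "ref_1",
                              event_id = 1L, p0 = p0, p1 = p1,
                              q_piece = "", params = list())
  expect_error(apply_modifications(ref, list(ev(100L, 400L),
                                             ev(300L, 600L))),
               "overlapping")
})

test_that("truth ledgers project consistently onto the emitted query", {
  kinds <- c("simple_insertion", "simple_deletion", "substitution", "gap",
             "inserted_gap", "gap_enlarged", "tandem_duplication",
             "duplication", "collapsed_tandem_repeat", "collapsed_repeat",
             "inversion", "reshuffling", "unaligned_beginning",
             "unaligned_end", "unaligned_sequence",
             "relocation_with_insertion", "translocation_with_overlap",
             "rotation")
  for (kind in kinds) {
    sim <- simulate_genome_pair(kind, seed = 105,
                                genome_length = 60000)
    expect_true(isTRUE(verify_truth_projection(sim$ref, sim$query,
                                               sim$truth)),
                info = kind)
  }
  # length bookkeeping for a composite edit plan
  sim <- simulate_genome_pair(
    c("simple_insertion", "simple_deletion", "inserted_gap"),
    seed = 106, genome_length = 50000)
  tr <- sim$truth
  net <- sum(tr$length[tr$diff_type %in%
                         c("simple_insertion", "inserted_gap")]) -
    sum(tr$length[tr$diff_type == "simple_deletion"])
  expect_equal(nchar(sim$query[["query_1"]]) - 50000L, net)
})

test_that("recovery evaluation distinguishes exact and overlap matching", {
  truth <- alndiff:::truth_row(1L, "simple_deletion", "simple_deletion",
                               "q", 100L, 100L, "r", 100L, 200L, 100L)
  hit <- alndiff:::diff_row("simple_deletion", "q", 100L, 100L, "r",
                            100L, 200L, 100L, category = "struct")
  shifted <- alndiff:::diff_row("simple_deletion", "q", 103L, 103L, "r",
                                103L, 203L, 100L, category = "struct")
  expect_equal(evaluate_recovery(truth, hit, "exact")$n_correct, 1L)
  expect_equal(evaluate_recovery(truth, shifted, "exact")$n_correct, 0L)
  expect_equal(evaluate_recovery(truth, shifted, "overlap")$n_correct, 1L)

  # a tandem duplication detected as a simple insertion is wrong exactly
  # but correct under the grouped matching
  t2 <- alndiff:::truth_row(1L, "tandem_duplication", "tandem_duplication",
                            "q", 500L, 800L, "r", 200L, 500L, 300L)
  asins <- alndiff:::diff_row("simple_insertion", "q", 500L, 800L, "r",
                              500L, 500L, 300L, category = "struct")
  expect_equal(evaluate_recovery(t2, asins, "exact")$n_correct, 0L)
  expect_equal(evaluate_recovery(t2, asins, "overlap")$n_correct, 1L)
})

test_that("distant duplications surface as simple insertions (documented)", {
  sim <- simulate_genome_pair("duplication_distant", seed = 107)
  res <- compare_genomes(sim$ref, sim$query)
  tr <- sim$truth
  ins <- res$differences[res$differences$diff_type == "simple_insertion", ]
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$query_start, tr$query_start)
  expect_equal(ins$query_end, tr$query_end)
  ov <- evaluate_recovery(tr, res$differences, "overlap")
  expect_equal(ov$n_correct, ov$n_truth)
})
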