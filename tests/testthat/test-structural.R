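test_that("translocation subtypes follow the junction content", {
  for (kind in c("translocation", "translocation_with_insertion",
                 "translocation_with_overlap")) {
    sim <- simulate_genome_pair(kind, seed = 71)
    res <- compare_genomes(sim$ref, sim$query)
    tr <- res$differences[res$differences$diff_type == "translocation", ]
    expect_equal(nrow(tr), 1L, info = kind)
    expect_equal(tr$subtype, sim$truth$subtype[sim$truth$diff_type ==
                                                 "translocation"],
                 info = kind)
    if (kind == "translocation_with_insertion") {
      ins <- res$differences[res$differences$diff_type ==
                               "simple_insertion", ]
      expect_equal(nrow(ins), 1L)
      expect_equal(ins$length, tr$length)
    }
  }
})

test_that("relocations report the five subtypes with companion differences", {
  sim <- simulate_genome_pair("relocation_with_inserted_gap", seed = 72)
  res <- compare_genomes(sim$ref, sim$query)
  rl <- res$differences[res$differences$diff_type == "relocation", ]
  expect_equal(rl$subtype, "with_inserted_gap")
  ig <- res$differences[res$differences$diff_type == "inserted_gap", ]
  expect_equal(nrow(ig), 1L)
  expect_equal(ig$length, rl$length)

  sim2 <- simulate_genome_pair("relocation", seed = 73)
  res2 <- compare_genomes(sim2$ref, sim2$query)
  rl2 <- res2$differences[res2$differences$diff_type == "relocation", ]
  expect_equal(rl2$subtype, "simple")
  expect_equal(rl2$length, 0L)
})

test_that("nearby wrong-order fragments route to reshuffling, not relocation", {
  # three adjacent reference segments emitted in query order 2,1,3:
  # members 1 and 2 are the reshuffled group, member 3 stays in place
  f <- fragments(query_id = "q",
                 query_start = c(0, 3000, 6000),
                 query_end = c(3000, 6000, 9000),
                 ref_id = "r",
                 ref_start = c(3000, 0, 6000),
                 ref_end = c(6000, 3000, 9000),
                 frag_id = 1:3)
  rt <- structural_routing(f, diff_config())
  expect_equal(rt$pairs$route, c("reshuffling", "reshuffling"))
  expect_equal(length(rt$groups), 1L)
  expect_setequal(rt$groups[[1]]$reshuffled, c(1L, 2L))
  # oracle: the permutation (2,1,3) has non-fixed points exactly {1,2}
  perm <- rank(f$ref_start)
  expect_setequal(f$frag_id[perm != seq_along(perm)], c(1L, 2L))
})

test_that("reshuffling emits per-member differences plus junction insertions", {
  sim <- simulate_genome_pair("reshuffling_with_insertion", seed = 74)
  res <- compare_genomes(sim$ref, sim$query)
  rs <- res$differences[res$differences$diff_type == "reshuffling", ]
  expect_equal(nrow(rs), 2L)
  ins <- res$differences[res$differences$diff_type == "simple_insertion", ]
  expect_equal(nrow(ins), 1L)
  ev <- evaluate_recovery(sim$truth, res$differences, "exact")
  expect_equal(ev$n_correct, ev$n_truth)
})

test_that("rotated circular genomes annotate the start without differences", {
  sim <- simulate_genome_pair("rotation", seed = 75)
  res <- compare_genomes(sim$ref, sim$query)
  expect_equal(attr(res$summary, "total"), 0L)
  expect_equal(res$summary[["circular_genome_start"]], 1L)

  # non-rotated identical genome: nothing
  set.seed(75)
  s <- rand_dna(50000)
  res2 <- compare_genomes(c(ref_1 = s), c(query_1 = s))
  expect_equal(sum(res2$summary), 0L)

  # rotation plus an internal deletion keeps both calls
  sim3 <- simulate_genome_pair(c("rotation", "simple_deletion"), seed = 76)
  res3 <- compare_genomes(sim3$ref, sim3$query)
  expect_equal(res3$summary[["circular_genome_start"]], 1L)
  expect_equal(res3$summary[["simple_deletion"]], 1L)
  ev3 <- evaluate_recovery(sim3$truth, res3$differences, "exact")
  expect_equal(ev3$n_correct, ev3$n_truth)
})

test_that("inversions are the reversed minority, never a whole reversed query", {
  sim <- simulate_genome_pair("inversion", seed = 77)
  res <- compare_genomes(sim$ref, sim$query)
  inv <- res$differences[res$differences$diff_type == "inversion", ]
  expect_equal(nrow(inv), 1L)
  expect_equal(inv$query_start, sim$truth$query_start)
  expect_equal(inv$query_end, sim$truth$query_end)
  expect_equal(nrow(res$blocks), 3L)

  # whole-sequence reverse complement: no inversion
  set.seed(77)
  s <- rand_dna(30000)
  res2 <- compare_genomes(c(ref_1 = s), c(query_1 = rc(s)))
  expect_equal(sum(res2$summary), 0L)
  expect_equal(res2$fragments$strand, "-")

  # direct detector check: fwd/rev/fwd marks only the middle fragment
  f <- fragments(query_id = "q", query_start = c(0, 100, 200),
                 query_end = c(100, 200, 300), ref_id = "r",
                 ref_start = c(0, 100, 200), ref_end = c(100, 200, 300),
                 strand = c("+", "-", "+"), frag_id = 1:3)
  d <- detect_inversions(f)
  expect_equal(nrow(d), 1L)
  expect_equal(c(d$query_start, d$query_end), c(100L, 200L))
})

test_that("an inverted fragment inside a translocation reports both", {
  f <- fragments(query_id = "q", query_start = c(0, 5000),
                 query_end = c(5000, 9000), ref_id = c("r1", "r2"),
                 ref_start = c(0, 2000), ref_end = c(5000, 6000),
                 strand = c("+", "-"), frag_id = 1:2)
  q <- sequence_set(c(q = strrep("A", 9000)), "query")
  st <- alndiff:::structural_stage(f, q, NULL, diff_config())
  expect_setequal(
    unique(st$differences$diff_type), c("translocation", "inversion"))
})

test_that("mapped blocks are query-disjoint and split at rearrangements", {
  set.seed(78)
  s <- rand_dna(20000)
  res <- compare_genomes(c(ref_1 = s), c(query_1 = s))
  expect_equal(nrow(res$blocks), 1L)

  sim <- simulate_genome_pair("translocation_with_overlap", seed = 79)
  res2 <- compare_genomes(sim$ref, sim$query)
  b <- res2$blocks[res2$blocks$query_id == "query_1", ]
  b <- b[order(b$query_start), ]
  expect_equal(nrow(b), 2L)
  expect_true(all(b$query_end[-nrow(b)] <= b$query_start[-1]))
})

test_that("structural routing consumes each neighbour pair exactly once", {
  sim <- simulate_genome_pair(
    c("inversion", "reshuffling", "simple_deletion", "collapsed_repeat"),
    seed = 80)
  res <- compare_genomes(sim$ref, sim$query)
  rt <- res$routing
  f <- res$fragments
  # every adjacent pair appears once with a single category
  for (qid in unique(f$query_id)) {
    ff <- f[f$query_id == qid, ]
    ff <- ff[order(ff$query_start), ]
    if (nrow(ff) < 2) next
    expect_equal(nrow(rt[rt$query_id == qid, ]), nrow(ff) - 1L)
  }
  expect_true(all(rt$route %in% c("translocation", "relocation",
                                  "circular", "reshuffling",
                                  "continuation")))
})
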