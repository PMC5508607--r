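sim_result_fixture <- function(seed = 91) {
  sim <- simulate_genome_pair(
    c("simple_insertion", "simple_deletion", "substitution", "gap",
      "inversion", "tandem_duplication"),
    seed = seed, genome_length = 60000)
  list(sim = sim, res = compare_genomes(sim$ref, sim$query))
}

test_that("GFF3 round trip recovers every difference field", {
  fx <- sim_result_fixture()
  d <- fx$res$differences
  for (category in c("local", "structural")) {
    want <- if (category == "local") "local" else "struct"
    path <- tempfile(fileext = ".gff3")
    write_gff3(d, NULL, "query", category, path)
    back <- read_diff_gff3(path)
    orig <- d[d$category == want, , drop = FALSE]
    o1 <- orig[order(orig$query_id, orig$query_start, orig$diff_type,
                     orig$ref_start), ]
    o2 <- back[order(back$query_id, back$query_start, back$diff_type,
                     back$ref_start), ]
    rownames(o1) <- rownames(o2) <- NULL
    expect_equal(o2, o1)
  }
})

test_that("zero-length spans become one-base anchors flagged zero_length", {
  d <- alndiff:::diff_row("simple_deletion", "q", 500L, 500L, "r",
                          500L, 600L, 100L, category = "struct")
  path <- tempfile(fileext = ".gff3")
  write_gff3(d, NULL, "query", "structural", path)
  ln <- grep("simple_deletion", readLines(path), value = TRUE)
  f <- strsplit(ln, "\t")[[1]]
  expect_equal(f[4], "500")
  expect_equal(f[5], "500")
  expect_match(f[9], "zero_length=true")
  # the reference-based file carries the true 1-based inclusive span
  path2 <- tempfile(fileext = ".gff3")
  write_gff3(d, NULL, "reference", "structural", path2)
  f2 <- strsplit(grep("simple_deletion", readLines(path2),
                      value = TRUE), "\t")[[1]]
  expect_equal(as.integer(f2[4:5]), c(501L, 600L))
})

test_that("empty difference tables give a valid header-only file", {
  path <- tempfile(fileext = ".gff3")
  write_gff3(alndiff:::empty_differences(), NULL, "query", "local", path)
  expect_equal(readLines(path), "##gff-version 3")
  expect_equal(nrow(read_diff_gff3(path)), 0L)
})

test_that("summary counts every taxonomy type and a regenerated summary agrees", {
  d <- do.call(rbind, replicate(5, alndiff:::diff_row(
    "simple_insertion", "q", 0L, 10L, "r", 0L, 0L, 10L,
    category = "local"), simplify = FALSE))
  n <- count_differences(d)
  expect_equal(n[["simple_insertion"]], 5L)
  expect_equal(sum(n), 5L)
  expect_equal(attr(n, "total"), 5L)

  fx <- sim_result_fixture(92)
  files <- write_results(fx$res, tempfile("out"), "t")
  back <- rbind(read_diff_gff3(files[["local_query"]]),
                read_diff_gff3(files[["struct_query"]]))
  expect_equal(count_differences(back), fx$res$summary)
  sum_lines <- readLines(files[["summary"]])
  expect_equal(length(files), 7L)
  expect_true(all(file.exists(files)))
  expect_true(any(grepl("^total\t", sum_lines)))
})

test_that("written GFF3 parses with an independent GFF reader", {
  fx <- sim_result_fixture(93)
  path <- tempfile(fileext = ".gff3")
  write_gff3(fx$res$differences, NULL, "reference", "local", path)
  gr <- rtracklayer::import(path)
  d <- fx$res$differences
  d <- d[d$category == "local", ]
  expect_equal(length(gr), nrow(d))
  expect_true(all(GenomicRanges::start(gr) >= 1L))
  expect_setequal(as.character(gr$type), unique(d$diff_type))
})

test_that("bedGraph aggregation counts genomes per base and conserves mass", {
  del <- function(s, e) alndiff:::diff_row(
    "simple_deletion", "q", 0L, 0L, "chr", as.integer(s), as.integer(e),
    as.integer(e - s), category = "struct")
  # one genome, one deletion
  one <- aggregate_bedgraph(list(g1 = del(100, 200)), "simple_deletion",
                            c(chr = 1000L))
  expect_equal(one, data.frame(ref_id = "chr", start = 100, end = 200,
                               value = 1L),
               ignore_attr = TRUE)
  # 15 of 21 genomes share a deletion
  genomes <- c(lapply(1:15, function(i) del(300, 400)),
               lapply(16:21, function(i) del(600, 650)))
  names(genomes) <- paste0("g", 1:21)
  agg <- aggregate_bedgraph(genomes, "simple_deletion", c(chr = 1000L))
  expect_equal(agg$value[agg$start == 300], 15L)
  expect_equal(agg$value[agg$start == 600], 6L)
  # mass conservation: sum(value * width) equals summed event widths
  expect_equal(sum(agg$value * (agg$end - agg$start)),
               15L * 100L + 6L * 50L)
  # disjoint events in different genomes stay disjoint value-1 intervals
  two <- aggregate_bedgraph(list(g1 = del(0, 10), g2 = del(50, 60)),
                            "simple_deletion", c(chr = 100L))
  expect_equal(two$value, c(1L, 1L))
  # coordinates beyond the reference length are an error naming the genome
  expect_error(
    aggregate_bedgraph(list(bad_genome = del(900, 1100)),
                       "simple_deletion", c(chr = 1000L)),
    "bad_genome")
})

test_that("bedGraph output file is 0-based half-open", {
  path <- tempfile(fileext = ".bedgraph")
  aggregate_bedgraph(
    list(g1 = alndiff:::diff_row("gap", "q", 0L, 0L, "chr", 10L, 20L,
                                 10L, category = "local")),
    "gap", c(chr = 100L), path)
  lines <- readLines(path)
  expect_match(lines[1], "^track type=bedGraph")
  expect_equal(lines[2], "chr\t10\t20\t1")
})
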