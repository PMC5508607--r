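# Test helpers: independent oracles and case generators.
#
# brute_anchors: maximal-exact-match discovery by full equality-matrix
#   diagonal scanning — a different algorithm from the k-mer seeding used
#   by the package.
# seq_diff_oracle: classifies the difference between two region strings
#   from the sequences alone, via longest-common-prefix/suffix
#   decomposition plus repeat-suffix detection; independent of the
#   fragment-geometry case table it is used to check.
# make_pair_case: builds sequences and a consistent fragment pair for
#   each cell of the placement-case table, with boundary guards so the
#   decomposition is unambiguous.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

rc <- function(s) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(s)))

# longest common prefix length of two character vectors
lcp_len <- function(a, b) {
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  w <- which(a[seq_len(n)] != b[seq_len(n)])
  if (!length(w)) n else w[1L] - 1L
}

lcs_len <- function(a, b) lcp_len(rev(a), rev(b))

# --- sequence-level difference oracle ------------------------------------

ins_family_oracle <- function(seq) {
  ch <- chars(seq)
  r <- rle(ch == "N")
  data.frame(type = ifelse(r$values, "inserted_gap", "simple_insertion"),
             length = r$lengths, stringsAsFactors = FALSE)
}

seq_diff_oracle <- function(R, Q) {
  none <- data.frame(type = character(), length = integer(),
                     stringsAsFactors = FALSE)
  if (identical(R, Q)) return(none)
  rch <- chars(R); qch <- chars(Q)
  p <- lcp_len(rch, qch)
  rrem <- rch[seq_len(length(rch) - p) + p]
  qrem <- qch[seq_len(length(qch) - p) + p]
  s <- lcs_len(rrem, qrem)
  RM <- rrem[seq_len(length(rrem) - s)]
  QM <- qrem[seq_len(length(qrem) - s)]
  pre <- rch[seq_len(p)]
  o_q <- if (length(QM)) lcs_len(QM, pre) else 0L
  o_r <- if (length(RM)) lcs_len(RM, pre) else 0L
  row <- function(type, len) data.frame(type = type, length = len,
                                        stringsAsFactors = FALSE)
  if (!length(RM) && !length(QM)) return(none)
  if (!length(RM)) {
    qm <- paste(QM, collapse = "")
    if (o_q == length(QM)) return(row("tandem_duplication", o_q))
    if (o_q > 0L) {
      return(rbind(row("duplication", o_q),
                   ins_family_oracle(substr(qm, 1L, length(QM) - o_q))))
    }
    return(ins_family_oracle(qm))
  }
  if (!length(QM)) {
    if (o_r == length(RM)) return(row("collapsed_tandem_repeat", o_r))
    if (o_r > 0L) return(row("collapsed_repeat", length(RM)))
    return(row("simple_deletion", length(RM)))
  }
  if (o_q > 0L) {
    qm <- paste(QM, collapse = "")
    return(rbind(row("duplication", o_q),
                 ins_family_oracle(substr(qm, 1L, length(QM) - o_q))))
  }
  if (length(RM) == length(QM)) {
    return(row(if (all(QM == "N")) "gap" else "substitution", length(RM)))
  }
  if (all(QM == "N") && all(RM != "N")) {
    m <- min(length(RM), length(QM))
    extra <- if (length(QM) > length(RM)) {
      row("inserted_gap", length(QM) - m)
    } else {
      row("simple_deletion", length(RM) - m)
    }
    return(rbind(row("gap", m), extra))
  }
  rbind(row("simple_deletion", length(RM)),
        ins_family_oracle(paste(QM, collapse = "")))
}

# --- placement-case generator --------------------------------------------

pair_case_cells <- function() {
  c("insertion", "insertion_n", "insertion_mixed", "deletion",
    "substitution", "gap_equal", "gap_enlarged", "gap_shrunk",
    "indel", "tandem_duplication", "duplication",
    "collapsed_tandem_repeat", "collapsed_repeat", "double_overlap_q",
    "double_overlap_r", "none")
}

# replace character at 0-based i so it differs from `avoid`
force_diff <- function(s, i, avoid) {
  if (substr(s, i + 1L, i + 1L) %in% avoid) {
    substr(s, i + 1L, i + 1L) <-
      sample(setdiff(c("A", "C", "G", "T"), avoid), 1L)
  }
  s
}

# Build (R, Q, a, b): two fragments a (query-first) and b over sequences
# R (reference) and Q (query) realizing one cell of the case table.
# When rev = TRUE the pair is represented on the reverse strand (Q is
# reverse-complemented and fragment coordinates reflected).
make_pair_case <- function(cell, rev = FALSE) {
  ra <- 80L + sample.int(60L, 1L)
  rb <- 80L + sample.int(60L, 1L)
  g <- 5L + sample.int(40L, 1L)    # query-side gap / overlap size
  h <- 5L + sample.int(40L, 1L)    # ref-side gap / overlap size
  A <- rand_dna(ra); B <- rand_dna(rb)
  QM <- ""; RM <- ""
  qb_off <- 0L; rb_off <- 0L       # b start offsets relative to ra
  if (cell %in% c("insertion", "insertion_n", "insertion_mixed")) {
    QM <- switch(cell,
                 insertion = rand_dna(g),
                 insertion_n = strrep("N", g),
                 insertion_mixed = paste0(rand_dna(g), strrep("N", h)))
    if (cell != "insertion_n") {
      QM <- force_diff(QM, 0L, substr(B, 1L, 1L))
    }
    last <- nchar(QM) - 1L
    if (substr(QM, last + 1L, last + 1L) != "N") {
      QM <- force_diff(QM, last, substr(A, ra, ra))
    }
    qb_off <- nchar(QM)
  } else if (cell == "deletion") {
    RM <- rand_dna(h)
    RM <- force_diff(RM, 0L, substr(B, 1L, 1L))
    RM <- force_diff(RM, h - 1L, substr(A, ra, ra))
    rb_off <- h
  } else if (cell %in% c("substitution", "gap_equal", "gap_enlarged",
                         "gap_shrunk", "indel")) {
    rl <- h
    ql <- switch(cell, substitution = h, gap_equal = h,
                 gap_enlarged = h + g, gap_shrunk = max(1L, h - g),
                 indel = h + g)
    if (cell == "gap_shrunk" && ql >= rl) ql <- rl - 1L
    RM <- rand_dna(rl)
    RM <- force_diff(RM, 0L, substr(B, 1L, 1L))
    RM <- force_diff(RM, rl - 1L, substr(A, ra, ra))
    if (cell == "substitution") {
      QM <- paste(vapply(chars(RM), function(x) {
        sample(setdiff(c("A", "C", "G", "T"), x), 1L)
      }, character(1)), collapse = "")
      QM <- force_diff(QM, 0L, c(substr(B, 1L, 1L), substr(RM, 1L, 1L)))
      QM <- force_diff(QM, ql - 1L,
                       c(substr(A, ra, ra), substr(RM, rl, rl)))
    } else if (cell == "indel") {
      QM <- rand_dna(ql)
      QM <- force_diff(QM, 0L, c(substr(B, 1L, 1L), substr(RM, 1L, 1L)))
      QM <- force_diff(QM, ql - 1L,
                       c(substr(A, ra, ra), substr(RM, rl, rl)))
    } else {
      QM <- strrep("N", ql)
    }
    qb_off <- ql; rb_off <- rl
  } else if (cell == "tandem_duplication") {
    A <- force_diff(A, ra - g - 1L, substr(A, ra, ra))  # cap repeat at g
    X <- substr(A, ra - g + 1L, ra)
    QM <- X
    B <- force_diff(B, 0L, substr(X, 1L, 1L))
    qb_off <- 0L; rb_off <- -g
  } else if (cell == "duplication") {
    A <- force_diff(A, ra - h - 1L, substr(A, ra, ra))  # cap repeat at h
    X <- substr(A, ra - h + 1L, ra)
    B <- force_diff(B, 0L, substr(X, 1L, 1L))
    G <- rand_dna(g)
    G <- force_diff(G, 0L, substr(B, 1L, 1L))
    G <- force_diff(G, g - 1L, substr(A, ra - h, ra - h))
    QM <- paste0(G, X)
    qb_off <- g; rb_off <- -h
  } else if (cell == "collapsed_tandem_repeat") {
    A <- force_diff(A, ra - g - 1L, substr(A, ra, ra))
    X <- substr(A, ra - g + 1L, ra)
    RM <- X
    B <- force_diff(B, 0L, substr(X, 1L, 1L))
    qb_off <- -g; rb_off <- 0L
  } else if (cell == "collapsed_repeat") {
    A <- force_diff(A, ra - g - 1L, substr(A, ra, ra))
    X <- substr(A, ra - g + 1L, ra)
    B <- force_diff(B, 0L, substr(X, 1L, 1L))
    S <- rand_dna(h)
    S <- force_diff(S, 0L, substr(B, 1L, 1L))
    S <- force_diff(S, h - 1L, substr(A, ra - g, ra - g))
    RM <- paste0(S, X)
    qb_off <- -g; rb_off <- h
  } else if (cell %in% c("double_overlap_q", "double_overlap_r")) {
    # a periodic tail of period p on A; one side carries one extra
    # period, and the fragment pair overlaps on both coordinates (the
    # side with the extra period overlapping by p more than the other)
    p <- 4L + sample.int(12L, 1L)
    reps <- 3L
    U <- rand_dna(p)
    A <- paste0(rand_dna(ra - p * reps), strrep(U, reps))
    A <- force_diff(A, ra - p * reps - 1L, substr(U, p, p))
    B <- force_diff(B, 0L, substr(U, 1L, 1L))
    o_small <- sample.int(p * (reps - 1L), 1L)
    if (cell == "double_overlap_q") {
      QM <- U
      qb_off <- -o_small
      rb_off <- -o_small - p
    } else {
      RM <- U
      qb_off <- -o_small - p
      rb_off <- -o_small
    }
  } else if (cell == "none") {
    # spurious split: identical continuation
  } else stop("unknown cell: ", cell)

  R <- paste0(A, RM, B)
  Q <- paste0(A, QM, B)
  lenR <- nchar(R); lenQ <- nchar(Q)
  a <- list(qs = 0L, qe = ra, rs = 0L, re = ra)
  b <- list(qs = ra + qb_off, qe = lenQ, rs = ra + rb_off, re = lenR)
  if (rev) {
    Qr <- rc(Q)
    ar <- list(qs = lenQ - b$qe, qe = lenQ - b$qs, rs = b$rs, re = b$re)
    br <- list(qs = lenQ - a$qe, qe = lenQ - a$qs, rs = a$rs, re = a$re)
    a <- ar; b <- br; Q_out <- Qr; strand <- "-"
  } else {
    Q_out <- Q; strand <- "+"
  }
  frag <- function(x, id) data.frame(
    frag_id = id, query_id = "q", query_start = x$qs, query_end = x$qe,
    ref_id = "r", ref_start = x$rs, ref_end = x$re, strand = strand,
    identity = 100, stringsAsFactors = FALSE)
  list(R = R, Q = Q, query = sequence_set(c(q = Q_out), "query"),
       a = frag(a, 1L), b = frag(b, 2L), cell = cell)
}

# --- anchor oracle --------------------------------------------------------

brute_anchors_one <- function(rs, qs, k) {
  eq <- outer(qs, rs, "==")
  idx <- which(eq, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(ref_pos = integer(), query_pos = integer(),
                      length = integer()))
  }
  d <- idx[, 1L] - idx[, 2L]
  o <- order(d, idx[, 1L])
  qp <- idx[o, 1L]; rp <- idx[o, 2L]; dd <- d[o]
  n <- length(qp)
  new_run <- if (n > 1L) {
    c(TRUE, dd[-1L] != dd[-n] | diff(qp) != 1L)
  } else TRUE
  starts <- which(new_run)
  lens <- diff(c(starts, n + 1L))
  out <- data.frame(ref_pos = rp[starts] - 1L, query_pos = qp[starts] - 1L,
                    length = lens)
  out[out$length >= k, , drop = FALSE]
}

brute_anchors <- function(ref_seq, query_seq, k) {
  rs <- chars(ref_seq)
  fwd <- brute_anchors_one(rs, chars(query_seq), k)
  if (nrow(fwd)) fwd$strand <- "+" else fwd$strand <- character(0)
  rcq <- rc(query_seq)
  rev <- brute_anchors_one(rs, chars(rcq), k)
  L <- nchar(query_seq)
  if (nrow(rev)) {
    rev$query_pos <- L - (rev$query_pos + rev$length)
    rev$strand <- "-"
  } else rev$strand <- character(0)
  out <- rbind(fwd, rev)
  out[order(out$strand, out$query_pos, out$ref_pos), , drop = FALSE]
}

# --- truth projection checks ---------------------------------------------

# verify that every truth row is consistent with the emitted query:
# copied content matches, inverted content reverse-complements, deletion
# junction flanks agree, N runs are N
verify_truth_projection <- function(ref, query, truth, w = 20L) {
  sub0 <- function(s, i, j) substr(s, i + 1L, j)
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    q <- query[[tr$query_id]]
    qpart <- sub0(q, tr$query_start, tr$query_end)
    ok <- switch(tr$diff_type,
      substitution = {
        r <- sub0(ref[[tr$ref_id]], tr$ref_start, tr$ref_end)
        nchar(qpart) == nchar(r) && all(chars(qpart) != chars(r))
      },
      gap = grepl("^N+$", qpart) &&
        (tr$ref_end - tr$ref_start) == tr$length,
      inserted_gap = grepl("^N*$", qpart) &&
        nchar(qpart) == tr$length,
      simple_insertion = nchar(qpart) == tr$length,
      unaligned_beginning = tr$query_start == 0L,
      unaligned_end = nchar(q) == tr$query_end,
      unaligned_sequence = is.na(tr$ref_id) && nchar(q) == tr$length,
      simple_deletion = ,
      collapsed_tandem_repeat = ,
      collapsed_repeat = {
        r <- ref[[tr$ref_id]]
        sub0(q, tr$query_start - w, tr$query_start) ==
          sub0(r, tr$ref_start - w, tr$ref_start) &&
          sub0(q, tr$query_start, tr$query_start + w) ==
            sub0(r, tr$ref_end, tr$ref_end + w)
      },
      tandem_duplication = ,
      duplication = ,
      reshuffling = qpart == sub0(ref[[tr$ref_id]], tr$ref_start,
                                  tr$ref_end),
      inversion = qpart == rc(sub0(ref[[tr$ref_id]], tr$ref_start,
                                   tr$ref_end)),
      translocation = ,
      relocation = {
        off <- if (identical(tr$subtype, "with_overlap")) tr$length else 0L
        sub0(q, tr$query_end, tr$query_end + w) ==
          sub0(ref[[tr$ref_id]], tr$ref_start + off,
               tr$ref_start + off + w)
      },
      circular_genome_start = TRUE,
      TRUE)
    if (!isTRUE(ok)) {
      return(structure(FALSE, row = i, type = tr$diff_type))
    }
  }
  TRUE
}

# sort a type/length multiset for comparison
norm_multiset <- function(df) {
  df <- df[order(df$type, df$length), , drop = FALSE]
  rownames(df) <- NULL
  df
}

diffs_to_multiset <- function(d) {
  norm_multiset(data.frame(type = d$diff_type, length = d$length,
                           stringsAsFactors = FALSE))
}
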