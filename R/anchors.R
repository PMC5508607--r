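# Anchor discovery: maximal exact matches via k-mer seeding.
#
# A maximal exact match of length L >= k contains exactly L - k + 1
# consecutive k-mer hits on one diagonal, and conversely a maximal run of
# consecutive same-diagonal k-mer hits corresponds to one maximal exact
# match (extending the run by one base would extend the k-mer run).  So
# anchors are recovered exactly by joining the k-mer tables of the two
# sets and run-length encoding the hits per diagonal.  N is treated as a
# literal residue, so shared N runs match while N never matches A/C/G/T.

kmer_table <- function(seqs, k) {
  ids <- character(0); pos <- integer(0); kmer <- character(0)
  id_codes <- integer(0)
  code <- 0L
  for (id in names(seqs)) {
    s <- seqs[[id]]
    n <- nchar(s) - k + 1L
    if (n < 1L) next
    code <- code + 1L
    ids <- c(ids, id)
    pos <- c(pos, 0:(n - 1L))
    id_codes <- c(id_codes, rep.int(code, n))
    kmer <- c(kmer, substring(s, 1:n, k:(n + k - 1L)))
  }
  list(ids = ids, id_code = id_codes, pos = pos, kmer = kmer)
}

# hits between a reference k-mer table and a query k-mer table, collapsed
# into maximal exact matches; positions refer to the frames the tables
# were built in.  The join uses a hash match for the (dominant) unique
# reference k-mers plus a small explicit join for duplicated ones.
anchor_scan <- function(ref_kt, query_kt, k) {
  empty <- data.frame(ref_id = character(), ref_pos = integer(),
                      query_id = character(), query_pos = integer(),
                      length = integer(), stringsAsFactors = FALSE)
  if (!length(ref_kt$kmer) || !length(query_kt$kmer)) return(empty)
  m <- match(query_kt$kmer, ref_kt$kmer)
  qi <- which(!is.na(m))
  dup <- duplicated(ref_kt$kmer)
  if (any(dup)) {
    dup_kmers <- unique(ref_kt$kmer[dup])
    q_isdup <- query_kt$kmer[qi] %in% dup_kmers
    h_q <- qi[!q_isdup]
    h_r <- m[h_q]
    q_extra <- qi[q_isdup]
    if (length(q_extra)) {
      # explicit small cross-join for k-mers repeated in the reference
      r_extra <- which(ref_kt$kmer %in% dup_kmers)
      rsplit <- split(r_extra, ref_kt$kmer[r_extra])
      hl <- rsplit[query_kt$kmer[q_extra]]
      lens <- lengths(hl)
      h_q <- c(h_q, rep.int(q_extra, lens))
      h_r <- c(h_r, unlist(hl, use.names = FALSE))
    }
  } else {
    h_q <- qi
    h_r <- m[qi]
  }
  if (!length(h_q)) return(empty)
  q_id <- query_kt$id_code[h_q]
  r_id <- ref_kt$id_code[h_r]
  q_pos <- query_kt$pos[h_q]
  r_pos <- ref_kt$pos[h_r]
  diag_off <- q_pos - r_pos
  o <- order(r_id, q_id, diag_off, q_pos, method = "radix")
  q_id <- q_id[o]; r_id <- r_id[o]; q_pos <- q_pos[o]; r_pos <- r_pos[o]
  diag_off <- diag_off[o]
  n <- length(q_pos)
  new_run <- if (n > 1L) {
    c(TRUE, r_id[-1L] != r_id[-n] | q_id[-1L] != q_id[-n] |
        diag_off[-1L] != diag_off[-n] | diff(q_pos) != 1L)
  } else TRUE
  starts <- which(new_run)
  lens <- diff(c(starts, n + 1L))
  data.frame(ref_id = ref_kt$ids[r_id[starts]],
             ref_pos = r_pos[starts],
             query_id = query_kt$ids[q_id[starts]],
             query_pos = q_pos[starts],
             length = lens + k - 1L, stringsAsFactors = FALSE)
}

#' Find maximal exact matches between two sequence sets
#'
#' Reports every maximal exact match of length at least `min_match_len`
#' between any query sequence (both strands) and any reference sequence.
#' Maximality means extension by one base in either direction breaks the
#' match.  For reverse-strand anchors `query_pos` refers to the leftmost
#' matching base in the original (forward) query coordinates.
#'
#' @param ref,query [sequence_set()] objects (or named character vectors).
#' @param min_match_len minimum match length, at least 8.
#' @return a `data.frame` with columns `ref_id`, `ref_pos`, `query_id`,
#'   `query_pos`, `length`, `strand` (0-based positions).
#' @export
find_anchors <- function(ref, query, min_match_len = 20L) {
  k <- as.integer(min_match_len)
  if (k < 8L) stop("min_match_len must be at least 8")
  ref <- as_sequence_set(ref, "reference")
  query <- as_sequence_set(query, "query")
  ref_kt <- kmer_table(ref, k)

  fwd <- anchor_scan(ref_kt, kmer_table(query, k), k)
  if (nrow(fwd)) fwd$strand <- "+"

  rc <- stats::setNames(vapply(unclass(query), revcomp, character(1)),
                        names(query))
  rev <- anchor_scan(ref_kt, kmer_table(rc, k), k)
  if (nrow(rev)) {
    qlen <- seq_lengths(query)
    rev$query_pos <- unname(qlen[rev$query_id]) - (rev$query_pos + rev$length)
    rev$strand <- "-"
  }
  out <- rbind(
    if (nrow(fwd)) fwd,
    if (nrow(rev)) rev)
  if (is.null(out)) {
    out <- data.frame(ref_id = character(), ref_pos = integer(),
                      query_id = character(), query_pos = integer(),
                      length = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  }
  out[order(out$query_id, out$strand, out$query_pos, out$ref_id,
            out$ref_pos), , drop = FALSE]
}
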