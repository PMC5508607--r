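# Chaining anchors into fragments, filling inter-anchor gaps with a small
# unit-cost alignment, and per-query consistent-chain (LIS) filtering.

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

# unit-cost edit script between two short character vectors.
# Ties prefer substitution over indel; remaining indel-placement ties are
# resolved leftmost (traceback consumes matches first from the right).
# Returns a matrix with columns op (0 sub, 1 ins, 2 del), i (ref chars
# consumed), j (query chars consumed).
edit_script <- function(rs, qs) {
  n <- length(rs); m <- length(qs)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1L] <- 0:n
  D[1L, ] <- 0:m
  jj <- 0:m
  row_prev <- D[1L, ]
  for (i in seq_len(n)) {
    mis <- as.integer(rs[i] != qs)
    cand <- pmin(row_prev[1:m] + mis, row_prev[2:(m + 1L)] + 1L)
    vals <- c(i, cand)
    cur <- cummin(vals - jj) + jj
    D[i + 1L, ] <- cur
    row_prev <- cur
  }
  ops <- matrix(0L, 0L, 3L)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        D[i + 1L, j + 1L] == D[i, j] + (rs[i] != qs[j])) {
      if (rs[i] != qs[j]) ops <- rbind(c(0L, i, j), ops)
      i <- i - 1L; j <- j - 1L
    } else if (j > 0L && D[i + 1L, j + 1L] == D[i + 1L, j] + 1L) {
      ops <- rbind(c(1L, i, j), ops)
      j <- j - 1L
    } else {
      ops <- rbind(c(2L, i, j), ops)
      i <- i - 1L
    }
  }
  colnames(ops) <- c("op", "i", "j")
  ops
}

# snp records for the region between two chained anchors.
# rseq/qseq are the in-frame chunks; ref_off/query_off their 0-based
# frame offsets.  Equal-length chunks are compared positionwise
# (substitutions only); pure one-sided chunks become plain indel runs;
# the general case runs the unit-cost alignment.
fill_gap <- function(rseq, qseq, ref_off, query_off) {
  rl <- nchar(rseq); ql <- nchar(qseq)
  if (rl == 0L && ql == 0L) return(NULL)
  if (rl == 0L) {
    qs <- strsplit(qseq, "", fixed = TRUE)[[1]]
    return(snp_records(frag_id = rep(NA_integer_, ql), kind = "insertion",
                       ref_pos = rep(ref_off, ql),
                       query_pos = query_off + seq_len(ql) - 1L,
                       ref_base = ".", query_base = qs))
  }
  if (ql == 0L) {
    rs <- strsplit(rseq, "", fixed = TRUE)[[1]]
    return(snp_records(frag_id = rep(NA_integer_, rl), kind = "deletion",
                       ref_pos = ref_off + seq_len(rl) - 1L,
                       query_pos = rep(query_off, rl),
                       ref_base = rs, query_base = "."))
  }
  rs <- strsplit(rseq, "", fixed = TRUE)[[1]]
  qs <- strsplit(qseq, "", fixed = TRUE)[[1]]
  if (rl == ql) {
    mis <- which(rs != qs)
    if (!length(mis)) return(NULL)
    return(snp_records(frag_id = rep(NA_integer_, length(mis)),
                       kind = "substitution",
                       ref_pos = ref_off + mis - 1L,
                       query_pos = query_off + mis - 1L,
                       ref_base = rs[mis], query_base = qs[mis]))
  }
  ops <- edit_script(rs, qs)
  if (!nrow(ops)) return(NULL)
  kind <- c("substitution", "insertion", "deletion")[ops[, "op"] + 1L]
  ref_pos <- ifelse(ops[, "op"] == 1L, ref_off + ops[, "i"],
                    ref_off + ops[, "i"] - 1L)
  query_pos <- ifelse(ops[, "op"] == 2L, query_off + ops[, "j"],
                      query_off + ops[, "j"] - 1L)
  ref_base <- ifelse(ops[, "op"] == 1L, ".", rs[pmax(ops[, "i"], 1L)])
  query_base <- ifelse(ops[, "op"] == 2L, ".", qs[pmax(ops[, "j"], 1L)])
  snp_records(frag_id = rep(NA_integer_, nrow(ops)), kind = kind,
              ref_pos = ref_pos, query_pos = query_pos,
              ref_base = ref_base, query_base = query_base)
}

# greedy co-linear chaining of in-frame anchors (columns fq, ref_pos,
# length, ref_id).  Small overlaps between consecutive anchors (shorter
# than the seed length, typically junction homology) are trimmed from the
# incoming anchor; larger overlaps start a new chain so repeat-induced
# placements stay separate fragments.
chain_anchors <- function(sub, config) {
  ext <- config$extension_distance
  k <- config$min_match_len
  chains <- list()
  for (idx in seq_len(nrow(sub))) {
    a <- sub[idx, ]
    best <- 0L; best_cost <- Inf; best_trim <- 0L
    for (ci in seq_along(chains)) {
      ch <- chains[[ci]]
      if (!identical(ch$ref_id, a$ref_id)) next
      qgap <- a$fq - ch$qend
      rgap <- a$ref_pos - ch$rend
      t <- max(0L, -qgap, -rgap)
      if (t >= a$length || t >= k) next
      qg <- qgap + t; rg <- rgap + t
      if (qg < 0L || rg < 0L || qg > ext || rg > ext) next
      if (qg + rg < best_cost) {
        best_cost <- qg + rg; best <- ci; best_trim <- t
      }
    }
    row <- data.frame(fq = a$fq + best_trim, rpos = a$ref_pos + best_trim,
                      len = a$length - best_trim)
    if (best > 0L) {
      ch <- chains[[best]]
      ch$rows[[length(ch$rows) + 1L]] <- row
      ch$qend <- row$fq + row$len
      ch$rend <- row$rpos + row$len
      ch$n <- ch$n + 1L
      chains[[best]] <- ch
    } else {
      chains[[length(chains) + 1L]] <- list(
        ref_id = a$ref_id, rows = list(row),
        qend = row$fq + row$len, rend = row$rpos + row$len, n = 1L)
    }
  }
  chains
}

#' Chain anchors into aligned fragments
#'
#' Clusters co-linear anchors whose separation on both coordinates is at
#' most `extension_distance` into fragments, filling the gaps between
#' chained anchors with a unit-cost alignment that yields per-base SNP
#' records.  Local differences longer than `extension_distance`, and any
#' structural rearrangement, break the chain so the alignment splits into
#' separate fragments.  Lone anchors shorter than `min_cluster_len` are
#' dropped as chance matches.
#'
#' @param anchors anchor table from [find_anchors()].
#' @param ref,query [sequence_set()] objects.
#' @param config an [diff_config()].
#' @return list with elements `fragments` and `snps`.
#' @export
cluster_and_extend <- function(anchors, ref, query, config = diff_config()) {
  ref <- as_sequence_set(ref, "reference")
  query <- as_sequence_set(query, "query")
  anchors <- as.data.frame(anchors)
  qlen <- seq_lengths(query)
  frag_rows <- list(); snp_rows <- list()
  next_id <- 1L
  for (qid in unique(anchors$query_id)) {
    for (st in c("+", "-")) {
      sub <- anchors[anchors$query_id == qid & anchors$strand == st, ,
                     drop = FALSE]
      if (!nrow(sub)) next
      L <- qlen[[qid]]
      if (st == "-") {
        qframe <- revcomp(query[[qid]])
        sub$fq <- L - (sub$query_pos + sub$length)
      } else {
        qframe <- query[[qid]]
        sub$fq <- sub$query_pos
      }
      sub <- sub[order(sub$fq, sub$ref_pos), , drop = FALSE]
      chains <- chain_anchors(sub, config)
      for (ch in chains) {
        rows <- do.call(rbind, ch$rows)
        span <- (rows$fq[nrow(rows)] + rows$len[nrow(rows)]) - rows$fq[1L]
        if (ch$n == 1L && span < config$min_cluster_len) next
        rseq <- ref[[ch$ref_id]]
        snps <- list()
        if (nrow(rows) > 1L) {
          for (i in seq_len(nrow(rows) - 1L)) {
            pe_q <- rows$fq[i] + rows$len[i]
            pe_r <- rows$rpos[i] + rows$len[i]
            snps[[i]] <- fill_gap(
              substr0(rseq, pe_r, rows$rpos[i + 1L]),
              substr0(qframe, pe_q, rows$fq[i + 1L]),
              pe_r, pe_q)
          }
        }
        snps <- Filter(Negate(is.null), snps)
        snps <- if (length(snps)) {
          as.data.frame(data.table::rbindlist(snps))
        } else snp_records()
        qs_f <- rows$fq[1L]
        qe_f <- rows$fq[nrow(rows)] + rows$len[nrow(rows)]
        rs <- rows$rpos[1L]
        re <- rows$rpos[nrow(rows)] + rows$len[nrow(rows)]
        if (st == "-") {
          q_start <- L - qe_f; q_end <- L - qs_f
          if (nrow(snps)) {
            is_base <- snps$kind != "deletion"
            snps$query_pos <- ifelse(is_base, L - 1L - snps$query_pos,
                                     L - snps$query_pos)
            snps$query_base <- ifelse(snps$query_base == ".", ".",
                                      comp_base(snps$query_base))
          }
        } else {
          q_start <- qs_f; q_end <- qe_f
        }
        edits <- nrow(snps)
        aln <- max(q_end - q_start, re - rs)
        ident <- 100 * (1 - edits / aln)
        if (nrow(snps)) snps$frag_id <- next_id
        frag_rows[[length(frag_rows) + 1L]] <- data.frame(
          frag_id = next_id, query_id = qid,
          query_start = q_start, query_end = q_end,
          ref_id = ch$ref_id, ref_start = rs, ref_end = re,
          strand = st, identity = ident, stringsAsFactors = FALSE)
        snp_rows[[length(snp_rows) + 1L]] <- snps
        next_id <- next_id + 1L
      }
    }
  }
  frags <- if (length(frag_rows)) {
    as.data.frame(data.table::rbindlist(frag_rows))
  } else empty_fragments()
  snps <- Filter(function(s) nrow(s) > 0, snp_rows)
  snps <- if (length(snps)) {
    as.data.frame(data.table::rbindlist(snps))
  } else snp_records()
  list(fragments = frags, snps = snps)
}

#' Keep the heaviest consistent fragment chain per query sequence
#'
#' Per query sequence, retains the chain of fragments maximizing the sum
#' of fragment length times percent identity over fragments whose query
#' intervals advance strictly (both starts and ends increasing) and
#' overlap at most half of the shorter fragment.  This emulates
#' query-side consistent-alignment filtering: alternative placements of
#' the same query region compete and the lighter one is dropped, while
#' partially overlapping fragments at repeat-mediated junctions survive
#' for structural typing.  Reference-side placement is unconstrained, so
#' rearranged fragments pass through.  Ties take the chain starting
#' earlier on the query.  Dropped fragments are kept in the `"dropped"`
#' attribute for diagnostics.
#'
#' @param frags fragment table.
#' @param config an [diff_config()].
#' @return the retained fragments, with attribute `dropped`.
#' @export
filter_query_lis <- function(frags, config = diff_config()) {
  if (!nrow(frags)) return(frags)
  keep <- logical(nrow(frags))
  for (qid in unique(frags$query_id)) {
    idx <- which(frags$query_id == qid)
    f <- frags[idx, , drop = FALSE]
    o <- order(f$query_start, f$query_end)
    f <- f[o, , drop = FALSE]; idx <- idx[o]
    n <- nrow(f)
    len <- f$query_end - f$query_start
    w <- len * pmax(f$identity, 1e-9)
    best <- w; prev <- integer(n)
    if (n > 1L) {
      for (i in 2:n) {
        for (j in seq_len(i - 1L)) {
          if (f$query_start[j] < f$query_start[i] &&
              f$query_end[j] < f$query_end[i] &&
              (f$query_end[j] - f$query_start[i]) <=
                0.5 * min(len[i], len[j])) {
            cand <- best[j] + w[i]
            if (cand > best[i] + 1e-9) {
              best[i] <- cand; prev[i] <- j
            }
          }
        }
      }
    }
    cur <- which.max(best)
    while (cur != 0L) {
      keep[idx[cur]] <- TRUE
      cur <- prev[cur]
    }
  }
  out <- frags[keep, , drop = FALSE]
  attr(out, "dropped") <- frags[!keep, , drop = FALSE]
  out
}

#' Align two sequence sets with the built-in anchor aligner
#'
#' Runs anchor discovery, chaining/extension, the identity filter and the
#' per-query consistent-chain filter, yielding fragments and SNP records
#' ready for classification.
#'
#' @param ref,query [sequence_set()] objects or named character vectors.
#' @param config an [diff_config()].
#' @return list with `fragments`, `snps` and `dropped` (fragments removed
#'   by filtering).
#' @export
align_genomes <- function(ref, query, config = diff_config()) {
  ref <- as_sequence_set(ref, "reference")
  query <- as_sequence_set(query, "query")
  anchors <- find_anchors(ref, query, config$min_match_len)
  al <- cluster_and_extend(anchors, ref, query, config)
  frags <- al$fragments
  ident_drop <- frags[frags$identity < config$min_identity, , drop = FALSE]
  frags <- frags[frags$identity >= config$min_identity, , drop = FALSE]
  frags <- filter_query_lis(frags, config)
  dropped <- rbind(ident_drop, attr(frags, "dropped"))
  snps <- al$snps[al$snps$frag_id %in% frags$frag_id, , drop = FALSE]
  list(fragments = frags, snps = snps, dropped = dropped)
}
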