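# Stage 4: structural differences.  Pairs of neighbouring query fragments
# that survived merging are routed to exactly one structural category:
#
#   translocation  pair maps to different reference sequences
#   circular       rotated start of a circular genome (annotation only)
#   reshuffling    nearby reference regions emitted in a different order
#   relocation     same reference, separated by >= structural_distance
#   continuation   same mapped block (e.g. an inversion junction)
#
# Reference-side overlaps between fragments of one query are truncated
# (rightmost fragment in query order trimmed) before subtype detection,
# losing repeat identity by design; query-side overlaps are preserved for
# the with_overlap subtypes and only removed when mapped blocks are
# emitted.

#' Route neighbouring fragment pairs to structural categories
#'
#' Computes, for every neighbouring query-fragment pair left after
#' merging, which single structural category consumes it.  Reshuffling
#' groups are maximal query-consecutive runs of same-reference fragments
#' chained by reference adjacency (per-link distance at most
#' `structural_distance`) whose query order differs from their reference
#' order; members out of place are the reshuffled fragments.
#'
#' @param frags post-merge fragment table.
#' @param config an [diff_config()].
#' @param ref_len named reference lengths (needed for circular
#'   recognition; NULL disables it).
#' @return list with `pairs` (query_id, a_id, b_id, route), `groups`
#'   (reshuffling groups) and `circular` (recognized rotations).
#' @export
structural_routing <- function(frags, config = diff_config(), ref_len = NULL) {
  sd <- config$structural_distance
  pair_rows <- list(); groups <- list(); circ_rows <- list()
  for (qid in unique(frags$query_id)) {
    f <- frags[frags$query_id == qid, , drop = FALSE]
    f <- f[order(f$query_start, f$query_end), , drop = FALSE]
    n <- nrow(f)
    if (n < 2L) next
    route <- rep(NA_character_, n - 1L)
    if (config$circular && n == 2L && !is.null(ref_len) &&
        f$strand[1L] == f$strand[2L] && f$ref_id[1L] == f$ref_id[2L]) {
      tol <- config$extension_distance
      L <- ref_len[[f$ref_id[1L]]]
      qgap <- f$query_start[2L] - f$query_end[1L]
      if (f$ref_start[1L] > f$ref_start[2L] &&
          f$ref_start[2L] <= tol && f$ref_end[1L] >= L - tol &&
          abs(qgap) <= tol) {
        route[1L] <- "circular"
        circ_rows[[length(circ_rows) + 1L]] <- data.frame(
          query_id = qid, junction = f$query_end[1L],
          ref_id = f$ref_id[1L], ref_anchor = f$ref_start[2L],
          a_id = f$frag_id[1L], b_id = f$frag_id[2L],
          stringsAsFactors = FALSE)
      }
    }
    for (i in seq_len(n - 1L)) {
      if (is.na(route[i]) && f$ref_id[i] != f$ref_id[i + 1L]) {
        route[i] <- "translocation"
      }
    }
    # reshuffling groups within unrouted same-reference runs
    i <- 1L
    while (i <= n) {
      j <- i
      while (j < n && is.na(route[j]) && f$ref_id[j + 1L] == f$ref_id[i]) {
        j <- j + 1L
      }
      if (j > i) {
        run <- i:j
        ro <- run[order(f$ref_start[run], f$ref_end[run])]
        gaps <- f$ref_start[ro[-1L]] - f$ref_end[ro[-length(ro)]]
        comp_id <- cumsum(c(1L, as.integer(gaps > sd)))
        for (cid in unique(comp_id)) {
          mem <- sort(ro[comp_id == cid])
          sub_id <- cumsum(c(1L, as.integer(diff(mem) != 1L)))
          for (sid in unique(sub_id)) {
            mm <- mem[sub_id == sid]
            if (length(mm) < 2L) next
            rr <- rank(f$ref_start[mm], ties.method = "first")
            if (all(rr == seq_along(mm))) next
            groups[[length(groups) + 1L]] <- list(
              query_id = qid,
              members = f$frag_id[mm],
              reshuffled = f$frag_id[mm[rr != seq_along(mm)]])
            for (p in mm[-length(mm)]) {
              if (is.na(route[p])) route[p] <- "reshuffling"
            }
          }
        }
      }
      i <- j + 1L
    }
    for (i in seq_len(n - 1L)) {
      if (is.na(route[i]) && f$ref_id[i] == f$ref_id[i + 1L]) {
        sep <- max(0L, f$ref_start[i + 1L] - f$ref_end[i],
                   f$ref_start[i] - f$ref_end[i + 1L])
        if (sep >= sd) route[i] <- "relocation"
      }
    }
    route[is.na(route)] <- "continuation"
    pair_rows[[length(pair_rows) + 1L]] <- data.frame(
      query_id = qid, a_id = f$frag_id[-n], b_id = f$frag_id[-1L],
      route = route, stringsAsFactors = FALSE)
  }
  pairs <- if (length(pair_rows)) {
    as.data.frame(data.table::rbindlist(pair_rows))
  } else {
    data.frame(query_id = character(), a_id = integer(), b_id = integer(),
               route = character(), stringsAsFactors = FALSE)
  }
  circ <- if (length(circ_rows)) {
    as.data.frame(data.table::rbindlist(circ_rows))
  } else {
    data.frame(query_id = character(), junction = integer(),
               ref_id = character(), ref_anchor = integer(),
               a_id = integer(), b_id = integer(), stringsAsFactors = FALSE)
  }
  list(pairs = pairs, groups = groups, circular = circ)
}

# trim reference-interval overlaps between fragments of one query; the
# fragment later in query order loses the overlap on both coordinates
truncate_ref_overlaps <- function(frags) {
  drop <- logical(nrow(frags))
  for (qid in unique(frags$query_id)) {
    idx <- which(frags$query_id == qid)
    idx <- idx[order(frags$query_start[idx])]
    if (length(idx) < 2L) next
    for (u in seq_along(idx)[-length(idx)]) {
      for (v in seq(u + 1L, length(idx))) {
        i <- idx[u]; j <- idx[v]
        if (drop[i] || drop[j]) next
        if (frags$ref_id[i] != frags$ref_id[j]) next
        ov <- min(frags$ref_end[i], frags$ref_end[j]) -
          max(frags$ref_start[i], frags$ref_start[j])
        if (ov <= 0L) next
        if (ov >= frags$ref_end[j] - frags$ref_start[j]) {
          drop[j] <- TRUE
          next
        }
        if (frags$ref_start[j] >= frags$ref_start[i]) {
          # j overlaps i's right side: trim j's left edge
          frags$ref_start[j] <- frags$ref_start[j] + ov
          if (frags$strand[j] == "+") {
            frags$query_start[j] <- frags$query_start[j] + ov
          } else {
            frags$query_end[j] <- frags$query_end[j] - ov
          }
        } else {
          # j overlaps i's left side: trim j's right edge
          frags$ref_end[j] <- frags$ref_end[j] - ov
          if (frags$strand[j] == "+") {
            frags$query_end[j] <- frags$query_end[j] - ov
          } else {
            frags$query_start[j] <- frags$query_start[j] + ov
          }
        }
        if (frags$query_end[j] <= frags$query_start[j]) drop[j] <- TRUE
      }
    }
  }
  frags[!drop, , drop = FALSE]
}

# trim query-interval overlaps (rightmost fragment trimmed); used for
# mapped-block emission and inside reshuffling groups
truncate_query_overlaps <- function(frags) {
  drop <- logical(nrow(frags))
  for (qid in unique(frags$query_id)) {
    idx <- which(frags$query_id == qid)
    idx <- idx[order(frags$query_start[idx], frags$query_end[idx])]
    if (length(idx) < 2L) next
    for (v in seq_along(idx)[-1L]) {
      j <- idx[v]
      prev_end <- max(frags$query_end[idx[seq_len(v - 1L)][
        !drop[idx[seq_len(v - 1L)]]]], -Inf)
      if (frags$query_start[j] >= prev_end) next
      t <- as.integer(prev_end - frags$query_start[j])
      if (t >= frags$query_end[j] - frags$query_start[j]) {
        drop[j] <- TRUE
        next
      }
      frags$query_start[j] <- frags$query_start[j] + t
      if (frags$strand[j] == "+") {
        frags$ref_start[j] <- frags$ref_start[j] + t
      } else {
        frags$ref_end[j] <- frags$ref_end[j] - t
      }
    }
  }
  frags[!drop, , drop = FALSE]
}

# subtype + companion differences for translocation/relocation pairs
structural_pair_diffs <- function(f, pairs, query, kind) {
  if (!nrow(pairs)) return(empty_differences())
  rows <- list()
  for (r in seq_len(nrow(pairs))) {
    a <- f[f$frag_id == pairs$a_id[r], ]
    b <- f[f$frag_id == pairs$b_id[r], ]
    if (!nrow(a) || !nrow(b)) next
    qg <- b$query_start - a$query_end
    anchor <- if (b$strand == "+") b$ref_start else b$ref_end
    note <- paste0(kind, ":pair:", a$frag_id, "+", b$frag_id)
    if (qg == 0L) {
      subtype <- "simple"; qs <- a$query_end; qe <- a$query_end; ins <- ""
    } else if (qg < 0L) {
      subtype <- "with_overlap"; qs <- b$query_start; qe <- a$query_end
      ins <- ""
    } else {
      ins <- substr0(query[[a$query_id]], a$query_end, b$query_start)
      has_n <- grepl("N", ins, fixed = TRUE)
      has_base <- grepl("[ACGT]", ins)
      subtype <- if (has_n && has_base) "with_insertion_and_inserted_gap"
      else if (has_n) "with_inserted_gap" else "with_insertion"
      qs <- a$query_end; qe <- b$query_start
    }
    rows[[length(rows) + 1L]] <- diff_row(
      kind, a$query_id, qs, qe, b$ref_id, anchor, anchor, abs(qg),
      subtype = subtype, note = note)
    if (qg > 0L) {
      rows[[length(rows) + 1L]] <- insertion_family(
        ins, a$query_id, a$query_end, b$ref_id, anchor, note = note)
    }
  }
  bind_differences(rows)
}

# reshuffling groups: truncate query overlaps inside each group, emit one
# reshuffling difference per out-of-order member, then report unmapped
# query bases between neighbouring members as insertions and unmapped
# reference bases as deletions
process_reshufflings <- function(f, groups, query) {
  rows <- list()
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    note <- paste0("reshuffling:group:", gi)
    idx <- match(g$members, f$frag_id)
    idx <- idx[!is.na(idx)]
    if (length(idx) < 2L) next
    idx <- idx[order(f$query_start[idx])]
    for (v in seq_along(idx)[-1L]) {
      j <- idx[v]; i <- idx[v - 1L]
      ovl <- f$query_end[i] - f$query_start[j]
      if (ovl > 0L && ovl < f$query_end[j] - f$query_start[j]) {
        f$query_start[j] <- f$query_start[j] + ovl
        if (f$strand[j] == "+") f$ref_start[j] <- f$ref_start[j] + ovl
        else f$ref_end[j] <- f$ref_end[j] - ovl
      }
    }
    mem <- f[idx, , drop = FALSE]
    for (fid in intersect(g$reshuffled, mem$frag_id)) {
      fr <- mem[mem$frag_id == fid, ]
      rows[[length(rows) + 1L]] <- diff_row(
        "reshuffling", fr$query_id, fr$query_start, fr$query_end,
        fr$ref_id, fr$ref_start, fr$ref_end,
        fr$query_end - fr$query_start, note = note)
    }
    for (v in seq_len(nrow(mem) - 1L)) {
      qg <- mem$query_start[v + 1L] - mem$query_end[v]
      if (qg > 0L) {
        anchor <- if (mem$strand[v + 1L] == "+") mem$ref_start[v + 1L]
        else mem$ref_end[v + 1L]
        rows[[length(rows) + 1L]] <- insertion_family(
          substr0(query[[mem$query_id[v]]], mem$query_end[v],
                  mem$query_start[v + 1L]),
          mem$query_id[v], mem$query_end[v], mem$ref_id[v + 1L], anchor,
          note = note)
      }
    }
    ro <- order(mem$ref_start)
    for (v in seq_len(nrow(mem) - 1L)) {
      i <- ro[v]; j <- ro[v + 1L]
      rg <- mem$ref_start[j] - mem$ref_end[i]
      if (rg > 0L) {
        qanchor <- if (mem$strand[i] == "+") mem$query_end[i]
        else mem$query_start[i]
        rows[[length(rows) + 1L]] <- diff_row(
          "simple_deletion", mem$query_id[i], qanchor, qanchor,
          mem$ref_id[i], mem$ref_end[i], mem$ref_start[j], rg, note = note)
      }
    }
  }
  list(differences = bind_differences(rows), fragments = f)
}

#' Detect inversions
#'
#' A fragment whose direction is opposite to its reference fragment is an
#' inversion, unless every fragment of that query sequence is reversed —
#' then the query is simply the reverse complement of the reference and
#' no difference is reported.
#'
#' @param frags post-structural fragment table.
#' @return a difference table with one `inversion` per reversed fragment.
#' @export
detect_inversions <- function(frags) {
  rows <- list()
  for (qid in unique(frags$query_id)) {
    f <- frags[frags$query_id == qid, , drop = FALSE]
    nrev <- sum(f$strand == "-")
    if (nrev == 0L || nrev == nrow(f)) next
    for (i in which(f$strand == "-")) {
      fr <- f[i, ]
      rows[[length(rows) + 1L]] <- diff_row(
        "inversion", qid, fr$query_start, fr$query_end,
        fr$ref_id, fr$ref_start, fr$ref_end,
        fr$query_end - fr$query_start,
        note = paste0("frag:", fr$frag_id))
    }
  }
  bind_differences(rows)
}

#' Emit mapped blocks
#'
#' One block per surviving fragment, after truncating any residual
#' query-side overlaps (the fragment later in query order is trimmed), so
#' blocks on one query sequence never overlap on the query.  Blocks are
#' the maximal query regions mapped without structural interruption: the
#' query split at translocations, relocations, inversions and
#' reshufflings.
#'
#' @param frags post-structural fragment table.
#' @return a `data.frame` of blocks.
#' @export
emit_mapped_blocks <- function(frags) {
  f <- truncate_query_overlaps(frags)
  f <- f[order(f$query_id, f$query_start), , drop = FALSE]
  data.frame(
    block_id = seq_len(nrow(f)),
    query_id = f$query_id, query_start = f$query_start,
    query_end = f$query_end,
    ref_id = f$ref_id, ref_start = f$ref_start, ref_end = f$ref_end,
    strand = f$strand, stringsAsFactors = FALSE)
}

# full structural stage; returns differences, updated fragments, blocks
# and the pair routing table
structural_stage <- function(frags, query, ref = NULL,
                             config = diff_config()) {
  query <- as_sequence_set(query, "query")
  ref_len <- if (!is.null(ref)) seq_lengths(as_sequence_set(ref, "reference"))
  routing <- structural_routing(frags, config, ref_len)
  f <- truncate_ref_overlaps(frags)
  diffs <- list()
  if (nrow(routing$circular)) {
    for (r in seq_len(nrow(routing$circular))) {
      cr <- routing$circular[r, ]
      diffs[[length(diffs) + 1L]] <- diff_row(
        "circular_genome_start", cr$query_id, cr$junction, cr$junction,
        cr$ref_id, cr$ref_anchor, cr$ref_anchor, 0L,
        note = paste0("circular:pair:", cr$a_id, "+", cr$b_id))
    }
  }
  p <- routing$pairs
  diffs[[length(diffs) + 1L]] <-
    structural_pair_diffs(f, p[p$route == "translocation", , drop = FALSE],
                          query, "translocation")
  diffs[[length(diffs) + 1L]] <-
    structural_pair_diffs(f, p[p$route == "relocation", , drop = FALSE],
                          query, "relocation")
  rs <- process_reshufflings(f, routing$groups, query)
  f <- rs$fragments
  diffs[[length(diffs) + 1L]] <- rs$differences
  diffs[[length(diffs) + 1L]] <- detect_inversions(f)
  list(differences = bind_differences(diffs), fragments = f,
       blocks = emit_mapped_blocks(f), routing = routing$pairs,
       groups = routing$groups)
}

#' Detect translocations / relocations / circular starts / reshufflings
#'
#' Convenience wrappers running the full structural stage on a post-merge
#' fragment table and returning only the differences of one category
#' (including their companion insertion differences, identified by the
#' shared note).
#'
#' @param frags post-merge fragment table.
#' @param query the query [sequence_set()].
#' @param config an [diff_config()].
#' @param ref optional reference [sequence_set()] (required for circular
#'   recognition).
#' @return a difference table.
#' @export
detect_translocations <- function(frags, query, config = diff_config(),
                                  ref = NULL) {
  d <- structural_stage(frags, query, ref, config)$differences
  d[startsWith(d$note, "translocation:"), , drop = FALSE]
}

#' @rdname detect_translocations
#' @export
detect_relocations <- function(frags, query, config = diff_config(),
                               ref = NULL) {
  d <- structural_stage(frags, query, ref, config)$differences
  d[startsWith(d$note, "relocation:"), , drop = FALSE]
}

#' @rdname detect_translocations
#' @export
detect_circular_start <- function(frags, query, config = diff_config(),
                                  ref = NULL) {
  d <- structural_stage(frags, query, ref, config)$differences
  d[d$diff_type == "circular_genome_start", , drop = FALSE]
}

#' @rdname detect_translocations
#' @export
detect_reshufflings <- function(frags, query, config = diff_config(),
                                ref = NULL) {
  d <- structural_stage(frags, query, ref, config)$differences
  d[startsWith(d$note, "reshuffling:"), , drop = FALSE]
}
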