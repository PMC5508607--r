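# Stage 3: nested-fragment filtering, unaligned query ends, and the
# iterative merging of neighbouring fragment pairs whose separation is
# explained by a local (non-structural) difference.
#
# The placement-case table implemented by classify_pair, keyed by the
# signs of the query gap and the orientation-consistent reference gap:
#
#   (+, 0)  insertion family (simple_insertion / inserted_gap by N content)
#   (0, +)  simple_deletion
#   (0, -)  tandem_duplication        (extra copy adjacent on the query)
#   (+, -)  duplication + insertion family on the remainder
#   (-, 0)  collapsed_tandem_repeat
#   (-, +)  collapsed_repeat          (one interspersed copy + spacer lost)
#   (+, +)  substitution when gaps are equal (gap when the query side is
#           all N); unequal all-N gaps combine gap with inserted_gap or
#           simple_deletion; otherwise separate deletion + insertion
#   (-, -)  trim the smaller overlap from the right fragment, re-evaluate
#   (0, 0)  nothing (spurious split)
#
# Reversed pairs are classified after reflecting reference geometry
# (left/right ends chosen by orientation), so one code path serves both.

#' Filter nested fragments
#'
#' Discards any fragment whose query span is fully contained in another
#' fragment's query span on the same query sequence, or whose reference
#' span is fully contained in another same-query fragment's reference
#' span (a region duplicated in the query maps twice to one reference
#' region; the extra copy is the nested one).  Under mutual containment
#' the longer fragment is kept.  Discarded duplications and collapsed
#' repeats resurface as simple insertions/deletions at later stages.
#'
#' @param frags fragment table, any order.
#' @return list with `kept` and `discarded` fragment tables.
#' @export
filter_nested_fragments <- function(frags) {
  if (nrow(frags) < 2L) return(list(kept = frags, discarded = empty_fragments()))
  discard <- logical(nrow(frags))
  size <- (frags$query_end - frags$query_start) +
    (frags$ref_end - frags$ref_start)
  for (qid in unique(frags$query_id)) {
    idx <- which(frags$query_id == qid)
    if (length(idx) < 2L) next
    f <- frags[idx, , drop = FALSE]
    contained <- function(i, j) {
      (f$query_start[j] <= f$query_start[i] &&
         f$query_end[i] <= f$query_end[j]) ||
        (f$ref_id[i] == f$ref_id[j] &&
           f$ref_start[j] <= f$ref_start[i] &&
           f$ref_end[i] <= f$ref_end[j])
    }
    for (i in seq_along(idx)) {
      for (j in seq_along(idx)) {
        if (i == j) next
        if (!contained(i, j)) next
        mutual <- contained(j, i)
        si <- size[idx[i]]; sj <- size[idx[j]]
        if (!mutual || si < sj ||
            (si == sj && f$frag_id[i] > f$frag_id[j])) {
          discard[idx[i]] <- TRUE
        }
      }
    }
  }
  list(kept = frags[!discard, , drop = FALSE],
       discarded = frags[discard, , drop = FALSE])
}

#' Detect unaligned query ends
#'
#' Query bases before the first fragment of a sequence become an
#' `unaligned_beginning` difference, bases after the last fragment an
#' `unaligned_end`; the reference span is a zero-length anchor at the
#' flanking fragment's reference boundary.  Wholly unaligned sequences
#' are handled by [detect_unaligned_sequences()], not here.
#'
#' @param query a [sequence_set()].
#' @param frags fragment table.
#' @return a difference table.
#' @export
detect_unaligned_ends <- function(query, frags) {
  query <- as_sequence_set(query, "query")
  qlen <- seq_lengths(query)
  rows <- list()
  for (qid in intersect(names(query), unique(frags$query_id))) {
    f <- frags[frags$query_id == qid, , drop = FALSE]
    first <- f[which.min(f$query_start), ]
    if (first$query_start > 0L) {
      anchor <- if (first$strand == "+") first$ref_start else first$ref_end
      rows[[length(rows) + 1L]] <- diff_row(
        "unaligned_beginning", qid, 0L, first$query_start,
        first$ref_id, anchor, anchor, first$query_start,
        category = "struct", note = paste0("before frag:", first$frag_id))
    }
    last <- f[which.max(f$query_end), ]
    if (last$query_end < qlen[[qid]]) {
      anchor <- if (last$strand == "+") last$ref_end else last$ref_start
      rows[[length(rows) + 1L]] <- diff_row(
        "unaligned_end", qid, last$query_end, qlen[[qid]],
        last$ref_id, anchor, anchor, qlen[[qid]] - last$query_end,
        category = "struct", note = paste0("after frag:", last$frag_id))
    }
  }
  bind_differences(rows)
}

#' Can a neighbouring fragment pair be merged?
#'
#' True iff the pair's separation can be explained by a local difference:
#' both fragments map to the same reference sequence, share a direction
#' (possibly jointly opposite to the reference), their reference
#' fragments are placed in the order consistent with that direction
#' (query order for forward pairs, reverse order for reversed pairs),
#' and the reference gap does not exceed `max_merge_distance`.  The
#' query-side gap is unconstrained: overlapping, adjacent and
#' insert-separated pairs all qualify.
#'
#' The criteria also require the separating regions to be unmapped: a
#' reference gap covered by another fragment of the same query is not a
#' deletion but rearranged material (a reshuffling or relocation in the
#' making), so such pairs are left unmerged.  Pass the query's full
#' fragment table as `others` to enable that check.
#'
#' @param a,b one-row fragments, `a` preceding `b` on the query.
#' @param config an [diff_config()].
#' @param others optional fragment table of the same query used to test
#'   whether the reference gap region is mapped elsewhere.
#' @return logical flag.
#' @export
mergeable <- function(a, b, config = diff_config(), others = NULL) {
  g <- fragment_pair_geometry(a, b)
  ok <- isTRUE(g$same_ref && g$same_direction && g$ref_order_consistent &&
                 g$ref_gap <= config$max_merge_distance)
  if (ok && g$ref_gap > 0L && !is.null(others) && nrow(others)) {
    o <- others[others$frag_id != a$frag_id & others$frag_id != b$frag_id &
                  others$ref_id == a$ref_id, , drop = FALSE]
    if (nrow(o)) {
      covered <- pmin(o$ref_end, g$right_ref_start) -
        pmax(o$ref_start, g$left_ref_end)
      if (any(covered > 0L)) ok <- FALSE
    }
  }
  ok
}

# split an inserted query stretch into simple_insertion / inserted_gap
# runs by N content; ref side is a zero-length anchor
insertion_family <- function(seqstr, query_id, qstart, ref_id, ref_anchor,
                             category = "struct", note = "") {
  if (!nchar(seqstr)) return(NULL)
  chars <- strsplit(seqstr, "", fixed = TRUE)[[1]]
  r <- rle(chars == "N")
  off <- cumsum(c(0L, r$lengths))
  rows <- lapply(seq_along(r$lengths), function(i) {
    diff_row(if (r$values[i]) "inserted_gap" else "simple_insertion",
             query_id, qstart + off[i], qstart + off[i + 1L],
             ref_id, ref_anchor, ref_anchor, r$lengths[i],
             category = category, note = note)
  })
  bind_differences(rows)
}

#' Classify the difference between a mergeable fragment pair
#'
#' Applies the placement-case table (see the header of this file) to the
#' pair geometry and emits the implied differences with coordinates in
#' both systems.  Insertion-like differences carry their query span and a
#' zero-length reference anchor; deletion-like differences the converse.
#' The length of every emitted difference equals its owning span, so the
#' signed sum of emitted indel lengths accounts exactly for the
#' span-length change of the merged fragment.
#'
#' @param a,b one-row fragments satisfying [mergeable()].
#' @param query the query [sequence_set()] (for N-content of inserts).
#' @param config an [diff_config()].
#' @return a difference table (possibly empty).
#' @export
classify_pair <- function(a, b, query, config = diff_config()) {
  if (!mergeable(a, b, config)) {
    stop("classify_pair: fragment pair does not satisfy the merge criteria")
  }
  query <- as_sequence_set(query, "query")
  g <- fragment_pair_geometry(a, b, query)
  if (g$query_gap < 0 && g$ref_gap < 0) {
    # double overlap: trim the smaller overlap from the right fragment
    t <- min(-g$query_gap, -g$ref_gap)
    b <- as.list(b)
    b$query_start <- b$query_start + t
    if (g$reversed_pair) b$ref_end <- b$ref_end - t
    else b$ref_start <- b$ref_start + t
    g <- fragment_pair_geometry(a, as.data.frame(b), query)
  }
  qg <- g$query_gap; rg <- g$ref_gap
  qid <- g$a$query_id; rid <- g$a$ref_id
  jq0 <- g$a$query_end; jq1 <- g$b$query_start
  lre <- g$left_ref_end; rrs <- g$right_ref_start
  note <- paste0("pair:", g$a$frag_id, "+", g$b$frag_id)
  rows <- list()
  add <- function(d) rows[[length(rows) + 1L]] <<- d
  if (qg > 0 && rg == 0) {
    add(insertion_family(g$inserted_query_seq, qid, jq0, rid, lre,
                         note = note))
  } else if (qg == 0 && rg > 0) {
    add(diff_row("simple_deletion", qid, jq0, jq0, rid, lre, rrs, rg,
                 note = note))
  } else if (qg == 0 && rg < 0) {
    o <- -rg
    add(diff_row("tandem_duplication", qid, jq1, jq1 + o, rid, rrs, rrs + o,
                 o, note = note))
  } else if (qg < 0 && rg == 0) {
    o <- -qg
    add(diff_row("collapsed_tandem_repeat", qid, jq0, jq0, rid, lre, lre + o,
                 o, note = note))
  } else if (qg < 0 && rg > 0) {
    o <- -qg
    add(diff_row("collapsed_repeat", qid, jq0, jq0, rid, lre, rrs + o,
                 rg + o, note = paste0(note, ";repeat_unit=", o)))
  } else if (qg > 0 && rg < 0) {
    o <- -rg
    add(diff_row("duplication", qid, jq1, jq1 + o, rid, rrs, rrs + o, o,
                 note = note))
    add(insertion_family(g$inserted_query_seq, qid, jq0, rid, lre,
                         note = note))
  } else if (qg > 0 && rg > 0) {
    ins <- g$inserted_query_seq
    all_n <- grepl("^N+$", ins)
    if (qg == rg) {
      add(diff_row(if (all_n) "gap" else "substitution",
                   qid, jq0, jq1, rid, lre, rrs, qg, note = note))
    } else if (all_n) {
      m <- min(qg, rg)
      add(diff_row("gap", qid, jq0, jq0 + m, rid, lre, lre + m, m,
                   note = note))
      if (qg > rg) {
        add(diff_row("inserted_gap", qid, jq0 + m, jq1, rid, rrs, rrs,
                     qg - m, note = note))
      } else {
        add(diff_row("simple_deletion", qid, jq1, jq1, rid, lre + m, rrs,
                     rg - m, note = note))
      }
    } else {
      add(diff_row("simple_deletion", qid, jq0, jq0, rid, lre, rrs, rg,
                   note = note))
      add(insertion_family(ins, qid, jq0, rid, lre, note = note))
    }
  }
  bind_differences(rows)
}

#' Iteratively merge mergeable neighbour pairs
#'
#' Scans each query sequence left to right; the leftmost mergeable pair
#' is classified, its differences recorded, and the two fragments
#' replaced by one continuous fragment spanning both (SNP records are
#' re-attached to the merged fragment).  The scan repeats until no pair
#' is mergeable, which terminates because every merge reduces the
#' fragment count.  Emitted differences carry the id of their final
#' merged fragment in `frag_group`, so span-length conservation can be
#' checked per fragment.
#'
#' @param frags fragment table (post nested-filtering).
#' @param snps SNP record table.
#' @param query the query [sequence_set()].
#' @param config an [diff_config()].
#' @return list with `fragments`, `snps`, `differences`.
#' @export
merge_pass <- function(frags, snps, query, config = diff_config()) {
  query <- as_sequence_set(query, "query")
  diffs <- list()
  remap <- integer(0)
  next_id <- if (nrow(frags)) max(frags$frag_id) + 1L else 1L
  out <- list()
  for (qid in unique(frags$query_id)) {
    f <- frags[frags$query_id == qid, , drop = FALSE]
    f <- f[order(f$query_start, f$query_end), , drop = FALSE]
    repeat {
      merged <- FALSE
      if (nrow(f) >= 2L) {
        for (i in seq_len(nrow(f) - 1L)) {
          a <- f[i, ]; b <- f[i + 1L, ]
          if (!mergeable(a, b, config, others = f)) next
          d <- classify_pair(a, b, query, config)
          new <- a
          new$frag_id <- next_id
          new$query_start <- min(a$query_start, b$query_start)
          new$query_end <- max(a$query_end, b$query_end)
          new$ref_start <- min(a$ref_start, b$ref_start)
          new$ref_end <- max(a$ref_end, b$ref_end)
          wl <- a$query_end - a$query_start
          wr <- b$query_end - b$query_start
          new$identity <- (a$identity * wl + b$identity * wr) / (wl + wr)
          if (nrow(d)) {
            d$frag_group <- next_id
            diffs[[length(diffs) + 1L]] <- d
          }
          remap[as.character(c(a$frag_id, b$frag_id))] <- next_id
          snps$frag_id[snps$frag_id %in% c(a$frag_id, b$frag_id)] <- next_id
          f <- rbind(
            if (i > 1L) f[seq_len(i - 1L), , drop = FALSE],
            new,
            if (i + 1L < nrow(f)) f[seq(i + 2L, nrow(f)), , drop = FALSE])
          next_id <- next_id + 1L
          merged <- TRUE
          break
        }
      }
      if (!merged) break
    }
    out[[length(out) + 1L]] <- f
  }
  fragments <- if (length(out)) {
    as.data.frame(data.table::rbindlist(out))
  } else frags
  d <- bind_differences(diffs)
  if (nrow(d)) {
    resolve <- function(id) {
      while (!is.na(remap[as.character(id)])) id <- remap[[as.character(id)]]
      id
    }
    d$frag_group <- vapply(d$frag_group, resolve, integer(1))
  }
  list(fragments = fragments, snps = snps, differences = d)
}
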