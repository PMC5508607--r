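# Simulation engine: random genomes, a catalogue of controlled
# modifications covering every difference type, a machine-readable truth
# ledger, and the recovery evaluator.
#
# Every planted event is boundary-guarded: the residues flanking each
# junction are resampled (or the position rejected) so that no junction
# carries accidental homology with its surroundings.  Without the guards
# maximal-exact-match extension shifts breakpoints by a few bases at
# roughly 1/4 of junctions, which the recovery evaluation in exact mode
# would count as wrong placements; the guards make planted breakpoints
# unambiguous, mirroring how repeat-free simulated genomes are meant to
# behave.

#' Generate a random genome
#'
#' @param n_sequences number of sequences.
#' @param lengths length (bp) of each sequence (recycled).
#' @param gc target GC fraction.
#' @param seed optional RNG seed for reproducibility.
#' @param ids sequence ids; defaults to `ref_1`, `ref_2`, ...
#' @return a [sequence_set()] with role "reference".
#' @export
random_genome <- function(n_sequences = 1L, lengths = 100000L, gc = 0.5,
                          seed = NULL, ids = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lengths <- rep_len(as.integer(lengths), n_sequences)
  if (is.null(ids)) ids <- paste0("ref_", seq_len(n_sequences))
  seqs <- vapply(lengths, random_dna, character(1), gc = gc)
  sequence_set(stats::setNames(seqs, ids), role = "reference")
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# 0-based single-character accessor / replacement
ch <- function(s, i) substr(s, i + 1L, i + 1L)
`ch<-` <- function(s, i, value) {
  substr(s, i + 1L, i + 1L) <- value
  s
}
alt_base <- function(x) {
  pool <- setdiff(c("A", "C", "G", "T"), x)
  pool[sample.int(length(pool), 1L)]
}

#' The modification catalogue
#'
#' Names of every modification kind the simulator can plant, covering
#' each leaf of the difference taxonomy (including the five placement
#' variants of relocations and translocations), plus `rotation` for the
#' circular-genome start shift.
#'
#' @return character vector of kind names.
#' @export
modification_catalogue <- function() {
  c("simple_insertion", "simple_deletion", "substitution", "gap",
    "inserted_gap", "gap_enlarged",
    "tandem_duplication", "duplication", "duplication_distant",
    "collapsed_tandem_repeat", "collapsed_repeat",
    "inversion", "reshuffling", "reshuffling_with_insertion",
    "unaligned_beginning", "unaligned_end", "unaligned_sequence",
    "relocation", "relocation_with_insertion",
    "relocation_with_inserted_gap",
    "relocation_with_insertion_and_inserted_gap",
    "relocation_with_overlap",
    "translocation", "translocation_with_insertion",
    "translocation_with_inserted_gap",
    "translocation_with_insertion_and_inserted_gap",
    "translocation_with_overlap",
    "rotation")
}

edit_kinds <- function() {
  c("simple_insertion", "simple_deletion", "substitution", "gap",
    "inserted_gap", "gap_enlarged", "tandem_duplication", "duplication",
    "duplication_distant", "collapsed_tandem_repeat", "collapsed_repeat",
    "inversion", "reshuffling", "reshuffling_with_insertion",
    "unaligned_beginning", "unaligned_end")
}

truth_template <- function() {
  data.frame(event_id = integer(), kind = character(),
             diff_type = character(), subtype = character(),
             query_id = character(),
             query_start = integer(), query_end = integer(),
             ref_id = character(), ref_start = integer(),
             ref_end = integer(), length = integer(), note = character(),
             stringsAsFactors = FALSE)
}

truth_row <- function(event_id, kind, diff_type, query_id, qs, qe,
                      ref_id, rs, re, length, subtype = NA_character_,
                      note = "") {
  data.frame(event_id = as.integer(event_id), kind = kind,
             diff_type = diff_type, subtype = subtype,
             query_id = query_id,
             query_start = as.integer(qs), query_end = as.integer(qe),
             ref_id = ref_id, ref_start = as.integer(rs),
             ref_end = as.integer(re), length = as.integer(length),
             note = note, stringsAsFactors = FALSE)
}

# expected difference rows for one edit event; off is the query offset
# accumulated before the event's reference position
edit_truth_rows <- function(ev, off, qid, rid) {
  p0 <- ev$p0; p1 <- ev$p1
  q0 <- p0 + off
  n <- nchar(ev$q_piece)
  id <- ev$event_id
  switch(ev$kind,
    simple_insertion = truth_row(id, ev$kind, "simple_insertion", qid,
                                 q0, q0 + n, rid, p0, p0, n),
    unaligned_beginning = truth_row(id, ev$kind, "unaligned_beginning", qid,
                                    q0, q0 + n, rid, p0, p0, n),
    unaligned_end = truth_row(id, ev$kind, "unaligned_end", qid,
                              q0, q0 + n, rid, p0, p0, n),
    simple_deletion = truth_row(id, ev$kind, "simple_deletion", qid,
                                q0, q0, rid, p0, p1, p1 - p0),
    substitution = truth_row(id, ev$kind, "substitution", qid,
                             q0, q0 + (p1 - p0), rid, p0, p1, p1 - p0),
    gap = truth_row(id, ev$kind, "gap", qid,
                    q0, q0 + (p1 - p0), rid, p0, p1, p1 - p0),
    gap_enlarged = rbind(
      truth_row(id, ev$kind, "gap", qid, q0, q0 + (p1 - p0),
                rid, p0, p1, p1 - p0),
      truth_row(id, ev$kind, "inserted_gap", qid, q0 + (p1 - p0), q0 + n,
                rid, p1, p1, n - (p1 - p0))),
    inserted_gap = truth_row(id, ev$kind, "inserted_gap", qid,
                             q0, q0 + n, rid, p0, p0, n),
    tandem_duplication = truth_row(id, ev$kind, "tandem_duplication", qid,
                                   q0, q0 + n, rid, p0 - n, p0, n),
    duplication = {
      g <- ev$params$spacer_len; l <- n - g
      rbind(
        truth_row(id, ev$kind, "duplication", qid, q0 + g, q0 + n,
                  rid, p0 - l, p0, l),
        truth_row(id, ev$kind, "simple_insertion", qid, q0, q0 + g,
                  rid, p0, p0, g))
    },
    duplication_distant = truth_row(id, ev$kind, "duplication", qid,
                                    q0, q0 + n, rid, ev$params$src0,
                                    ev$params$src1, n, note = "distant copy"),
    collapsed_tandem_repeat = truth_row(id, ev$kind,
                                        "collapsed_tandem_repeat", qid,
                                        q0, q0, rid, p0, p1, p1 - p0),
    collapsed_repeat = truth_row(id, ev$kind, "collapsed_repeat", qid,
                                 q0, q0, rid, p0, p1, p1 - p0,
                                 note = paste0("repeat_unit=",
                                               ev$params$unit_len)),
    inversion = truth_row(id, ev$kind, "inversion", qid,
                          q0, q0 + (p1 - p0), rid, p0, p1, p1 - p0),
    reshuffling = ,
    reshuffling_with_insertion = {
      b <- ev$params$b; g <- ev$params$spacer_len
      l1 <- b - p0; l2 <- p1 - b
      rows <- rbind(
        truth_row(id, ev$kind, "reshuffling", qid, q0, q0 + l2,
                  rid, b, p1, l2),
        truth_row(id, ev$kind, "reshuffling", qid, q0 + l2 + g,
                  q0 + l2 + g + l1, rid, p0, b, l1))
      if (g > 0L) {
        rows <- rbind(rows,
          truth_row(id, ev$kind, "simple_insertion", qid, q0 + l2,
                    q0 + l2 + g, rid, p0, p0, g))
      }
      rows
    },
    stop("unknown edit kind: ", ev$kind)
  )
}

# --- planners -------------------------------------------------------------

new_occupied <- function() data.frame(s = integer(), e = integer())

pick_position <- function(occ, L, left, right, margin, guard = NULL,
                          tries = 4000L) {
  # when the genome is crowded the separation margin is relaxed once
  # (halved, floor 2 kb) before giving up
  for (mg in unique(c(margin, max(2000L, margin %/% 2L)))) {
    lo <- left + mg
    hi <- L - right - mg
    if (hi <= lo) next
    for (i in seq_len(tries)) {
      p <- sample.int(hi - lo, 1L) + lo
      if (nrow(occ) && any(p - left - mg < occ$e &
                           p + right + mg > occ$s)) next
      if (!is.null(guard) && !guard(p)) next
      return(p)
    }
  }
  stop("could not place event (", tries, " attempts per margin)")
}

# random insert whose terminal residues avoid the given flanking bases
guarded_insert <- function(n, left_avoid, right_avoid, gc = 0.5) {
  s <- random_dna(n, gc)
  if (ch(s, 0L) == right_avoid) ch(s, 0L) <- alt_base(right_avoid)
  if (ch(s, n - 1L) == left_avoid) ch(s, n - 1L) <- alt_base(left_avoid)
  s
}

ev_len <- function(event_length) {
  sample.int(event_length[2] - event_length[1] + 1L, 1L) +
    event_length[1] - 1L
}

# plan one edit event; may plant repeats into the reference sequence.
# Returns list(ev, seq, occ).
plan_edit_event <- function(kind, s, occ, event_length, margin, event_id) {
  L <- nchar(s)
  n <- ev_len(event_length)
  ev <- list(kind = kind, event_id = event_id, params = list())
  if (kind == "simple_insertion") {
    p <- pick_position(occ, L, 1L, 1L, margin)
    ev$p0 <- p; ev$p1 <- p
    ev$q_piece <- guarded_insert(n, ch(s, p - 1L), ch(s, p))
    occ <- rbind(occ, data.frame(s = p - 1L, e = p + 1L))
  } else if (kind == "unaligned_beginning") {
    ev$p0 <- 0L; ev$p1 <- 0L
    ev$q_piece <- random_dna(n)
    occ <- rbind(occ, data.frame(s = 0L, e = 1L))
  } else if (kind == "unaligned_end") {
    ev$p0 <- L; ev$p1 <- L
    ev$q_piece <- random_dna(n)
    occ <- rbind(occ, data.frame(s = L - 1L, e = L))
  } else if (kind == "simple_deletion") {
    p <- pick_position(occ, L, 1L, n + 1L, margin, guard = function(p) {
      ch(s, p) != ch(s, p + n) && ch(s, p - 1L) != ch(s, p + n - 1L)
    })
    ev$p0 <- p; ev$p1 <- p + n; ev$q_piece <- ""
    occ <- rbind(occ, data.frame(s = p - 1L, e = p + n + 1L))
  } else if (kind == "substitution") {
    p <- pick_position(occ, L, 1L, n + 1L, margin)
    orig <- strsplit(substr0(s, p, p + n), "", fixed = TRUE)[[1]]
    ev$p0 <- p; ev$p1 <- p + n
    ev$q_piece <- paste(vapply(orig, alt_base, character(1)), collapse = "")
    occ <- rbind(occ, data.frame(s = p - 1L, e = p + n + 1L))
  } else if (kind == "gap") {
    p <- pick_position(occ, L, 1L, n + 1L, margin)
    ev$p0 <- p; ev$p1 <- p + n
    ev$q_piece <- strrep("N", n)
    occ <- rbind(occ, data.frame(s = p - 1L, e = p + n + 1L))
  } else if (kind == "gap_enlarged") {
    k <- max(100L, n %/% 3L)
    p <- pick_position(occ, L, 1L, n + 1L, margin)
    ev$p0 <- p; ev$p1 <- p + n
    ev$q_piece <- strrep("N", n + k)
    occ <- rbind(occ, data.frame(s = p - 1L, e = p + n + 1L))
  } else if (kind == "inserted_gap") {
    p <- pick_position(occ, L, 1L, 1L, margin)
    ev$p0 <- p; ev$p1 <- p
    ev$q_piece <- strrep("N", n)
    occ <- rbind(occ, data.frame(s = p - 1L, e = p + 1L))
  } else if (kind == "tandem_duplication") {
    # unit is ref[p-n, p); the copy is inserted at p
    p <- pick_position(occ, L, n + 1L, 1L, margin, guard = function(p) {
      ch(s, p - n) != ch(s, p) && ch(s, p - n - 1L) != ch(s, p - 1L)
    })
    ev$p0 <- p; ev$p1 <- p
    ev$q_piece <- substr0(s, p - n, p)
    occ <- rbind(occ, data.frame(s = p - n - 1L, e = p + 1L))
  } else if (kind == "duplication") {
    g <- 300L + sample.int(500L, 1L)
    p <- pick_position(occ, L, n + 1L, 1L, margin)
    G <- guarded_insert(g, ch(s, p - n - 1L), ch(s, p))
    ev$p0 <- p; ev$p1 <- p
    ev$q_piece <- paste0(G, substr0(s, p - n, p))
    ev$params <- list(spacer_len = g)
    occ <- rbind(occ, data.frame(s = p - n - 1L, e = p + 1L))
  } else if (kind == "duplication_distant") {
    src <- pick_position(occ, L, 1L, n + 1L, margin)
    occ <- rbind(occ, data.frame(s = src - 1L, e = src + n + 1L))
    X <- substr0(s, src, src + n)
    t <- pick_position(occ, L, 1L, 1L, max(margin, 25000L),
                       guard = function(t) {
      abs(t - src) > 25000L && ch(X, 0L) != ch(s, t) &&
        ch(X, n - 1L) != ch(s, t - 1L)
    })
    ev$p0 <- t; ev$p1 <- t
    ev$q_piece <- X
    ev$params <- list(src0 = src, src1 = src + n)
    occ <- rbind(occ, data.frame(s = t - 1L, e = t + 1L))
  } else if (kind == "collapsed_tandem_repeat") {
    # plant an adjacent duplicate ref[p, p+n) -> ref[p+n, p+2n),
    # then delete the second copy from the query
    p <- pick_position(occ, L, 1L, 2L * n + 1L, margin, guard = function(p) {
      ch(s, p + 2L * n) != ch(s, p) && ch(s, p - 1L) != ch(s, p + n - 1L)
    })
    s <- paste0(substr0(s, 0L, p + n), substr0(s, p, p + n),
                substr0(s, p + 2L * n, L))
    ev$p0 <- p + n; ev$p1 <- p + 2L * n; ev$q_piece <- ""
    occ <- rbind(occ, data.frame(s = p - 1L, e = p + 2L * n + 1L))
  } else if (kind == "collapsed_repeat") {
    d <- 2000L + sample.int(6000L, 1L)
    span <- 2L * n + d
    p <- pick_position(occ, L, 1L, span + 1L, margin, guard = function(p) {
      # after the query deletion the suffix abuts the spacer on the
      # reference: guard suffix[0] vs spacer[0] and the left junction
      ch(s, p + span) != ch(s, p + n) && ch(s, p - 1L) != ch(s, p + n + d - 1L)
    })
    s <- paste0(substr0(s, 0L, p + n + d), substr0(s, p, p + n),
                substr0(s, p + span, L))
    ev$p0 <- p + n; ev$p1 <- p + span; ev$q_piece <- ""
    ev$params <- list(unit_len = n)
    occ <- rbind(occ, data.frame(s = p - 1L, e = p + span + 1L))
  } else if (kind == "inversion") {
    n <- max(n, 1000L)
    p <- pick_position(occ, L, 1L, n + 1L, margin, guard = function(p) {
      ch(s, p) != comp_base(ch(s, p + n - 1L)) &&
        ch(s, p - 1L) != comp_base(ch(s, p + n))
    })
    ev$p0 <- p; ev$p1 <- p + n
    ev$q_piece <- revcomp(substr0(s, p, p + n))
    occ <- rbind(occ, data.frame(s = p - 1L, e = p + n + 1L))
  } else if (kind %in% c("reshuffling", "reshuffling_with_insertion")) {
    l1 <- 2000L + sample.int(6000L, 1L)
    l2 <- 2000L + sample.int(6000L, 1L)
    g <- if (kind == "reshuffling_with_insertion") {
      100L + sample.int(400L, 1L)
    } else 0L
    span <- l1 + l2
    p <- pick_position(occ, L, 1L, span + 1L, margin, guard = function(p) {
      b <- p + l1; cc <- p + span
      ch(s, b) != ch(s, p) &&                         # f1 right edge
        ch(s, p - 1L) != ch(s, b - 1L) &&             # f2 left edge
        (g > 0L || ch(s, p) != ch(s, cc)) &&          # f2 right edge
        (g > 0L || ch(s, cc - 1L) != ch(s, p - 1L)) && # f3 left edge
        ch(s, cc) != ch(s, b) &&                      # f3 right edge
        ch(s, b - 1L) != ch(s, cc - 1L)               # f4 left edge
    })
    b <- p + l1
    G <- if (g > 0L) {
      # first base must differ from the reference base after B2's region,
      # last base from the base preceding B1's region
      guarded_insert(g, ch(s, p - 1L), ch(s, p + span))
    } else ""
    ev$p0 <- p; ev$p1 <- p + span
    ev$q_piece <- paste0(substr0(s, b, p + span), G, substr0(s, p, b))
    ev$params <- list(b = b, spacer_len = g)
    occ <- rbind(occ, data.frame(s = p - 1L, e = p + span + 1L))
  } else {
    stop("unknown edit kind: ", kind)
  }
  list(ev = ev, seq = s, occ = occ)
}

# --- application ----------------------------------------------------------

#' Apply a modification plan to a reference
#'
#' Mechanically applies a concrete plan (as built by
#' [simulate_genome_pair()]) to the reference, with exact bookkeeping of
#' coordinate shifts, and returns the query plus the truth ledger whose
#' rows give every expected difference with final query coordinates.
#' Edit events on one sequence must not overlap; layout events
#' (rotation, relocations, translocations) restructure a whole sequence
#' and are applied by the planner, so the plan they appear in is
#' executed as stored.
#'
#' @param ref a [sequence_set()].
#' @param plan list of event lists (see [simulate_genome_pair()]).
#' @param seed unused; accepted so that fully concrete plans remain
#'   reproducible to apply regardless of RNG state.
#' @return list with `query` (a [sequence_set()]) and `truth` (the
#'   ledger data.frame).
#' @export
apply_modifications <- function(ref, plan, seed = NULL) {
  ref <- as_sequence_set(ref, "reference")
  qmap <- stats::setNames(sub("^ref", "query", names(ref)), names(ref))
  queries <- list()
  truth <- list(truth_template())
  for (rid in names(ref)) {
    evs <- Filter(function(e) identical(e$seq_id, rid) &&
                    e$kind %in% edit_kinds(), plan)
    rot <- Filter(function(e) identical(e$seq_id, rid) &&
                    e$kind == "rotation", plan)
    s <- ref[[rid]]
    qid <- qmap[[rid]]
    if (length(evs)) {
      ord <- order(vapply(evs, function(e) e$p0, integer(1)))
      evs <- evs[ord]
      pieces <- character(0)
      cur <- 0L; off <- 0L
      for (e in evs) {
        if (e$p0 < cur) stop("overlapping event placements on ", rid)
        pieces <- c(pieces, substr0(s, cur, e$p0))
        truth[[length(truth) + 1L]] <- edit_truth_rows(e, off, qid, rid)
        pieces <- c(pieces, e$q_piece)
        off <- off + nchar(e$q_piece) - (e$p1 - e$p0)
        cur <- e$p1
      }
      pieces <- c(pieces, substr0(s, cur, nchar(s)))
      q <- paste(pieces, collapse = "")
    } else {
      q <- s
    }
    if (length(rot)) {
      r <- rot[[1L]]$params$r
      Lq <- nchar(q)
      if (length(evs) && any(vapply(evs, function(e) e$p0, integer(1)) < r)) {
        stop("edits combined with rotation must lie after the rotation point")
      }
      q <- paste0(substr0(q, r, Lq), substr0(q, 0L, r))
      n_t <- length(truth)
      for (i in seq_len(n_t)) {
        if (nrow(truth[[i]]) && all(truth[[i]]$query_id == qid)) {
          truth[[i]]$query_start <- truth[[i]]$query_start - r
          truth[[i]]$query_end <- truth[[i]]$query_end - r
        }
      }
      truth[[length(truth) + 1L]] <- truth_row(
        rot[[1L]]$event_id, "rotation", "circular_genome_start", qid,
        Lq - r, Lq - r, rid, 0L, 0L, 0L)
    }
    queries[[qid]] <- q
  }
  # layout events carrying a prebuilt query sequence
  for (e in Filter(function(e) !is.null(e$layout_query), plan)) {
    queries[[e$layout_query$id]] <- e$layout_query$seq
    truth[[length(truth) + 1L]] <- e$layout_query$truth
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(query = sequence_set(unlist(queries), role = "query"),
       truth = truth)
}

# --- high-level pair simulation ------------------------------------------

#' Simulate a reference/query genome pair with controlled modifications
#'
#' Builds a random reference, plants the requested modifications (with
#' boundary guards and, for repeat-dependent kinds, repeats planted into
#' the reference first), and derives the query plus a truth ledger of
#' every expected difference in final query coordinates.
#'
#' Edit kinds (see [modification_catalogue()]) may be combined and
#' repeated; they are placed at least `min_separation` bases apart.
#' Layout kinds (`rotation`, the relocation/translocation variants,
#' `unaligned_sequence`) restructure whole sequences: relocation and
#' translocation kinds must be requested alone, `rotation` may be
#' combined with edit kinds (which are then placed after the rotation
#' point), and `unaligned_sequence` adds an extra novel query sequence.
#'
#' @param kinds character vector of modification kinds.
#' @param seed RNG seed (one seed drives all randomness).
#' @param genome_length total reference length in bp.
#' @param gc GC fraction of the random genome.
#' @param config an [diff_config()] (distances inform event geometry).
#' @param event_length two integers: range of local event lengths.
#' @param min_separation minimum distance between planted events.
#' @return list with `ref`, `query`, `truth`, `plan`.
#' @export
simulate_genome_pair <- function(kinds, seed = NULL,
                                 genome_length = 100000L, gc = 0.5,
                                 config = diff_config(),
                                 event_length = c(300L, 2000L),
                                 min_separation = 5000L) {
  if (!is.null(seed)) set.seed(seed)
  kinds <- as.character(kinds)
  unknown <- setdiff(kinds, modification_catalogue())
  if (length(unknown)) stop("unknown kind(s): ", paste(unknown, collapse = ", "))
  sd <- config$structural_distance
  reloc <- grep("^relocation", kinds, value = TRUE)
  transl <- grep("^translocation", kinds, value = TRUE)
  plan <- list()
  eid <- 0L

  if (length(transl)) {
    if (length(kinds) > 1L) stop("translocation kinds must be simulated alone")
    kind <- transl
    half <- genome_length %/% 2L
    ref <- random_genome(2L, half, gc)
    r1 <- ref[["ref_1"]]; r2 <- ref[["ref_2"]]
    built <- build_junction_query(kind, r1, r2, "ref_1", "ref_2",
                                  sd, event_length, eid + 1L)
    plan[[1L]] <- list(kind = kind, seq_id = "ref_1", event_id = 1L,
                       params = built$params,
                       layout_query = built$layout_query)
    ref <- sequence_set(c(ref_1 = built$r1, ref_2 = built$r2),
                        role = "reference")
    ap <- apply_modifications(ref, plan)
    return(list(ref = ref, query = ap$query, truth = ap$truth, plan = plan))
  }

  if (length(reloc)) {
    if (length(kinds) > 1L) stop("relocation kinds must be simulated alone")
    kind <- reloc
    ref <- random_genome(1L, genome_length, gc)
    r1 <- ref[["ref_1"]]
    built <- build_junction_query(kind, r1, r1, "ref_1", "ref_1",
                                  sd, event_length, 1L)
    plan[[1L]] <- list(kind = kind, seq_id = "ref_1", event_id = 1L,
                       params = built$params,
                       layout_query = built$layout_query)
    ref <- sequence_set(c(ref_1 = built$r1), role = "reference")
    ap <- apply_modifications(ref, plan)
    return(list(ref = ref, query = ap$query, truth = ap$truth, plan = plan))
  }

  ref <- random_genome(1L, genome_length, gc)
  s <- ref[["ref_1"]]
  occ <- new_occupied()
  rot_r <- NULL
  if ("rotation" %in% kinds) {
    rot_r <- as.integer(genome_length %/% 4L +
                          sample.int(genome_length %/% 4L, 1L))
    eid <- eid + 1L
    plan[[length(plan) + 1L]] <- list(kind = "rotation", seq_id = "ref_1",
                                      event_id = eid,
                                      params = list(r = rot_r))
    occ <- rbind(occ, data.frame(s = 0L, e = rot_r + min_separation))
    kinds <- setdiff(kinds, "rotation")
  }
  for (kind in kinds) {
    if (kind == "unaligned_sequence") {
      eid <- eid + 1L
      n <- 1000L + sample.int(2000L, 1L)
      qid <- paste0("query_novel_", eid)
      plan[[length(plan) + 1L]] <- list(
        kind = "unaligned_sequence", seq_id = NA_character_,
        event_id = eid, params = list(length = n),
        layout_query = list(
          id = qid, seq = random_dna(n),
          truth = truth_row(eid, "unaligned_sequence",
                            "unaligned_sequence", qid, 0L, n,
                            NA_character_, NA_integer_, NA_integer_, n)))
      next
    }
    eid <- eid + 1L
    planned <- plan_edit_event(kind, s, occ, event_length,
                               min_separation, eid)
    s <- planned$seq
    occ <- planned$occ
    ev <- planned$ev
    ev$seq_id <- "ref_1"
    plan[[length(plan) + 1L]] <- ev
  }
  ref <- sequence_set(c(ref_1 = s), role = "reference")
  ap <- apply_modifications(ref, plan)
  list(ref = ref, query = ap$query, truth = ap$truth, plan = plan)
}

# build the query for a relocation/translocation kind: a reference-1
# prefix joined (with optional spacer or planted overlap) to a distant
# region of reference-2 (identical to reference-1 for relocations).
# Returns updated reference sequence(s), params and the layout query.
build_junction_query <- function(kind, r1, r2, rid1, rid2, sd,
                                 event_length, event_id) {
  inter <- rid1 != rid2
  L1 <- nchar(r1); L2 <- nchar(r2)
  variant <- sub("^(translocation|relocation)(_with_)?", "", kind)
  if (variant == "") variant <- "simple"
  base_kind <- if (inter) "translocation" else "relocation"
  a <- L1 %/% 3L + sample.int(L1 %/% 6L, 1L)
  if (inter) {
    b <- L2 %/% 3L + sample.int(L2 %/% 6L, 1L)
  } else {
    b <- a + sd + 2000L + sample.int(10000L, 1L)
  }
  m <- min(L2 - b, 20000L + sample.int(10000L, 1L))
  stopifnot(m > 1000L)
  spacer <- ""
  mu <- 0L
  n <- ev_len(event_length)
  fix_guards <- function() {
    # junction guards: query = r1[0,a) ++ spacer ++ r2[b, b+m)
    if (nchar(spacer)) {
      if (ch(spacer, 0L) == ch(r1, a)) {
        ch(spacer, 0L) <<- alt_base(ch(r1, a))
      }
      if (ch(spacer, nchar(spacer) - 1L) == ch(r2, b - 1L)) {
        ch(spacer, nchar(spacer) - 1L) <<- alt_base(ch(r2, b - 1L))
      }
    }
  }
  ok_simple <- function() {
    ch(r2, b) != ch(r1, a) && ch(r1, a - 1L) != ch(r2, b - 1L)
  }
  if (variant %in% c("simple", "overlap")) {
    tries <- 0L
    while (!ok_simple() && tries < 2000L) {
      a <- L1 %/% 3L + sample.int(L1 %/% 6L, 1L)
      if (!inter) b <- a + sd + 2000L + sample.int(10000L, 1L)
      tries <- tries + 1L
    }
  }
  if (variant == "insertion") {
    spacer <- random_dna(n); fix_guards()
  } else if (variant == "inserted_gap") {
    spacer <- strrep("N", n)
  } else if (variant == "insertion_and_inserted_gap") {
    spacer <- paste0(random_dna(n), strrep("N", max(100L, n %/% 2L)))
    fix_guards()
  } else if (variant == "overlap") {
    mu <- 60L + sample.int(90L, 1L)
    # plant r2[b-mu, b) := r1[a-mu, a), guard the base before the repeat
    motif <- substr0(r1, a - mu, a)
    r2 <- paste0(substr0(r2, 0L, b - mu), motif, substr0(r2, b, L2))
    if (!inter && identical(rid1, rid2)) r1 <- r2
    if (ch(r1, a - mu - 1L) == ch(r2, b - mu - 1L)) {
      r2 <- `ch<-`(r2, b - mu - 1L, alt_base(ch(r1, a - mu - 1L)))
      if (!inter) r1 <- r2
    }
  }
  qseq <- paste0(substr0(r1, 0L, a), spacer, substr0(r2, b, b + m))
  qid <- "query_1"
  g <- nchar(spacer)
  subtype <- c(simple = "simple", insertion = "with_insertion",
               inserted_gap = "with_inserted_gap",
               insertion_and_inserted_gap = "with_insertion_and_inserted_gap",
               overlap = "with_overlap")[[variant]]
  rows <- if (variant == "overlap") {
    truth_row(event_id, kind, base_kind, qid, a - mu, a, rid2,
              b - mu, b - mu, mu, subtype = subtype)
  } else {
    truth_row(event_id, kind, base_kind, qid, a, a + g, rid2, b, b, g,
              subtype = subtype)
  }
  if (g > 0L) {
    chars <- strsplit(spacer, "", fixed = TRUE)[[1]]
    rl <- rle(chars == "N")
    offs <- cumsum(c(0L, rl$lengths))
    for (i in seq_along(rl$lengths)) {
      rows <- rbind(rows, truth_row(
        event_id, kind,
        if (rl$values[i]) "inserted_gap" else "simple_insertion",
        qid, a + offs[i], a + offs[i + 1L], rid2, b, b, rl$lengths[i]))
    }
  }
  list(r1 = r1, r2 = r2,
       params = list(a = a, b = b, m = m, mu = mu, spacer = spacer),
       layout_query = list(id = qid, seq = qseq, truth = rows))
}
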