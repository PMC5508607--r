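# Core data model: aligned fragments, per-base SNP records, differences.
#
# All internal coordinates are 0-based half-open on both the query and the
# reference.  Reference coordinates of a fragment are always stored
# ascending; reversal is carried solely in `strand` ("+"/"-").  MUMmer
# dialects and GFF3 (both 1-based inclusive) are converted at the I/O
# boundary only.

#' Construct a fragment table
#'
#' An aligned fragment is one matched query-region/reference-region pair.
#' Fragments are stored as a data.frame with columns `frag_id`,
#' `query_id`, `query_start`, `query_end`, `ref_id`, `ref_start`,
#' `ref_end`, `strand` ("+" or "-": direction of the query fragment
#' relative to the reference) and `identity` (percent, in \[0, 100\]).
#' Coordinates are 0-based half-open and reference coordinates ascend
#' regardless of strand.
#'
#' @param query_id,query_start,query_end query side of each fragment.
#' @param ref_id,ref_start,ref_end reference side.
#' @param strand "+" or "-" per fragment.
#' @param identity percent similarity per fragment.
#' @param frag_id integer ids; generated when missing.
#' @return a `data.frame` of fragments.
#' @export
fragments <- function(query_id, query_start, query_end,
                      ref_id, ref_start, ref_end,
                      strand = "+", identity = 100,
                      frag_id = NULL) {
  n <- max(length(query_id), length(query_start), length(ref_start))
  if (is.null(frag_id)) frag_id <- seq_len(n)
  out <- data.frame(
    frag_id = as.integer(frag_id),
    query_id = rep_len(as.character(query_id), n),
    query_start = as.integer(query_start),
    query_end = as.integer(query_end),
    ref_id = as.character(ref_id),
    ref_start = as.integer(ref_start),
    ref_end = as.integer(ref_end),
    strand = rep_len(as.character(strand), n),
    identity = rep_len(as.numeric(identity), n),
    stringsAsFactors = FALSE
  )
  validate_fragments(out)
  out
}

empty_fragments <- function() {
  fragments(character(), integer(), integer(), character(), integer(),
            integer(), character(), numeric(), integer())
}

#' Validate a fragment table
#'
#' Checks the structural invariants of a fragment table: spans non-empty
#' with start < end on both sides, strand in {+,-}, identity in \[0,100\].
#' When a `snps` table is supplied, additionally checks that every SNP
#' record lies within its fragment on both coordinate systems and that
#' the query/reference span lengths differ exactly by the net indel
#' length implied by the SNPs.
#'
#' @param frags fragment table.
#' @param snps optional SNP table (see [snp_records()]).
#' @return invisibly TRUE; stops on violation.
#' @export
validate_fragments <- function(frags, snps = NULL) {
  stopifnot(is.data.frame(frags))
  if (nrow(frags)) {
    if (any(frags$query_start >= frags$query_end) ||
        any(frags$ref_start >= frags$ref_end)) {
      stop("fragment spans must satisfy start < end on both coordinates")
    }
    if (!all(frags$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (any(frags$identity < 0 | frags$identity > 100)) {
      stop("identity must lie in [0, 100]")
    }
    if (anyDuplicated(frags$frag_id)) stop("frag_id values must be unique")
  }
  if (!is.null(snps) && nrow(snps)) {
    idx <- match(snps$frag_id, frags$frag_id)
    if (anyNA(idx)) stop("snp records reference unknown fragments")
    f <- frags[idx, ]
    bad <- snps$ref_pos < f$ref_start | snps$ref_pos > f$ref_end |
      snps$query_pos < f$query_start | snps$query_pos > f$query_end
    if (any(bad)) stop("snp positions outside their fragment spans")
    for (fid in unique(snps$frag_id)) {
      fr <- frags[frags$frag_id == fid, ]
      s <- snps[snps$frag_id == fid, ]
      net <- sum(s$kind == "insertion") - sum(s$kind == "deletion")
      if ((fr$query_end - fr$query_start) - (fr$ref_end - fr$ref_start) != net) {
        stop("fragment ", fid, ": span lengths inconsistent with net indel ",
             "length implied by snps")
      }
    }
  }
  invisible(TRUE)
}

#' Construct a SNP record table
#'
#' One record per substituted, inserted or deleted base inside a
#' fragment.  Substitutions carry a residue on both sides; insertions a
#' gap marker (`"."`) on the reference side with `ref_pos` the 0-based
#' reference position *before which* the base is inserted; deletions a
#' gap marker on the query side with `query_pos` the position before
#' which the reference base is missing from the query.
#'
#' @param frag_id owning fragment id (NA allowed for records parsed
#'   before fragment assignment).
#' @param kind "substitution", "insertion" or "deletion".
#' @param ref_pos,query_pos 0-based coordinates (anchors for gap sides).
#' @param ref_base,query_base residue or `"."`.
#' @return a `data.frame` of SNP records.
#' @export
snp_records <- function(frag_id = integer(), kind = character(),
                        ref_pos = integer(), query_pos = integer(),
                        ref_base = character(), query_base = character()) {
  out <- data.frame(
    frag_id = as.integer(frag_id),
    kind = as.character(kind),
    ref_pos = as.integer(ref_pos),
    query_pos = as.integer(query_pos),
    ref_base = as.character(ref_base),
    query_base = as.character(query_base),
    stringsAsFactors = FALSE
  )
  if (nrow(out)) {
    if (!all(out$kind %in% c("substitution", "insertion", "deletion"))) {
      stop("snp kind must be substitution, insertion or deletion")
    }
    if (any(out$kind == "substitution" &
            (out$ref_base == "." | out$query_base == "."))) {
      stop("substitution records must carry residues on both sides")
    }
    if (any(out$kind == "insertion" & out$ref_base != ".")) {
      stop("insertion records must carry the gap marker on the reference side")
    }
    if (any(out$kind == "deletion" & out$query_base != ".")) {
      stop("deletion records must carry the gap marker on the query side")
    }
  }
  out
}

# --- differences ----------------------------------------------------------

# one difference row; zero-length spans mark breakpoints
diff_row <- function(diff_type, query_id, query_start, query_end,
                     ref_id, ref_start, ref_end, length,
                     subtype = NA_character_, category = "struct",
                     note = "", frag_group = NA_integer_) {
  data.frame(
    diff_type = diff_type, subtype = subtype,
    query_id = query_id,
    query_start = as.integer(query_start), query_end = as.integer(query_end),
    ref_id = ref_id,
    ref_start = as.integer(ref_start), ref_end = as.integer(ref_end),
    length = as.integer(length), category = category, note = note,
    frag_group = as.integer(frag_group),
    stringsAsFactors = FALSE
  )
}

empty_differences <- function() {
  diff_row(character(), character(), integer(), integer(), character(),
           integer(), integer(), integer(), character(), character(),
           character(), integer())
}

bind_differences <- function(lst) {
  lst <- Filter(function(d) !is.null(d) && nrow(d) > 0, lst)
  if (!length(lst)) return(empty_differences())
  as.data.frame(data.table::rbindlist(lst))
}

# --- pair geometry --------------------------------------------------------

#' Geometry of a neighbouring fragment pair
#'
#' For two fragments on the same query sequence with `a` preceding `b`,
#' computes the signed gap between them on the query
#' (`query_gap = b$query_start - a$query_end`; negative means the query
#' fragments overlap) and on the reference, in orientation-consistent
#' order: for forward pairs the reference fragments are expected in query
#' order, for jointly reversed pairs in reverse order, so
#' `ref_gap = right_ref_start - left_ref_end` with left/right chosen by
#' the pair orientation.  Flags report whether the fragments share a
#' direction and whether the reference fragments are placed in the
#' consistent order for that direction.
#'
#' @param a,b one-row fragment data.frames, `a` preceding `b` on the
#'   query (`a$query_start <= b$query_start`).
#' @param query optional [sequence_set()]; when given, the query residues
#'   between the fragments are returned in `inserted_query_seq`.
#' @return a list with `query_gap`, `ref_gap`, `same_direction`,
#'   `ref_order_consistent`, `reversed_pair`, `same_ref`, `ref_sep`
#'   (non-negative separation of the reference intervals),
#'   `left_ref_end`, `right_ref_start` and `inserted_query_seq`.
#' @export
fragment_pair_geometry <- function(a, b, query = NULL) {
  a <- as.list(a); b <- as.list(b)
  if (!identical(a$query_id, b$query_id)) {
    stop("fragments lie on different query sequences")
  }
  if (a$query_start > b$query_start ||
      (a$query_start == b$query_start && a$query_end > b$query_end)) {
    stop("fragment 'a' must precede fragment 'b' on the query")
  }
  query_gap <- b$query_start - a$query_end
  same_direction <- identical(a$strand, b$strand)
  reversed <- same_direction && identical(a$strand, "-")
  left <- if (reversed) b else a
  right <- if (reversed) a else b
  ref_gap <- right$ref_start - left$ref_end
  same_ref <- identical(a$ref_id, b$ref_id)
  ref_order_consistent <- same_ref && same_direction &&
    right$ref_start >= left$ref_start && right$ref_end >= left$ref_end
  ref_sep <- if (same_ref) {
    max(0L, b$ref_start - a$ref_end, a$ref_start - b$ref_end)
  } else NA_integer_
  ins <- ""
  if (!is.null(query) && query_gap > 0) {
    ins <- substr0(query[[a$query_id]], a$query_end, b$query_start)
  }
  list(
    query_gap = query_gap, ref_gap = ref_gap,
    same_direction = same_direction,
    ref_order_consistent = ref_order_consistent,
    reversed_pair = reversed, same_ref = same_ref,
    ref_sep = ref_sep,
    left_ref_end = left$ref_end, right_ref_start = right$ref_start,
    inserted_query_seq = ins,
    a = a, b = b
  )
}
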