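# Stage 2: local differences inside aligned fragments.  Per-base SNP
# records are coalesced into runs; runs whose query side is entirely N
# become gap-type differences (gap for same-length replacement,
# inserted_gap for added N), all others become simple insertions,
# deletions and substitutions.

# coalesce one fragment's snp records into difference rows
coalesce_fragment_snps <- function(fr, s) {
  if (!nrow(s)) return(NULL)
  qstep <- if (fr$strand == "+") 1L else -1L
  s <- s[order(s$ref_pos, qstep * s$query_pos), , drop = FALSE]
  n <- nrow(s)
  if (n > 1L) {
    dref <- diff(s$ref_pos)
    dq <- diff(s$query_pos)
    same_kind <- s$kind[-1L] == s$kind[-n]
    adj <- (s$kind[-1L] == "substitution" & dref == 1L & dq == qstep) |
           (s$kind[-1L] == "insertion" & dref == 0L & dq == qstep) |
           (s$kind[-1L] == "deletion" & dref == 1L & dq == 0L)
    qn <- s$query_base == "N"
    nsplit <- (s$kind[-1L] != "deletion") & (qn[-1L] != qn[-n])
    run <- cumsum(c(TRUE, !(same_kind & adj & !nsplit)))
  } else run <- 1L
  rows <- lapply(split(seq_len(n), run), function(ii) {
    r <- s[ii, , drop = FALSE]
    kind <- r$kind[1L]
    all_n <- all(r$query_base == "N")
    if (kind == "substitution") {
      diff_row(if (all_n) "gap" else "substitution",
               fr$query_id, min(r$query_pos), max(r$query_pos) + 1L,
               fr$ref_id, min(r$ref_pos), max(r$ref_pos) + 1L,
               length = nrow(r), category = "local",
               note = paste0("frag:", fr$frag_id), frag_group = fr$frag_id)
    } else if (kind == "insertion") {
      diff_row(if (all_n) "inserted_gap" else "simple_insertion",
               fr$query_id, min(r$query_pos), max(r$query_pos) + 1L,
               fr$ref_id, r$ref_pos[1L], r$ref_pos[1L],
               length = nrow(r), category = "local",
               note = paste0("frag:", fr$frag_id), frag_group = fr$frag_id)
    } else {
      diff_row("simple_deletion",
               fr$query_id, r$query_pos[1L], r$query_pos[1L],
               fr$ref_id, min(r$ref_pos), max(r$ref_pos) + 1L,
               length = nrow(r), category = "local",
               note = paste0("frag:", fr$frag_id), frag_group = fr$frag_id)
    }
  })
  bind_differences(rows)
}

coalesce_snps <- function(frags, snps) {
  if (!nrow(snps)) return(empty_differences())
  rows <- lapply(seq_len(nrow(frags)), function(i) {
    fr <- frags[i, ]
    coalesce_fragment_snps(fr, snps[snps$frag_id == fr$frag_id, , drop = FALSE])
  })
  d <- bind_differences(rows)
  if (!nrow(d)) return(d)
  # stable reporting order: by reference position; at a shared position a
  # length-bearing gap precedes a zero-length inserted_gap anchor
  d[order(d$ref_id, d$ref_start, d$ref_end == d$ref_start, d$query_start), ,
    drop = FALSE]
}

#' Detect SNP-derived differences inside fragments
#'
#' Coalesces adjacent SNP records of the same kind into one difference
#' per run: a run of k inserted bases becomes one `simple_insertion` of
#' length k, likewise deletions, and consecutive substituted bases become
#' one `substitution`.  Runs whose query bases are all N are routed to
#' the gap detector instead (see [detect_gap_runs()]).
#'
#' @param frags fragment table.
#' @param snps SNP record table.
#' @return a difference table with both coordinate systems filled.
#' @export
detect_snp_differences <- function(frags, snps) {
  d <- coalesce_snps(frags, snps)
  d[d$diff_type %in% c("substitution", "simple_insertion", "simple_deletion"), ,
    drop = FALSE]
}

#' Detect N-runs (gaps) inside fragments
#'
#' Maximal runs of N in the query inside a fragment yield `gap`
#' differences where they replace an equal-length reference span, and
#' `inserted_gap` differences where they add length to the query; an
#' enlarged gap yields both, the gap first in reference-coordinate
#' order.  N aligned against N (a gap shared by both sequences) is not a
#' difference and produces nothing.
#'
#' @param frags fragment table.
#' @param snps SNP record table.
#' @param query unused; accepted for interface symmetry (N content is
#'   already carried by the SNP records).
#' @return a difference table.
#' @export
detect_gap_runs <- function(frags, snps, query = NULL) {
  d <- coalesce_snps(frags, snps)
  d[d$diff_type %in% c("gap", "inserted_gap"), , drop = FALSE]
}
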