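# Stage 1: global differences — wholly unaligned query sequences.

#' Detect wholly unaligned query sequences
#'
#' A query sequence with no retained alignment fragment is reported as a
#' single `unaligned_sequence` difference spanning the whole sequence,
#' with no reference span.  Because lone matches shorter than
#' `min_cluster_len` are never retained by the aligner, any query
#' sequence shorter than that threshold (65 bp by default) is reported
#' unaligned automatically.  Fragments removed by filtering do not count
#' as alignments, so a query whose every candidate placement was filtered
#' away is also reported here.
#'
#' @param query a [sequence_set()].
#' @param frags retained (post-filter) fragment table.
#' @return a difference table.
#' @export
detect_unaligned_sequences <- function(query, frags) {
  query <- as_sequence_set(query, "query")
  missing_ids <- setdiff(names(query), unique(frags$query_id))
  if (!length(missing_ids)) return(empty_differences())
  qlen <- seq_lengths(query)
  bind_differences(lapply(missing_ids, function(id) {
    diff_row("unaligned_sequence", id, 0L, qlen[[id]],
             NA_character_, NA_integer_, NA_integer_,
             qlen[[id]], category = "struct",
             note = "no retained alignment")
  }))
}
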