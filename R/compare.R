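# Full comparison pipeline: align (or ingest fragments), then the four
# detection stages, then assembly of the result object.

#' Compare a query sequence set against a reference
#'
#' Runs the complete difference-classification workflow:
#' \enumerate{
#'   \item align with the built-in anchor aligner (or ingest supplied
#'     fragments/SNPs), apply the identity and per-query consistent-chain
#'     filters;
#'   \item report wholly unaligned query sequences;
#'   \item filter nested fragments and report unaligned query ends;
#'   \item iteratively merge neighbour pairs separated by local
#'     differences, classifying each junction;
#'   \item route the remaining fragmentation to structural categories
#'     (translocations, relocations, circular starts, reshufflings,
#'     inversions), truncate overlaps and emit mapped blocks;
#'   \item coalesce the per-base SNP records of the final fragments into
#'     local differences.
#' }
#'
#' @param ref,query [sequence_set()] objects or named character vectors.
#' @param config an [diff_config()].
#' @param fragments,snps optional pre-computed alignment (e.g. from
#'   [parse_coords()] / [parse_snps()]); when NULL the built-in aligner
#'   is used.
#' @return an object of class `alndiff_result`: a list with
#'   `differences` (all classified differences, dual coordinates),
#'   `blocks` (mapped blocks), `fragments` (final merged fragments),
#'   `snps`, `routing` (structural routing of neighbour pairs),
#'   `summary` (per-type counts) and `config`.
#' @examples
#' ref <- c(chr = paste(rep("ACGT", 400), collapse = ""))
#' res <- compare_genomes(ref, c(ctg = ref[["chr"]]))
#' res$summary
#' @export
compare_genomes <- function(ref, query, config = diff_config(),
                            fragments = NULL, snps = NULL) {
  ref <- as_sequence_set(ref, "reference")
  query <- as_sequence_set(query, "query")
  if (is.null(fragments)) {
    al <- align_genomes(ref, query, config)
    frags <- al$fragments
    snps <- al$snps
  } else {
    frags <- as.data.frame(fragments)
    if (is.null(snps)) snps <- snp_records()
    snps <- assign_snps_to_fragments(frags, snps)
    keep <- frags$identity >= config$min_identity
    frags <- frags[keep, , drop = FALSE]
    frags <- filter_query_lis(frags, config)
    snps <- snps[snps$frag_id %in% frags$frag_id, , drop = FALSE]
  }

  d_global <- detect_unaligned_sequences(query, frags)

  nf <- filter_nested_fragments(frags)
  frags <- nf$kept
  snps <- snps[snps$frag_id %in% frags$frag_id, , drop = FALSE]

  d_ends <- detect_unaligned_ends(query, frags)

  mp <- merge_pass(frags, snps, query, config)
  frags <- mp$fragments
  snps <- mp$snps

  st <- structural_stage(frags, query, ref, config)
  frags <- st$fragments

  # drop snp records trimmed out by overlap truncation, then coalesce
  if (nrow(snps)) {
    idx <- match(snps$frag_id, frags$frag_id)
    keep <- !is.na(idx) &
      snps$query_pos >= frags$query_start[idx] &
      snps$query_pos <= frags$query_end[idx] &
      snps$ref_pos >= frags$ref_start[idx] &
      snps$ref_pos <= frags$ref_end[idx]
    snps <- snps[keep, , drop = FALSE]
  }
  d_within <- coalesce_snps(frags, snps)

  differences <- bind_differences(list(
    d_global, d_ends, mp$differences, st$differences, d_within))
  o <- order(differences$query_id, differences$query_start,
             differences$query_end, differences$diff_type)
  differences <- differences[o, , drop = FALSE]
  rownames(differences) <- NULL

  structure(list(
    differences = differences,
    blocks = st$blocks,
    fragments = frags,
    merged_fragments = mp$fragments,
    snps = snps,
    routing = st$routing,
    discarded = list(filtered = if (is.null(fragments)) al$dropped else NULL,
                     nested = nf$discarded),
    summary = count_differences(differences),
    config = config,
    ref_lengths = seq_lengths(ref),
    query_lengths = seq_lengths(query)
  ), class = "alndiff_result")
}

# attach externally parsed snp records to the fragment containing them;
# records falling outside every fragment are retained with a warning
assign_snps_to_fragments <- function(frags, snps) {
  if (!nrow(snps)) return(snps)
  for (i in seq_len(nrow(snps))) {
    if (!is.na(snps$frag_id[i]) && snps$frag_id[i] %in% frags$frag_id) next
    hit <- which(frags$ref_start <= snps$ref_pos[i] &
                   snps$ref_pos[i] <= frags$ref_end &
                   frags$query_start <= snps$query_pos[i] &
                   snps$query_pos[i] <= frags$query_end)
    if (length(hit)) {
      snps$frag_id[i] <- frags$frag_id[hit[1L]]
    } else {
      warning("snp record at ref position ", snps$ref_pos[i],
              " lies outside every fragment; record retained")
    }
  }
  snps
}

#' Check span-length conservation of merged fragments
#'
#' For every final fragment, the reference-span length minus the
#' query-span length must equal the summed lengths of its deletion-like
#' differences minus its insertion-like differences (from both merging
#' junctions and coalesced SNP records).  Returns a per-fragment table
#' with the discrepancy, which is zero everywhere for a consistent
#' result.
#'
#' @param result an `alndiff_result`.
#' @return data.frame with columns `frag_id`, `span_delta`,
#'   `diff_delta`, `ok`.
#' @export
check_conservation <- function(result) {
  f <- result$fragments
  d <- result$differences
  out <- data.frame(frag_id = f$frag_id,
                    span_delta = (f$ref_end - f$ref_start) -
                      (f$query_end - f$query_start),
                    diff_delta = 0L)
  if (nrow(d)) {
    dd <- d[!is.na(d$frag_group), , drop = FALSE]
    if (nrow(dd)) {
      sign <- ifelse(dd$diff_type %in% deletion_like_types(), 1L,
                     ifelse(dd$diff_type %in% insertion_like_types(), -1L, 0L))
      agg <- tapply(sign * dd$length, dd$frag_group, sum)
      idx <- match(out$frag_id, as.integer(names(agg)))
      out$diff_delta <- ifelse(is.na(idx), 0L, as.integer(agg[idx]))
    }
  }
  out$ok <- out$span_delta == out$diff_delta
  out
}

#' @export
print.alndiff_result <- function(x, ...) {
  cat("<alndiff_result>\n")
  cat(sprintf("  %d query sequence(s) vs %d reference sequence(s)\n",
              length(x$query_lengths), length(x$ref_lengths)))
  cat(sprintf("  %d mapped block(s), %d difference(s)\n",
              nrow(x$blocks), attr(x$summary, "total")))
  nz <- x$summary[x$summary > 0]
  for (t in names(nz)) cat(sprintf("    %-24s %d\n", t, nz[[t]]))
  invisible(x)
}
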