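# Recovery evaluation: compare a truth ledger against detected
# differences, either exactly (type, subtype and both coordinate spans
# identical) or loosely (grouped type compatibility plus positional
# overlap of at least one base).

# coarse type groups used by overlap-mode matching: all insertion-like
# types are interchangeable (a duplication lost to filtering legitimately
# resurfaces as a simple insertion), likewise deletion-like and
# substitution-like types
recovery_groups <- function() {
  c(simple_insertion = "insertion", duplication = "insertion",
    tandem_duplication = "insertion", inserted_gap = "insertion",
    unaligned_beginning = "insertion", unaligned_end = "insertion",
    simple_deletion = "deletion", collapsed_repeat = "deletion",
    collapsed_tandem_repeat = "deletion",
    substitution = "substitution", gap = "substitution",
    translocation = "translocation", relocation = "relocation",
    reshuffling = "reshuffling", inversion = "inversion",
    unaligned_sequence = "unaligned_sequence",
    circular_genome_start = "circular_genome_start")
}

# half-open interval overlap with zero-length spans padded to one base
spans_touch <- function(s1, e1, s2, e2) {
  if (e1 == s1) e1 <- s1 + 1L
  if (e2 == s2) e2 <- s2 + 1L
  max(s1, s2) < min(e1, e2)
}

#' Evaluate detection against a truth ledger
#'
#' For each truth row, looks for a detected difference that matches it.
#' In `exact` mode the type (and subtype, when the truth specifies one)
#' and both coordinate spans must be identical — a detection shifted by
#' even one base counts as wrongly resolved despite the correct type.
#' In `overlap` mode the types need only belong to the same coarse group
#' and the spans must overlap by at least one base (query spans when the
#' truth has query extent, reference spans otherwise).
#'
#' @param truth truth ledger from [simulate_genome_pair()].
#' @param detected difference table from [compare_genomes()].
#' @param matching "exact" or "overlap".
#' @return data.frame with one row per difference type present in the
#'   truth: `diff_type`, `n_truth`, `n_correct`; attribute `matched` is
#'   a logical vector over truth rows.
#' @export
evaluate_recovery <- function(truth, detected,
                              matching = c("exact", "overlap")) {
  matching <- match.arg(matching)
  grp <- recovery_groups()
  n <- nrow(truth)
  matched <- logical(n)
  for (i in seq_len(n)) {
    tr <- truth[i, ]
    if (matching == "exact") {
      hit <- detected$diff_type == tr$diff_type &
        detected$query_id == tr$query_id &
        detected$query_start == tr$query_start &
        detected$query_end == tr$query_end
      if (!is.na(tr$subtype)) {
        hit <- hit & !is.na(detected$subtype) &
          detected$subtype == tr$subtype
      }
      if (!is.na(tr$ref_id)) {
        hit <- hit & !is.na(detected$ref_id) &
          detected$ref_id == tr$ref_id &
          detected$ref_start == tr$ref_start &
          detected$ref_end == tr$ref_end
      } else {
        hit <- hit & is.na(detected$ref_id)
      }
    } else {
      hit <- grp[detected$diff_type] == grp[[tr$diff_type]] &
        detected$query_id == tr$query_id
      use_query <- tr$query_end > tr$query_start || is.na(tr$ref_id)
      for (j in which(hit & !is.na(hit))) {
        ok <- if (use_query) {
          spans_touch(tr$query_start, tr$query_end,
                      detected$query_start[j], detected$query_end[j])
        } else {
          !is.na(detected$ref_id[j]) &&
            detected$ref_id[j] == tr$ref_id &&
            spans_touch(tr$ref_start, tr$ref_end,
                        detected$ref_start[j], detected$ref_end[j])
        }
        hit[j] <- isTRUE(ok)
      }
      hit[is.na(hit)] <- FALSE
    }
    matched[i] <- any(hit, na.rm = TRUE)
  }
  types <- unique(truth$diff_type)
  out <- data.frame(
    diff_type = types,
    n_truth = vapply(types, function(t) sum(truth$diff_type == t),
                     integer(1)),
    n_correct = vapply(types, function(t) {
      sum(matched[truth$diff_type == t])
    }, integer(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "matched") <- matched
  out
}
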