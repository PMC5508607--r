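#' Difference taxonomy
#'
#' The complete set of difference types emitted by the classifier, in the
#' canonical reporting order: the single global type, the local insertion,
#' deletion and substitution families, the structural types, and finally
#' the `circular_genome_start` annotation, which is reported but never
#' counted as a difference.
#'
#' @format A character vector of type names.
#' @export
diff_types <- function() {
  c(
    "unaligned_sequence",
    "simple_insertion", "duplication", "tandem_duplication", "inserted_gap",
    "unaligned_beginning", "unaligned_end",
    "simple_deletion", "collapsed_repeat", "collapsed_tandem_repeat",
    "substitution", "gap",
    "translocation", "relocation", "reshuffling", "inversion",
    "circular_genome_start"
  )
}

#' Translocation / relocation subtypes
#'
#' The five placement subtypes shared by translocations and relocations,
#' distinguished by what lies between the two query fragments at the
#' junction: nothing, inserted known bases, inserted unknown bases (N),
#' both, or a partial overlap of the query fragments.
#'
#' @export
structural_subtypes <- function() {
  c("simple", "with_insertion", "with_inserted_gap",
    "with_insertion_and_inserted_gap", "with_overlap")
}

# types whose length adds bases to the query (insertion-like) or removes
# bases relative to the reference (deletion-like); used by the
# conservation check and the summary
insertion_like_types <- function() {
  c("simple_insertion", "duplication", "tandem_duplication", "inserted_gap")
}
deletion_like_types <- function() {
  c("simple_deletion", "collapsed_repeat", "collapsed_tandem_repeat")
}

#' Count differences by type
#'
#' Tabulates a difference table into a named integer vector covering every
#' taxonomy type (zero counts included) in canonical order.
#' `circular_genome_start` is reported but excluded from the `total`
#' attribute, since it marks an alignment artefact of circular genomes
#' rather than a difference.
#'
#' @param differences a difference table (see [compare_genomes()]).
#' @return named integer vector over [diff_types()], with attribute
#'   `total` giving the number of counted differences.
#' @export
count_differences <- function(differences) {
  types <- diff_types()
  n <- integer(length(types))
  names(n) <- types
  if (!is.null(differences) && nrow(differences)) {
    tab <- table(factor(differences$diff_type, levels = types))
    n[names(tab)] <- as.integer(tab)
  }
  attr(n, "total") <- sum(n[setdiff(types, "circular_genome_start")])
  n
}
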