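#' Comparison configuration
#'
#' Thresholds governing alignment and classification.  The first four
#' mirror the knobs of an anchor-based whole-genome aligner; the last two
#' govern when fragment separation is explained by a local difference and
#' when it becomes structural.
#'
#' @param min_cluster_len minimum aligned length (bases) for a lone match
#'   to be kept; query sequences with no retained match of at least this
#'   length are reported as wholly unaligned.  Default 65.
#' @param min_match_len minimum length of a maximal exact match used as an
#'   alignment anchor.  Default 20.
#' @param extension_distance how far alignments are extended across a
#'   poorly matching region before the alignment is broken; local
#'   differences longer than this split fragments.  Default 200.
#' @param min_identity minimum percent identity of a fragment, in
#'   \[0, 100\]; fragments below it are dropped at ingestion.  Default 0.
#' @param max_merge_distance maximum distance (bases) between the
#'   reference fragments of a neighbouring pair for the pair to be merged
#'   as a local difference.  Default 10000.
#' @param structural_distance reference distance at or beyond which a
#'   same-reference neighbouring pair is a relocation, and the maximum
#'   per-link distance when grouping nearby fragments for reshuffling
#'   detection.  Default 10000.
#' @param circular whether to recognize the rotated-start geometry of
#'   circular genomes and annotate it (`circular_genome_start`) instead of
#'   calling a relocation.  Default TRUE.
#' @return a list of class `alndiff_config`.
#' @export
diff_config <- function(min_cluster_len = 65L,
                        min_match_len = 20L,
                        extension_distance = 200L,
                        min_identity = 0,
                        max_merge_distance = 10000L,
                        structural_distance = 10000L,
                        circular = TRUE) {
  cfg <- list(
    min_cluster_len = as.integer(min_cluster_len),
    min_match_len = as.integer(min_match_len),
    extension_distance = as.integer(extension_distance),
    min_identity = as.numeric(min_identity),
    max_merge_distance = as.integer(max_merge_distance),
    structural_distance = as.integer(structural_distance),
    circular = isTRUE(circular)
  )
  for (f in c("min_cluster_len", "min_match_len", "extension_distance",
              "max_merge_distance", "structural_distance")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) stop(f, " must be a positive integer")
  }
  if (cfg$min_identity < 0 || cfg$min_identity > 100) {
    stop("min_identity must lie in [0, 100]")
  }
  class(cfg) <- "alndiff_config"
  cfg
}

#' @export
print.alndiff_config <- function(x, ...) {
  cat("<alndiff_config>\n")
  for (f in setdiff(names(x), "circular")) cat(sprintf("  %-20s %s\n", f, x[[f]]))
  cat(sprintf("  %-20s %s\n", "circular", x$circular))
  invisible(x)
}
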