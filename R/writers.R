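# Serialization: dual-coordinate GFF3 tracks, per-type summary, internal
# fragment/SNP TSV, and cross-genome per-base bedGraph aggregation.
#
# GFF3 records are 1-based inclusive.  A zero-length (breakpoint) span is
# written as a one-base anchor at the junction with a `zero_length=true`
# attribute; the exact spans of both coordinate systems are carried in
# the `query_coord` / `ref_coord` attributes ("seqid:start-end", 1-based
# inclusive, with end = start - 1 encoding an empty span), which makes
# parsing the file back fully lossless.

gff_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  gsub("\t", "%09", x, fixed = TRUE)
}

gff_unescape <- function(x) {
  x <- gsub("%09", "\t", x, fixed = TRUE)
  x <- gsub("%26", "&", x, fixed = TRUE)
  x <- gsub("%2C", ",", x, fixed = TRUE)
  x <- gsub("%3D", "=", x, fixed = TRUE)
  x <- gsub("%3B", ";", x, fixed = TRUE)
  gsub("%25", "%", x, fixed = TRUE)
}

# 0-based half-open span -> "start-end" 1-based inclusive (empty: end = start-1)
fmt_span <- function(s, e) paste0(s + 1L, "-", e)
parse_span <- function(x) {
  m <- regmatches(x, regexec("^(-?[0-9]+)-(-?[0-9]+)$", x))[[1]]
  if (length(m) != 3L) stop("malformed coordinate span: ", x)
  c(as.integer(m[2]) - 1L, as.integer(m[3]))
}

#' Write a GFF3 track
#'
#' Writes differences (category `"local"` for in-fragment differences,
#' `"structural"` for everything that caused or constitutes alignment
#' fragmentation) or mapped blocks (`"blocks"`) as GFF3, with seqid and
#' the main span taken from the chosen coordinate system and the
#' opposite system's location carried in the attributes.  Records are
#' sorted by seqid then start.  In the reference-based file, differences
#' without a reference span (wholly unaligned query sequences) are
#' omitted.
#'
#' @param differences difference table (ignored for `category =
#'   "blocks"`).
#' @param blocks mapped-block table (used only for `category = "blocks"`).
#' @param coordinate_system `"query"` or `"reference"`.
#' @param category `"local"`, `"structural"` or `"blocks"`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_gff3 <- function(differences, blocks,
                       coordinate_system = c("query", "reference"),
                       category = c("local", "structural", "blocks"),
                       path) {
  coordinate_system <- match.arg(coordinate_system)
  category <- match.arg(category)
  lines <- "##gff-version 3"
  if (category == "blocks") {
    b <- blocks
    if (!is.null(b) && nrow(b)) {
      seqid <- if (coordinate_system == "query") b$query_id else b$ref_id
      s <- if (coordinate_system == "query") b$query_start else b$ref_start
      e <- if (coordinate_system == "query") b$query_end else b$ref_end
      attrs <- paste0(
        "ID=block_", b$block_id,
        ";query_coord=", b$query_id, ":", fmt_span(b$query_start, b$query_end),
        ";ref_coord=", b$ref_id, ":", fmt_span(b$ref_start, b$ref_end))
      rec <- data.frame(seqid = seqid, start = s + 1L, end = e,
                        strand = b$strand, attrs = attrs,
                        type = "mapped_block", stringsAsFactors = FALSE)
      rec <- rec[order(rec$seqid, rec$start), ]
      lines <- c(lines, sprintf("%s\talndiff\t%s\t%d\t%d\t.\t%s\t.\t%s",
                                rec$seqid, rec$type, rec$start, rec$end,
                                rec$strand, rec$attrs))
    }
    writeLines(lines, path)
    return(invisible(path))
  }
  d <- differences
  want <- if (category == "local") "local" else "struct"
  d <- d[d$category == want, , drop = FALSE]
  if (coordinate_system == "reference") d <- d[!is.na(d$ref_id), , drop = FALSE]
  if (nrow(d)) {
    missing_ref <- is.na(d$ref_id) & d$diff_type != "unaligned_sequence"
    if (any(missing_ref)) {
      stop("difference(s) of type ",
           paste(unique(d$diff_type[missing_ref]), collapse = ","),
           " lack the reference span required for GFF3 output")
    }
    if (coordinate_system == "query") {
      seqid <- d$query_id; s0 <- d$query_start; e0 <- d$query_end
    } else {
      seqid <- d$ref_id; s0 <- d$ref_start; e0 <- d$ref_end
    }
    zero <- e0 == s0
    start1 <- ifelse(zero, pmax(s0, 1L), s0 + 1L)
    end1 <- ifelse(zero, pmax(s0, 1L), e0)
    attrs <- paste0(
      "ID=", category, "_", seq_len(nrow(d)),
      ";Name=", ifelse(is.na(d$subtype), d$diff_type, d$subtype),
      ifelse(is.na(d$subtype), "", paste0(";subtype=", d$subtype)),
      ";len=", d$length,
      ";category=", d$category,
      ";query_coord=", d$query_id, ":", fmt_span(d$query_start, d$query_end),
      ifelse(is.na(d$ref_id), "",
             paste0(";ref_coord=", d$ref_id, ":",
                    fmt_span(d$ref_start, d$ref_end))),
      ifelse(zero, ";zero_length=true", ""),
      ifelse(is.na(d$frag_group), "",
             paste0(";frag_group=", d$frag_group)),
      ifelse(nchar(d$note) > 0, paste0(";note=", gff_escape(d$note)), ""))
    rec <- data.frame(seqid = seqid, type = d$diff_type,
                      start = start1, end = end1, attrs = attrs,
                      stringsAsFactors = FALSE)
    o <- order(rec$seqid, rec$start, rec$end)
    rec <- rec[o, ]
    lines <- c(lines, sprintf("%s\talndiff\t%s\t%d\t%d\t.\t.\t.\t%s",
                              rec$seqid, rec$type, rec$start, rec$end,
                              rec$attrs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read back a difference GFF3 file
#'
#' Reconstructs the difference table written by [write_gff3()] from the
#' `query_coord` / `ref_coord` attributes, so the round trip is exact.
#'
#' @param path file written by [write_gff3()].
#' @return a difference table.
#' @export
read_diff_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return(empty_differences())
  rows <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L) stop("malformed GFF3 record: ", ln)
    kv <- strsplit(strsplit(f[9], ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    at <- stats::setNames(
      vapply(kv, function(p) paste(p[-1], collapse = "="), character(1)),
      vapply(kv, `[`, character(1), 1L))
    qc <- strsplit(at[["query_coord"]], ":", fixed = TRUE)[[1]]
    qs <- parse_span(qc[2])
    if (!is.na(at["ref_coord"])) {
      rc <- strsplit(at[["ref_coord"]], ":", fixed = TRUE)[[1]]
      rs <- parse_span(rc[2])
      rid <- rc[1]
    } else {
      rs <- c(NA_integer_, NA_integer_); rid <- NA_character_
    }
    diff_row(f[3], qc[1], qs[1], qs[2], rid, rs[1], rs[2],
             as.integer(at[["len"]]),
             subtype = if (!is.na(at["subtype"])) at[["subtype"]]
             else NA_character_,
             category = at[["category"]],
             note = if (!is.na(at["note"])) gff_unescape(at[["note"]]) else "",
             frag_group = if (!is.na(at["frag_group"])) {
               as.integer(at[["frag_group"]])
             } else NA_integer_)
  })
  bind_differences(rows)
}

#' Write the per-type summary
#'
#' One line per taxonomy type (zero counts included) in canonical order,
#' then the total; the `circular_genome_start` annotation is listed
#' separately and excluded from the total.
#'
#' @param differences difference table.
#' @param path output file.
#' @return the counts (invisibly).
#' @export
write_summary <- function(differences, path) {
  n <- count_differences(differences)
  counted <- setdiff(diff_types(), "circular_genome_start")
  lines <- c("# alndiff summary: number of differences of each type",
             sprintf("%s\t%d", counted, n[counted]),
             sprintf("total\t%d", attr(n, "total")),
             "# annotations (not counted as differences)",
             sprintf("circular_genome_start\t%d", n[["circular_genome_start"]]))
  writeLines(lines, path)
  invisible(n)
}

#' Aggregate one difference type across genomes into bedGraph
#'
#' Given per-genome difference tables on one shared reference, computes
#' at every reference base the number of genomes exhibiting the given
#' difference type there (per-genome events are first collapsed, so a
#' genome counts at most once per base), run-length encoded as bedGraph
#' intervals (0-based half-open).  Zero-length breakpoint records carry
#' no bases and are ignored.
#'
#' @param per_genome_differences named list of difference tables.
#' @param diff_type one taxonomy type.
#' @param reference_lengths named vector of reference sequence lengths.
#' @param path optional output file; when NULL nothing is written.
#' @return data.frame with `ref_id`, `start`, `end`, `value` (rows with
#'   value zero omitted).
#' @export
aggregate_bedgraph <- function(per_genome_differences, diff_type,
                               reference_lengths, path = NULL) {
  stopifnot(length(diff_type) == 1L)
  per_ref <- lapply(names(reference_lengths), function(rid) {
    L <- reference_lengths[[rid]]
    cov <- NULL
    for (g in names(per_genome_differences)) {
      d <- per_genome_differences[[g]]
      d <- d[d$diff_type == diff_type & !is.na(d$ref_id) &
               d$ref_id == rid & d$ref_end > d$ref_start, , drop = FALSE]
      if (!nrow(d)) next
      if (any(d$ref_end > L | d$ref_start < 0)) {
        bad <- which(d$ref_end > L | d$ref_start < 0)[1]
        stop("genome '", g, "': record ", bad, " (", diff_type,
             " at ", d$ref_start[bad], "-", d$ref_end[bad],
             ") exceeds reference length ", L, " of ", rid)
      }
      ir <- IRanges::reduce(IRanges::IRanges(start = d$ref_start + 1L,
                                             end = d$ref_end))
      cv <- IRanges::coverage(ir, width = L)
      cov <- if (is.null(cov)) cv else cov + cv
    }
    if (is.null(cov)) return(NULL)
    rl <- S4Vectors::runLength(cov)
    rv <- S4Vectors::runValue(cov)
    e <- cumsum(rl)
    s <- e - rl
    keep <- rv > 0
    if (!any(keep)) return(NULL)
    data.frame(ref_id = rid, start = s[keep], end = e[keep],
               value = as.integer(rv[keep]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), per_ref))
  if (is.null(out)) {
    out <- data.frame(ref_id = character(), start = integer(),
                      end = integer(), value = integer(),
                      stringsAsFactors = FALSE)
  }
  if (!is.null(path)) {
    lines <- c(sprintf("track type=bedGraph name=%s", diff_type),
               sprintf("%s\t%d\t%d\t%d", out$ref_id, out$start, out$end,
                       out$value))
    writeLines(lines, path)
  }
  out
}

#' Write / read the internal fragment and SNP tables
#'
#' Tab-separated with a documented header; coordinates are 0-based
#' half-open, exactly as held in memory, so the round trip is the
#' identity.
#'
#' @param frags fragment table.
#' @param path file path.
#' @export
write_fragments <- function(frags, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# alndiff fragments: 0-based half-open coordinates;",
               "# reference coordinates ascend; strand carries reversal"),
             con)
  utils::write.table(frags, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments
#' @export
read_fragments <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = c(
                             frag_id = "integer", query_id = "character",
                             query_start = "integer", query_end = "integer",
                             ref_id = "character", ref_start = "integer",
                             ref_end = "integer", strand = "character",
                             identity = "numeric"))
  validate_fragments(out)
  out
}

#' @param snps SNP record table.
#' @rdname write_fragments
#' @export
write_snp_records <- function(snps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# alndiff snp records: 0-based positions; '.' marks the gap side",
             con)
  utils::write.table(snps, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments
#' @export
read_snp_records <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE,
                    colClasses = c(
                      frag_id = "integer", kind = "character",
                      ref_pos = "integer", query_pos = "integer",
                      ref_base = "character", query_base = "character"))
}

#' Write all result tracks
#'
#' Convenience writer producing the six GFF3 files (local and structural
#' differences plus mapped blocks, each in query- and reference-based
#' coordinates) and the summary, sharing one filename prefix.
#'
#' @param result an `alndiff_result` from [compare_genomes()].
#' @param outdir output directory (created if needed).
#' @param prefix filename prefix.
#' @return named character vector of the files written.
#' @export
write_results <- function(result, outdir, prefix = "alndiff") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(name) file.path(outdir, paste0(prefix, "_", name))
  files <- c(
    local_query = p("local_query.gff3"),
    local_ref = p("local_ref.gff3"),
    struct_query = p("struct_query.gff3"),
    struct_ref = p("struct_ref.gff3"),
    blocks_query = p("blocks_query.gff3"),
    blocks_ref = p("blocks_ref.gff3"),
    summary = p("summary.txt"))
  d <- result$differences
  write_gff3(d, NULL, "query", "local", files[["local_query"]])
  write_gff3(d, NULL, "reference", "local", files[["local_ref"]])
  write_gff3(d, NULL, "query", "structural", files[["struct_query"]])
  write_gff3(d, NULL, "reference", "structural", files[["struct_ref"]])
  write_gff3(NULL, result$blocks, "query", "blocks", files[["blocks_query"]])
  write_gff3(NULL, result$blocks, "reference", "blocks", files[["blocks_ref"]])
  write_summary(d, files[["summary"]])
  files
}
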