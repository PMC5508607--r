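# Reading MUMmer-family tabular output into the internal model, and the
# optional invocation of external aligner binaries.  The raw delta
# encoding is not parsed: fragments plus per-base SNP records are fully
# available from the tabular show-coords / show-snps dialects.

read_stream_lines <- function(stream) {
  if (is.character(stream) && length(stream) == 1L && file.exists(stream)) {
    readLines(stream)
  } else if (inherits(stream, "connection")) {
    readLines(stream)
  } else {
    as.character(stream)
  }
}

is_data_line <- function(x) grepl("^\\s*[0-9]", x)

#' Parse show-coords tabular output
#'
#' Accepts the compact 7-column tab dialect
#' `S1 E1 S2 E2 %IDY REF QRY` (1-based inclusive; a query row with
#' end < start encodes a reverse-strand match) as written by
#' [write_coords()], or the 9-column `show-coords -T -H` layout with
#' `LEN1 LEN2` columns, which are ignored.  Header and comment lines are
#' skipped; a malformed data row raises an error naming its line number.
#'
#' @param stream file path, connection, or character vector of lines.
#' @return a fragment table (0-based half-open, ascending reference
#'   coordinates, reversal in `strand`).
#' @export
parse_coords <- function(stream) {
  lines <- read_stream_lines(stream)
  rows <- list()
  id <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln)) || !is_data_line(ln)) next
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (!length(f) %in% c(7L, 9L)) {
      stop("parse_coords: malformed row at line ", i, ": ", ln)
    }
    if (length(f) == 9L) f <- f[c(1:4, 7:9)]
    num <- suppressWarnings(as.numeric(f[1:5]))
    if (anyNA(num)) stop("parse_coords: malformed row at line ", i, ": ", ln)
    s1 <- as.integer(num[1]); e1 <- as.integer(num[2])
    s2 <- as.integer(num[3]); e2 <- as.integer(num[4])
    id <- id + 1L
    if (s2 <= e2) {
      qs <- s2 - 1L; qe <- e2; strand <- "+"
    } else {
      qs <- e2 - 1L; qe <- s2; strand <- "-"
    }
    rows[[id]] <- data.frame(
      frag_id = id, query_id = f[7], query_start = qs, query_end = qe,
      ref_id = f[6], ref_start = s1 - 1L, ref_end = e1,
      strand = strand, identity = num[5], stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) {
    as.data.frame(data.table::rbindlist(rows))
  } else empty_fragments()
  validate_fragments(out)
  out
}

#' Write fragments in the 7-column coords dialect
#'
#' Inverse of [parse_coords()]: 1-based inclusive coordinates with the
#' query pair swapped for reverse-strand fragments.
#'
#' @param frags fragment table.
#' @param path output file.
#' @export
write_coords <- function(frags, path) {
  s2 <- ifelse(frags$strand == "+", frags$query_start + 1L, frags$query_end)
  e2 <- ifelse(frags$strand == "+", frags$query_end, frags$query_start + 1L)
  lines <- sprintf("%d\t%d\t%d\t%d\t%.2f\t%s\t%s",
                   frags$ref_start + 1L, frags$ref_end, s2, e2,
                   frags$identity, frags$ref_id, frags$query_id)
  writeLines(lines, path)
  invisible(path)
}

#' Parse show-snps tabular output
#'
#' Accepts the compact 6-column dialect `P1 REF_BASE QUERY_BASE P2
#' REF_ID QUERY_ID` (1-based; `.` marks the gap side) as written by
#' [write_snps()], or wider `show-snps -T -H` layouts, from which the
#' first four and last two columns are used.  Rows with a gap marker on
#' the reference side are insertions (P1 is then the reference position
#' immediately before the inserted base), rows with a gap marker on the
#' query side are deletions; everything else is a substitution.
#' Consecutive inserted bases at one reference position are retained as
#' individual records; grouping into runs happens during detection.
#'
#' @param stream file path, connection, or character vector of lines.
#' @return a SNP record table with `frag_id = NA` (assignment to
#'   fragments happens at comparison time).
#' @export
parse_snps <- function(stream) {
  lines <- read_stream_lines(stream)
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln)) || !is_data_line(ln)) next
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 6L) stop("parse_snps: malformed row at line ", i, ": ", ln)
    p1 <- suppressWarnings(as.integer(f[1]))
    p2 <- suppressWarnings(as.integer(f[4]))
    if (is.na(p1) || is.na(p2)) {
      stop("parse_snps: malformed row at line ", i, ": ", ln)
    }
    rb <- toupper(f[2]); qb <- toupper(f[3])
    n <- length(f)
    if (rb == ".") {
      kind <- "insertion"; ref_pos <- p1; query_pos <- p2 - 1L
    } else if (qb == ".") {
      kind <- "deletion"; ref_pos <- p1 - 1L; query_pos <- p2
    } else {
      kind <- "substitution"; ref_pos <- p1 - 1L; query_pos <- p2 - 1L
    }
    rows[[length(rows) + 1L]] <- data.frame(
      frag_id = NA_integer_, kind = kind, ref_pos = ref_pos,
      query_pos = query_pos, ref_base = rb, query_base = qb,
      ref_id = f[n - 1L], query_id = f[n], stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- snp_records()
    out$ref_id <- character(0); out$query_id <- character(0)
    return(out)
  }
  as.data.frame(data.table::rbindlist(rows))
}

#' Write SNP records in the 6-column snps dialect
#'
#' Inverse of [parse_snps()].  `ref_id`/`query_id` columns are used when
#' present; otherwise ids are looked up from `frags` via `frag_id`.
#'
#' @param snps SNP record table.
#' @param path output file.
#' @param frags optional fragment table for id lookup.
#' @export
write_snps <- function(snps, path, frags = NULL) {
  rid <- snps$ref_id
  qid <- snps$query_id
  if (is.null(rid) || is.null(qid)) {
    stopifnot(!is.null(frags))
    idx <- match(snps$frag_id, frags$frag_id)
    rid <- frags$ref_id[idx]
    qid <- frags$query_id[idx]
  }
  p1 <- ifelse(snps$kind == "insertion", snps$ref_pos, snps$ref_pos + 1L)
  p2 <- ifelse(snps$kind == "deletion", snps$query_pos, snps$query_pos + 1L)
  lines <- sprintf("%d\t%s\t%s\t%d\t%s\t%s",
                   p1, snps$ref_base, snps$query_base, p2, rid, qid)
  writeLines(lines, path)
  invisible(path)
}

#' Run the external MUMmer aligner pipeline
#'
#' Invokes `nucmer`, `delta-filter -q` (longest consistent query
#' alignments), `show-coords -T -H` and `show-snps -T -H` with the
#' thresholds mapped from `config` (`-c`, `-l`, `-b`, `-i`), and parses
#' the results into the internal fragment/SNP model.  The binaries are
#' optional: when any of them is not on the PATH this function stops
#' with an explicit error instructing use of the built-in aligner — it
#' never falls back silently.
#'
#' @param ref_fasta,query_fasta FASTA file paths.
#' @param config an [diff_config()].
#' @param workdir scratch directory for intermediate files.
#' @return list with `fragments` and `snps`.
#' @export
run_external_aligner <- function(ref_fasta, query_fasta,
                                 config = diff_config(),
                                 workdir = tempfile("alndiff_mummer")) {
  bins <- c("nucmer", "delta-filter", "show-coords", "show-snps")
  found <- Sys.which(bins)
  if (any(found == "")) {
    stop("external aligner binaries not found on PATH: ",
         paste(bins[found == ""], collapse = ", "),
         ". Use the built-in aligner (align_genomes / compare_genomes) ",
         "instead.")
  }
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  prefix <- file.path(workdir, "aln")
  run <- function(cmd, args, stdout = TRUE) {
    out <- suppressWarnings(system2(cmd, args, stdout = stdout,
                                    stderr = TRUE))
    status <- attr(out, "status")
    if (!is.null(status) && status != 0) {
      stop(cmd, " failed (exit ", status, "): ",
           paste(utils::tail(out, 5), collapse = " | "))
    }
    out
  }
  run("nucmer", c("-c", config$min_cluster_len, "-l", config$min_match_len,
                  "-b", config$extension_distance, "-p", prefix,
                  ref_fasta, query_fasta))
  filt <- run("delta-filter", c("-q", "-i", config$min_identity,
                                paste0(prefix, ".delta")))
  writeLines(filt, paste0(prefix, ".qdelta"))
  coords <- run("show-coords", c("-T", "-H", paste0(prefix, ".qdelta")))
  snps <- run("show-snps", c("-T", "-H", paste0(prefix, ".qdelta")))
  frags <- parse_coords(coords)
  list(fragments = frags, snps = parse_snps(snps))
}
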