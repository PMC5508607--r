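#' Sequence sets
#'
#' A sequence set is a named character vector of nucleotide sequences
#' (residues A, C, G, T, N) with a `role` attribute marking it as the
#' reference or the query side of a comparison.  Input is normalized to
#' upper case and validated; sequence ids must be unique.
#'
#' @param x named character vector, named list of single strings, or a
#'   `Biostrings::DNAStringSet`.
#' @param role `"reference"` or `"query"`.
#' @return an object of class `sequence_set`.
#' @examples
#' ss <- sequence_set(c(chr1 = "acgtn"), role = "reference")
#' ss[["chr1"]]
#' @export
sequence_set <- function(x, role = c("reference", "query")) {
  role <- match.arg(role)
  if (methods::is(x, "DNAStringSet")) {
    x <- stats::setNames(as.character(x), names(x))
  }
  if (is.list(x)) x <- unlist(x)
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
    stop("all sequences must be named")
  }
  if (anyDuplicated(names(x))) {
    stop("duplicate sequence ids: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  }
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("sequence(s) contain residues outside {A,C,G,T,N}: ",
         paste(names(x)[bad], collapse = ", "))
  }
  structure(x, role = role, class = "sequence_set")
}

as_sequence_set <- function(x, role) {
  if (inherits(x, "sequence_set")) return(x)
  sequence_set(x, role)
}

#' @export
print.sequence_set <- function(x, ...) {
  cat(sprintf("<sequence_set role=%s> %d sequence(s)\n",
              attr(x, "role"), length(x)))
  for (id in names(x)) cat(sprintf("  %s: %d bp\n", id, nchar(x[[id]])))
  invisible(x)
}

#' @export
`[.sequence_set` <- function(x, i) {
  structure(NextMethod(), role = attr(x, "role"), class = "sequence_set")
}

#' Sequence lengths of a set
#' @param x a [sequence_set()].
#' @return named integer vector of lengths.
#' @export
seq_lengths <- function(x) {
  stats::setNames(nchar(unclass(x)), names(x))
}

# reverse complement of a plain character string (N maps to N)
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# 0-based half-open substring
substr0 <- function(s, start, end) {
  if (end <= start) return("")
  substr(s, start + 1L, end)
}

#' Read / write FASTA
#'
#' Thin wrappers around Biostrings FASTA I/O returning/accepting
#' [sequence_set()] objects.
#'
#' @param path file path.
#' @param role role for the returned set.
#' @export
read_fasta <- function(path, role = c("reference", "query")) {
  role <- match.arg(role)
  sequence_set(Biostrings::readDNAStringSet(path), role = role)
}

#' @param x a [sequence_set()].
#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  dss <- Biostrings::DNAStringSet(unclass(x))
  Biostrings::writeXStringSet(dss, filepath = path)
  invisible(path)
}
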