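# Transcript containers and FASTA input/output.

#' Construct a transcript set
#'
#' An ordered collection of uni-transcript records.  Sequences are folded to
#' upper case; only A,C,G,T,N are accepted.  Ids must be unique, non-empty
#' and free of whitespace.
#'
#' @param id character vector of record identifiers.
#' @param seq character vector of nucleotide sequences (same length as `id`).
#' @param description optional character vector of free-text descriptions
#'   (the FASTA header after the first whitespace); retained but unused.
#' @return an object of class `transcript_set`: a data frame with columns
#'   `id`, `seq`, `description`.
#' @seealso [read_fasta()], [write_fasta()], [total_length_bp()]
#' @export
transcript_set <- function(id, seq, description = NULL) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) stop("id and seq lengths differ")
  if (is.null(description)) description <- rep("", length(id))
  if (any(is.na(id) | id == "")) stop("malformed header: empty id")
  if (any(grepl("[[:space:]]", id))) stop("id contains whitespace")
  dup <- unique(id[duplicated(id)])
  if (length(dup)) {
    stop("duplicate id(s): ", paste(dup, collapse = ", "))
  }
  if (any(nchar(seq) == 0L)) {
    stop("empty sequence for record(s): ",
         paste(id[nchar(seq) == 0L], collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop("illegal character (outside A,C,G,T,N) in record(s): ",
         paste(id[bad], collapse = ", "))
  }
  structure(
    data.frame(id = id, seq = seq, description = as.character(description),
               stringsAsFactors = FALSE),
    class = c("transcript_set", "data.frame"))
}

#' Total sequence length of a transcript set
#'
#' @param x a `transcript_set`.
#' @return integer: sum of record lengths in bp.
#' @export
total_length_bp <- function(x) {
  stopifnot(inherits(x, "transcript_set"))
  sum(nchar(x$seq))
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set: ", nrow(x), " record(s), ",
      format(total_length_bp(x), big.mark = ","), " bp total\n", sep = "")
  if (nrow(x)) {
    show <- utils::head(x, 5L)
    cat(paste0("  ", show$id, " (", nchar(show$seq), " bp)"), sep = "\n")
    if (nrow(x) > 5L) cat("  ...\n")
  }
  invisible(x)
}

#' Read transcript sequences from a FASTA file
#'
#' Multi-line records are joined and lower-case bases folded to upper case.
#' The record id is the header up to the first whitespace; the remainder is
#' kept as the description.  Characters outside A,C,G,T,N, empty sequences,
#' malformed headers and duplicate ids are each rejected with a distinct
#' error.
#'
#' @param path path to a FASTA file.
#' @return a [transcript_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  bs <- Biostrings::readBStringSet(path)
  headers <- names(bs)
  if (is.null(headers)) headers <- rep("", length(bs))
  ids <- sub("[[:space:]].*$", "", headers)
  desc <- ifelse(grepl("[[:space:]]", headers),
                 sub("^[^[:space:]]*[[:space:]]+", "", headers), "")
  transcript_set(id = ids, seq = as.character(bs), description = desc)
}

#' Write a transcript set to a FASTA file
#'
#' @param x a `transcript_set`.
#' @param path output path.
#' @param width line width for wrapped sequence (default 60).
#' @return invisibly, `path`.
#' @export
write_fasta <- function(x, path, width = 60L) {
  stopifnot(inherits(x, "transcript_set"))
  headers <- ifelse(x$description == "", x$id,
                    paste(x$id, x$description))
  bs <- Biostrings::BStringSet(stats::setNames(x$seq, headers))
  Biostrings::writeXStringSet(bs, filepath = path, width = as.integer(width))
  invisible(path)
}
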