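# Catalogue, primer-table and band-matrix input/output.

LOCUS_COLUMNS <- c("transcript_id", "start", "end", "motif",
                   "canonical_class", "unit_size", "copies", "tract_length",
                   "classification", "component_motifs")

#' Write an SSR catalogue to TSV or GFF3
#'
#' Internal coordinates are 0-based half-open; the GFF3 export converts to
#' the standard 1-based inclusive convention (a locus at \[10,26) becomes
#' `start=11 end=26`).  GFF3 features have type "microsatellite" and carry
#' the catalogue fields as percent-encoded attributes.
#'
#' @param loci a locus data frame from [classify_catalogue()] or
#'   [find_perfect_ssrs()].
#' @param path output path.
#' @param format "tsv" (default) or "gff3".
#' @param transcript_set optional `transcript_set`; when given, loci that
#'   reference unknown transcript ids are an error.
#' @return invisibly, `path`.
#' @export
write_catalogue <- function(loci, path, format = c("tsv", "gff3"),
                            transcript_set = NULL) {
  format <- match.arg(format)
  stopifnot(is.data.frame(loci), all(LOCUS_COLUMNS %in% names(loci)))
  loci <- loci[, LOCUS_COLUMNS, drop = FALSE]
  if (!is.null(transcript_set)) {
    unknown <- setdiff(loci$transcript_id, transcript_set$id)
    if (length(unknown)) {
      stop("loci reference unknown transcript id(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  if (format == "tsv") {
    utils::write.table(loci, file = path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    enc <- function(x) {
      x <- as.character(x)
      x[is.na(x)] <- "NA"
      vapply(x, utils::URLencode, character(1), reserved = TRUE,
             USE.NAMES = FALSE)
    }
    attrs <- paste0(
      "ID=", enc(paste0(loci$transcript_id, ".ssr", seq_len(nrow(loci)))),
      ";motif=", enc(loci$motif),
      ";canonical_class=", enc(loci$canonical_class),
      ";unit_size=", enc(loci$unit_size),
      ";copies=", enc(loci$copies),
      ";tract_length=", enc(loci$tract_length),
      ";classification=", enc(loci$classification),
      ";component_motifs=", enc(loci$component_motifs))
    if (!nrow(loci)) attrs <- character(0)
    lines <- c("##gff-version 3",
               paste(loci$transcript_id, "ssrmine", "microsatellite",
                     loci$start + 1L, loci$end, ".", "+", ".", attrs,
                     sep = "\t"))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read an SSR catalogue from TSV
#'
#' Inverse of `write_catalogue(..., format = "tsv")`; round-trips a
#' catalogue exactly.
#'
#' @param path path to a catalogue TSV.
#' @return a locus data frame.
#' @export
read_catalogue <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  out <- utils::read.delim(
    path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
    na.strings = "NA",
    colClasses = c(transcript_id = "character", start = "integer",
                   end = "integer", motif = "character",
                   canonical_class = "character", unit_size = "integer",
                   copies = "integer", tract_length = "integer",
                   classification = "character",
                   component_motifs = "character"))
  if (!identical(names(out), LOCUS_COLUMNS)) {
    stop("not a catalogue TSV (unexpected columns)")
  }
  out$motif[is.na(out$motif)] <- ""
  out$component_motifs[is.na(out$component_motifs)] <- ""
  out
}

#' Write a primer table to TSV
#'
#' @param primers a primer-pair data frame from [design_primers()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_primer_table <- function(primers, path) {
  utils::write.table(primers, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read / write genotype band tables
#'
#' Band matrices are exchanged as long-format CSV with columns `marker`,
#' `accession`, `band` (band size in bp; empty/NA = no amplification for
#' that marker-accession pair).
#'
#' @param path CSV path.
#' @return for `read_bands`, a [genotype_matrix()].
#' @export
read_bands <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("marker", "accession", "band") %in% names(df))) {
    stop("bands CSV must have columns marker, accession, band")
  }
  genotype_matrix(df)
}

#' @rdname read_bands
#' @param gm a `genotype_matrix`.
#' @export
write_bands <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  utils::write.csv(gm$bands, file = path, row.names = FALSE, na = "")
  invisible(path)
}
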