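# Canonical motif classes.
#
# A repeat motif is identified up to cyclic rotation and reverse complement:
# (TC)n, (CT)n, (GA)n and (AG)n tracts are all occurrences of the AG/CT
# class.  The class representative is the lexicographically smallest string
# in the closure {rotations(motif)} U {rotations(revcomp(motif))}.

#' Reverse complement of nucleotide strings
#'
#' @param seq character vector of sequences over A,C,G,T,N.
#' @return character vector of reverse complements.
#' @examples
#' revcomp("GAA")  # "TTC"
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# All cyclic rotations of a motif.
rotations <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(motif)
  doubled <- paste0(motif, motif)
  vapply(seq_len(k), function(i) substr(doubled, i, i + k - 1L), character(1))
}

#' Is a motif primitive?
#'
#' A motif is primitive when it is not itself a tandem repetition of a
#' shorter unit ("AG" is primitive, "AGAG" and "AAA" are not).  Repeat loci
#' are always reported under their primitive unit.
#'
#' @param motif a single motif string.
#' @return logical scalar.
#' @export
is_primitive_motif <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L && strrep(substr(motif, 1L, d), k / d) == motif) {
      return(FALSE)
    }
  }
  TRUE
}

# Memoised canonical representative (mining calls this per detected run).
.canon_cache <- new.env(parent = emptyenv())

canonical_rep <- function(motif) {
  hit <- .canon_cache[[motif]]
  if (!is.null(hit)) return(hit)
  members <- unique(c(rotations(motif), rotations(revcomp(motif))))
  rep <- min(members)
  assign(motif, rep, envir = .canon_cache)
  rep
}

#' Canonical motif class of a repeat unit
#'
#' Maps a 1-6 bp repeat unit to its equivalence class under cyclic rotation
#' and reverse complement.  The representative is the lexicographically
#' smallest member of the closure; the display label pairs it with its
#' reverse complement (e.g. "AG/CT").  Published catalogues sometimes label
#' a family by a non-minimal member (CA/TG rather than AC/GT); class
#' membership, not the label, is what identifies a family.
#'
#' @param motif a single repeat unit over A,C,G,T; must be primitive.
#' @return an object of class `motif_class` with fields `representative`,
#'   `display_pair`, `unit_size` and `members`.
#' @examples
#' canonical_motif_class("TC")$display_pair    # "AG/CT"
#' canonical_motif_class("GTAT")$representative  # same class as "ATAC"
#' @export
canonical_motif_class <- function(motif) {
  if (!is.character(motif) || length(motif) != 1L || is.na(motif)) {
    stop("motif must be a single string")
  }
  motif <- toupper(motif)
  k <- nchar(motif)
  if (k < 1L || k > 6L) stop("motif must be 1-6 bp, got ", k, " bp")
  if (grepl("[^ACGT]", motif)) {
    stop("motif contains characters outside {A,C,G,T}: ", motif)
  }
  if (!is_primitive_motif(motif)) {
    stop("motif is not primitive (a tandem repeat of a shorter unit): ",
         motif)
  }
  members <- sort(unique(c(rotations(motif), rotations(revcomp(motif)))))
  rep <- members[1L]
  structure(
    list(representative = rep,
         display_pair = paste0(rep, "/", revcomp(rep)),
         unit_size = k,
         members = members),
    class = "motif_class")
}

#' @export
print.motif_class <- function(x, ...) {
  cat("Motif class ", x$display_pair, " (unit size ", x$unit_size, ")\n",
      "  members: ", paste(x$members, collapse = " "), "\n", sep = "")
  invisible(x)
}
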