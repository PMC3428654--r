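# Catalogue summary statistics: the counts, frequencies, densities and
# copy-number distributions a genic-SSR survey reports.

#' Summarise an SSR catalogue
#'
#' Produces disjoint counts by classification, by unit size within each
#' classification, by canonical motif class, and the per-unit copy-number
#' histogram of perfect loci, together with density and incidence when the
#' transcript totals are known.  All marginals are consistent: the four
#' classification counts sum to `n_ssrs`, and each classification's
#' unit-size (or compound-subtype) counts sum to that classification's
#' total.  Frequencies are kept exact internally; presentation rounding is
#' the print method's job.
#'
#' @param loci a locus data frame from [classify_catalogue()].
#' @param transcript_set optional `transcript_set` the catalogue was mined
#'   from; loci referencing unknown transcripts are an error.
#' @param threshold_bp the `min_tract_bp` the catalogue was produced under.
#' @return an object of class `catalogue_summary`.
#' @export
summarize_catalogue <- function(loci, transcript_set = NULL,
                                threshold_bp = 18L) {
  stopifnot(is.data.frame(loci))
  if (!is.null(transcript_set)) {
    unknown <- setdiff(loci$transcript_id, transcript_set$id)
    if (length(unknown)) {
      stop("loci reference unknown transcript id(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  classes <- c("perfect", "imperfect", "compound_perfect",
               "compound_imperfect")
  by_classification <- vapply(classes, function(cl)
    sum(loci$classification == cl), integer(1))
  unit_names <- c("mono", "di", "tri", "tetra", "penta", "hexa")
  by_unit_size <- lapply(c("perfect", "imperfect"), function(cl) {
    sub <- loci[loci$classification == cl, , drop = FALSE]
    counts <- vapply(1:6, function(k) sum(sub$unit_size == k), integer(1))
    stats::setNames(counts, unit_names)
  })
  names(by_unit_size) <- c("perfect", "imperfect")
  by_compound_subtype <- lapply(
    c("compound_perfect", "compound_imperfect"), function(cl) {
      sub <- loci[loci$classification == cl, , drop = FALSE]
      if (!nrow(sub)) return(stats::setNames(integer(0), character(0)))
      tab <- table(compound_subtype(sub$component_motifs))
      stats::setNames(as.integer(tab), names(tab))
    })
  names(by_compound_subtype) <- c("compound_perfect", "compound_imperfect")
  perf <- loci[loci$classification == "perfect", , drop = FALSE]
  by_motif_class <- if (nrow(perf)) {
    tab <- sort(table(perf$canonical_class), decreasing = TRUE)
    stats::setNames(as.integer(tab), names(tab))
  } else stats::setNames(integer(0), character(0))
  copy_number_histogram <- lapply(1:6, function(k) {
    sub <- perf[perf$unit_size == k, , drop = FALSE]
    if (!nrow(sub)) return(stats::setNames(integer(0), character(0)))
    tab <- table(sub$copies)
    stats::setNames(as.integer(tab), names(tab))
  })
  names(copy_number_histogram) <- unit_names
  n_transcripts <- if (is.null(transcript_set)) NA_integer_ else
    nrow(transcript_set)
  total_bp <- if (is.null(transcript_set)) NA_integer_ else
    total_length_bp(transcript_set)
  structure(
    list(n_ssrs = nrow(loci),
         by_classification = by_classification,
         by_unit_size = by_unit_size,
         by_compound_subtype = by_compound_subtype,
         by_motif_class = by_motif_class,
         copy_number_histogram = copy_number_histogram,
         n_transcripts = n_transcripts,
         total_length_bp = total_bp,
         threshold_bp = as.integer(threshold_bp)),
    class = "catalogue_summary")
}

#' @export
print.catalogue_summary <- function(x, ...) {
  cat("SSR catalogue summary (tract >= ", x$threshold_bp, " bp)\n",
      sep = "")
  cat("  loci: ", x$n_ssrs, sep = "")
  if (!is.na(x$n_transcripts)) {
    cat(" in ", x$n_transcripts, " transcripts (",
        format(x$total_length_bp, big.mark = ","), " bp)", sep = "")
  }
  cat("\n  by classification:\n")
  for (cl in names(x$by_classification)) {
    n <- x$by_classification[[cl]]
    pct <- if (x$n_ssrs > 0) round_half_up(100 * n / x$n_ssrs) else 0
    cat(sprintf("    %-19s %6d  (%.2f%%)\n", cl, n, pct))
  }
  if (length(x$by_motif_class)) {
    top <- utils::head(x$by_motif_class, 5L)
    cat("  top perfect motif classes: ",
        paste0(names(top), "=", top, collapse = ", "), "\n", sep = "")
  }
  if (!is.na(x$total_length_bp) && x$n_ssrs > 0) {
    cat("  density: one SSR per ",
        density_kb_per_ssr(x$total_length_bp, x$n_ssrs), " kb\n", sep = "")
  }
  invisible(x)
}

#' Repeat density in kb per SSR
#'
#' @param total_length_bp total sequence length surveyed, in bp.
#' @param n_ssrs number of SSR loci found.
#' @return kb of sequence per SSR, rounded half-up to 2 decimals;
#'   `NA` (with a warning) when `n_ssrs` is zero.
#' @examples
#' density_kb_per_ssr(47986977, 7324)  # 6.55
#' density_kb_per_ssr(47986977, 4440)  # 10.81
#' @export
density_kb_per_ssr <- function(total_length_bp, n_ssrs) {
  if (n_ssrs == 0) {
    warning("density undefined for an empty catalogue")
    return(NA_real_)
  }
  round_half_up((total_length_bp / 1000) / n_ssrs, 2)
}

#' SSR incidence as a percentage of transcripts
#'
#' The count ratio `100 * n_ssrs / n_transcripts`, the convention used in
#' genic-SSR surveys.  Note this is a per-transcript rate, not the fraction
#' of transcripts that contain at least one SSR (a transcript with two loci
#' counts twice in the numerator).
#'
#' @param n_ssrs number of SSR loci.
#' @param n_transcripts number of transcripts surveyed (> 0).
#' @return percentage, rounded half-up to 2 decimals.
#' @examples
#' incidence_pct(7324, 42566)  # 17.21
#' @export
incidence_pct <- function(n_ssrs, n_transcripts) {
  if (n_transcripts <= 0) stop("n_transcripts must be positive")
  round_half_up(100 * n_ssrs / n_transcripts, 2)
}

#' Filter a copy-number histogram by tract-length threshold
#'
#' Given the copy-number histogram of one unit size, returns the number of
#' loci whose tract (copies x unit size) reaches `min_tract_bp`.  Applying
#' the 18 bp filter to a >=15 bp histogram reconstructs the >=18 bp
#' per-unit totals.
#'
#' @param histogram named numeric vector: names are copy numbers, values
#'   are locus counts.
#' @param unit_size repeat unit size in bp (1-6).
#' @param min_tract_bp tract-length threshold in bp.
#' @return total count of loci passing the threshold.
#' @export
apply_length_threshold <- function(histogram, unit_size, min_tract_bp) {
  if (!length(histogram)) return(0L)
  copies <- as.integer(names(histogram))
  if (anyNA(copies) || any(copies < 1L)) {
    stop("histogram names must be copy numbers >= 1")
  }
  sum(histogram[copies * unit_size >= min_tract_bp])
}

#' Ranked copy-number modes
#'
#' Ranks copy numbers by total locus count across unit sizes and reports
#' each copy number's share of the catalogue.  Ties rank by ascending copy
#' number.
#'
#' @param histogram either a data frame whose first column is `copies` and
#'   remaining columns are per-unit-size counts (the layout of the packaged
#'   copy-number fixture), or a named numeric vector of total counts by
#'   copy number.
#' @return a data frame with columns `copies`, `count`, `share_pct`
#'   (rounded half-up to 2 decimals), ordered by rank.
#' @export
copy_number_modes <- function(histogram) {
  if (is.data.frame(histogram)) {
    copies <- as.integer(histogram[[1L]])
    count <- rowSums(histogram[, -1L, drop = FALSE])
  } else {
    copies <- as.integer(names(histogram))
    count <- as.numeric(histogram)
  }
  if (!length(copies) || sum(count) == 0) stop("empty histogram")
  keep <- count > 0
  copies <- copies[keep]; count <- count[keep]
  ord <- order(-count, copies)
  data.frame(copies = copies[ord], count = count[ord],
             share_pct = round_half_up(100 * count[ord] / sum(count), 2),
             row.names = NULL)
}
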