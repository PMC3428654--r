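# SSR detection and classification.
#
# The detector reports maximal perfect tandem runs of primitive 1-6 bp units
# and then assembles the catalogue taxonomy:
#   perfect            one uninterrupted run
#   imperfect          >=2 runs of the same canonical class separated by
#                      short (1-4 bp) interruptions
#   compound_perfect   adjacent runs of different classes (or of the same
#                      class when each run alone passes the length
#                      threshold) separated by a short spacer
#   compound_imperfect a compound locus in which a component is itself
#                      interrupted
# Precedence is compound > imperfect > perfect; every base belongs to at
# most one reported locus, so class counts are disjoint.

#' Mining configuration
#'
#' Tunable parameters of the SSR detector and classifier.
#'
#' @param min_tract_bp minimum total tract length in bp of a reported locus
#'   (applies to the full span of imperfect/compound loci). The two
#'   conventional settings are 18 (default) and 15.
#' @param unit_sizes repeat unit sizes to scan, a subset of 1:6.
#' @param imperfect_max_gap_bp largest interruption (bp) joining two
#'   same-class runs into an imperfect locus (default 4).
#' @param imperfect_min_run_copies minimum full copies per component run of
#'   an imperfect locus (default 2).
#' @param imperfect_unit_sizes unit sizes allowed to form imperfect loci
#'   (default 1:3; larger units are never observed as imperfect in genic-SSR
#'   surveys).
#' @param compound_max_spacer_bp largest spacer (bp) between the components
#'   of a compound locus (default 10).
#' @param compound_min_component_bp minimum tract length (bp) of a run
#'   eligible to be a compound component (default 6); keeps incidental
#'   two-copy micro-runs next to a real SSR from being promoted to compound
#'   status.
#' @return an object of class `mining_config`.
#' @export
mining_config <- function(min_tract_bp = 18L,
                          unit_sizes = 1:6,
                          imperfect_max_gap_bp = 4L,
                          imperfect_min_run_copies = 2L,
                          imperfect_unit_sizes = 1:3,
                          compound_max_spacer_bp = 10L,
                          compound_min_component_bp = 6L) {
  unit_sizes <- sort(unique(as.integer(unit_sizes)))
  if (!all(unit_sizes %in% 1:6)) stop("unit_sizes must be a subset of 1:6")
  min_tract_bp <- as.integer(min_tract_bp)
  if (min_tract_bp < max(unit_sizes)) {
    stop("min_tract_bp must be at least the largest unit size scanned")
  }
  if (imperfect_max_gap_bp < 0L || compound_max_spacer_bp < 0L) {
    stop("gap and spacer parameters must be >= 0")
  }
  if (imperfect_min_run_copies < 1L) {
    stop("imperfect_min_run_copies must be >= 1")
  }
  structure(
    list(min_tract_bp = min_tract_bp,
         unit_sizes = unit_sizes,
         imperfect_max_gap_bp = as.integer(imperfect_max_gap_bp),
         imperfect_min_run_copies = as.integer(imperfect_min_run_copies),
         imperfect_unit_sizes = as.integer(imperfect_unit_sizes),
         compound_max_spacer_bp = as.integer(compound_max_spacer_bp),
         compound_min_component_bp = as.integer(compound_min_component_bp)),
    class = "mining_config")
}

#' @export
print.mining_config <- function(x, ...) {
  cat("mining_config: min tract ", x$min_tract_bp, " bp, units {",
      paste(x$unit_sizes, collapse = ","), "}, imperfect gap <= ",
      x$imperfect_max_gap_bp, " bp, compound spacer <= ",
      x$compound_max_spacer_bp, " bp\n", sep = "")
  invisible(x)
}

# Empty locus table with the canonical column layout.
empty_locus_df <- function() {
  data.frame(transcript_id = character(0), start = integer(0),
             end = integer(0), motif = character(0),
             canonical_class = character(0), unit_size = integer(0),
             copies = integer(0), tract_length = integer(0),
             classification = character(0), component_motifs = character(0),
             stringsAsFactors = FALSE)
}

# Maximal perfect tandem runs (>=2 full copies, primitive unit, no length
# threshold).  Coordinates are 0-based half-open.  A run of a non-primitive
# unit (e.g. (AGAG)n) is reported only under its primitive unit ((AG)n).
# N never matches any base, so runs never cross N.
find_perfect_runs <- function(seq, unit_sizes = 1:6) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  res <- vector("list", length(unit_sizes))
  for (j in seq_along(unit_sizes)) {
    k <- unit_sizes[j]
    if (n < 2L * k) next
    eq <- chars[seq_len(n - k)] == chars[(k + 1L):n] &
      chars[seq_len(n - k)] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    keep <- which(r$values & r$lengths >= k)
    if (!length(keep)) next
    a <- ends[keep] - r$lengths[keep] + 1L   # 1-based start of period run
    span <- r$lengths[keep] + k
    copies <- span %/% k
    motif <- substring(seq, a, a + k - 1L)
    prim <- vapply(motif, is_primitive_motif, logical(1), USE.NAMES = FALSE)
    if (!any(prim)) next
    a <- a[prim]; copies <- copies[prim]; motif <- motif[prim]
    res[[j]] <- data.frame(
      start = a - 1L,
      end = a - 1L + copies * k,
      motif = motif,
      canonical_class = vapply(motif, canonical_rep, character(1),
                               USE.NAMES = FALSE),
      unit_size = k,
      copies = copies,
      tract_length = copies * k,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(start = integer(0), end = integer(0),
                      motif = character(0), canonical_class = character(0),
                      unit_size = integer(0), copies = integer(0),
                      tract_length = integer(0), stringsAsFactors = FALSE)
  }
  out[order(out$start, out$unit_size), , drop = FALSE]
}

# Resolve overlaps between runs of different unit sizes: the longer tract
# wins, ties go to the smaller unit, then to the earlier start.  The
# survivors are pairwise disjoint, which makes downstream class counts
# disjoint as well.
resolve_run_overlaps <- function(runs) {
  if (nrow(runs) < 2L) return(runs)
  ord <- order(-runs$tract_length, runs$unit_size, runs$start)
  keep <- logical(nrow(runs))
  ks <- integer(0); ke <- integer(0)
  for (i in ord) {
    if (!any(runs$start[i] < ke & runs$end[i] > ks)) {
      keep[i] <- TRUE
      ks <- c(ks, runs$start[i]); ke <- c(ke, runs$end[i])
    }
  }
  out <- runs[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Detect perfect SSR loci
#'
#' Reports every maximal perfect tandem run (primitive 1-6 bp unit, >=2 full
#' copies) whose tract length reaches `config$min_tract_bp`.  Runs of
#' different unit sizes may overlap here; [classify_catalogue()] resolves
#' overlaps when building the disjoint catalogue.
#'
#' @param x a `transcript_set`, or a single nucleotide string.
#' @param config a [mining_config()].
#' @return a locus data frame with columns `transcript_id`, `start`, `end`
#'   (0-based half-open), `motif`, `canonical_class`, `unit_size`, `copies`,
#'   `tract_length`, `classification` ("perfect"), `component_motifs`.
#' @examples
#' find_perfect_ssrs(paste0(strrep("CTGA", 5), strrep("AG", 26),
#'                          strrep("TCAG", 5)))
#' @export
find_perfect_ssrs <- function(x, config = mining_config()) {
  x <- as_transcript_input(x)
  out <- lapply(seq_len(nrow(x)), function(i) {
    runs <- find_perfect_runs(x$seq[i], config$unit_sizes)
    runs <- runs[runs$tract_length >= config$min_tract_bp, , drop = FALSE]
    if (!nrow(runs)) return(NULL)
    data.frame(transcript_id = x$id[i], runs[, c("start", "end", "motif",
               "canonical_class", "unit_size", "copies", "tract_length")],
               classification = "perfect", component_motifs = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty_locus_df() else `rownames<-`(out, NULL)
}

# --- classification pipeline ------------------------------------------------

# Group disjoint, position-sorted runs into elements: an element is either a
# single run or an imperfect group (same-class runs joined across 1-4 bp
# interruptions).  A same-class pair in which both runs independently pass
# the length threshold within compound spacer range is a compound pair and is
# deliberately NOT merged here (precedence compound > imperfect).
group_elements <- function(runs, config) {
  m <- nrow(runs)
  el <- integer(m)
  el[1L] <- 1L
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      g <- runs$start[i + 1L] - runs$end[i]
      same <- runs$canonical_class[i + 1L] == runs$canonical_class[i]
      compound_same <- same &&
        g <= config$compound_max_spacer_bp &&
        min(runs$tract_length[i], runs$tract_length[i + 1L]) >=
          config$min_tract_bp
      imp <- same && !compound_same &&
        g >= 1L && g <= config$imperfect_max_gap_bp &&
        min(runs$copies[i], runs$copies[i + 1L]) >=
          config$imperfect_min_run_copies &&
        runs$unit_size[i] %in% config$imperfect_unit_sizes
      el[i + 1L] <- if (imp) el[i] else el[i] + 1L
    }
  }
  idx <- split(seq_len(m), el)
  data.frame(
    start = vapply(idx, function(j) runs$start[j[1L]], integer(1)),
    end = vapply(idx, function(j) runs$end[j[length(j)]], integer(1)),
    canonical_class = vapply(idx, function(j) runs$canonical_class[j[1L]],
                             character(1)),
    unit_size = vapply(idx, function(j) runs$unit_size[j[1L]], integer(1)),
    copies = vapply(idx, function(j) sum(runs$copies[j]), integer(1)),
    n_runs = lengths(idx),
    motifs = vapply(idx, function(j) paste(runs$motif[j], collapse = "+"),
                    character(1)),
    first_motif = vapply(idx, function(j) runs$motif[j[1L]], character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

# Chain elements into compound loci: consecutive elements within spacer
# range whose classes differ (or whose classes match while both spans pass
# the length threshold), each large enough to count as a component.
chain_elements <- function(els, config) {
  p <- nrow(els)
  ch <- integer(p)
  ch[1L] <- 1L
  if (p > 1L) {
    for (i in seq_len(p - 1L)) {
      g <- els$start[i + 1L] - els$end[i]
      span_i <- els$end[i] - els$start[i]
      span_j <- els$end[i + 1L] - els$start[i + 1L]
      same <- els$canonical_class[i + 1L] == els$canonical_class[i]
      link <- g <= config$compound_max_spacer_bp &&
        min(span_i, span_j) >= config$compound_min_component_bp &&
        (!same || min(span_i, span_j) >= config$min_tract_bp)
      ch[i + 1L] <- if (link) ch[i] else ch[i] + 1L
    }
  }
  ch
}

classify_one <- function(id, seq, config, runs = NULL) {
  if (is.null(runs)) runs <- find_perfect_runs(seq, config$unit_sizes)
  if (!nrow(runs)) return(empty_locus_df())
  runs <- resolve_run_overlaps(runs)
  els <- group_elements(runs, config)
  ch <- chain_elements(els, config)
  loci <- lapply(split(seq_len(nrow(els)), ch), function(j) {
    e <- els[j, , drop = FALSE]
    start <- e$start[1L]; end <- e$end[nrow(e)]
    if (nrow(e) >= 2L) {             # compound chain
      cls <- if (all(e$n_runs == 1L)) "compound_perfect" else
        "compound_imperfect"
      data.frame(transcript_id = id, start = start, end = end,
                 motif = paste(e$motifs, collapse = ";"),
                 canonical_class = paste(e$canonical_class, collapse = ";"),
                 unit_size = NA_integer_, copies = sum(e$copies),
                 tract_length = end - start, classification = cls,
                 component_motifs = paste(e$motifs, collapse = ";"),
                 stringsAsFactors = FALSE)
    } else if (e$n_runs > 1L) {      # lone imperfect group
      data.frame(transcript_id = id, start = start, end = end,
                 motif = e$first_motif, canonical_class = e$canonical_class,
                 unit_size = e$unit_size, copies = e$copies,
                 tract_length = end - start, classification = "imperfect",
                 component_motifs = e$motifs, stringsAsFactors = FALSE)
    } else {                         # lone perfect run
      data.frame(transcript_id = id, start = start, end = end,
                 motif = e$first_motif, canonical_class = e$canonical_class,
                 unit_size = e$unit_size, copies = e$copies,
                 tract_length = end - start, classification = "perfect",
                 component_motifs = "", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, loci)
  out <- out[out$tract_length >= config$min_tract_bp, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the full SSR catalogue of a transcript set
#'
#' Builds the disjoint catalogue: maximal perfect runs are detected,
#' overlaps between unit sizes resolved (longer tract wins, ties to the
#' smaller unit), same-class runs joined across short interruptions into
#' imperfect loci, and adjacent components assembled into compound loci.
#' Precedence is compound > imperfect > perfect: a run consumed by a
#' compound locus is not also reported on its own, and each base belongs to
#' at most one reported locus.
#'
#' @inheritParams find_perfect_ssrs
#' @return a locus data frame (see [find_perfect_ssrs()]) whose
#'   `classification` column takes values in perfect, imperfect,
#'   compound_perfect, compound_imperfect.  For compound loci
#'   `component_motifs` encodes the joined components: elements separated by
#'   ";", runs within an interrupted element by "+".
#' @export
classify_catalogue <- function(x, config = mining_config()) {
  x <- as_transcript_input(x)
  out <- lapply(seq_len(nrow(x)),
                function(i) classify_one(x$id[i], x$seq[i], config))
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out)) return(empty_locus_df())
  rownames(out) <- NULL
  out
}

#' Detect imperfect SSR loci
#'
#' Joins >=2 maximal runs of the same canonical class (each with at least
#' `imperfect_min_run_copies` copies, unit sizes in
#' `config$imperfect_unit_sizes`) separated by interruptions of 1 to
#' `imperfect_max_gap_bp` bp.  The total span must reach `min_tract_bp`.
#' Same-class neighbours that each pass the threshold on their own are
#' compound, not imperfect (precedence).
#'
#' @inheritParams find_perfect_ssrs
#' @param runs optional precomputed run table from the internal scanner
#'   (single-sequence input only); computed when `NULL`.
#' @return the imperfect loci of the catalogue.
#' @export
detect_imperfect_ssrs <- function(x, config = mining_config(), runs = NULL) {
  cat_df <- if (!is.null(runs)) {
    x <- as_transcript_input(x)
    stopifnot(nrow(x) == 1L)
    classify_one(x$id[1L], x$seq[1L], config, runs = runs)
  } else {
    classify_catalogue(x, config)
  }
  cat_df[cat_df$classification == "imperfect", , drop = FALSE]
}

#' Assemble compound SSR loci
#'
#' Joins adjacent repeat components separated by at most
#' `compound_max_spacer_bp` bp: components of different canonical classes,
#' or of the same class when each passes `min_tract_bp` on its own.  The
#' locus is `compound_perfect` when every component is a single perfect run
#' and `compound_imperfect` when a component is itself interrupted.
#'
#' @inheritParams detect_imperfect_ssrs
#' @return the compound loci of the catalogue.
#' @seealso [compound_subtype()] for the mono-mono ... di-tri labels.
#' @export
assemble_compound_ssrs <- function(x, config = mining_config(), runs = NULL) {
  cat_df <- if (!is.null(runs)) {
    x <- as_transcript_input(x)
    stopifnot(nrow(x) == 1L)
    classify_one(x$id[1L], x$seq[1L], config, runs = runs)
  } else {
    classify_catalogue(x, config)
  }
  cat_df[startsWith(cat_df$classification, "compound"), , drop = FALSE]
}

#' Compound subtype label
#'
#' Derives the unit-size subtype of compound loci ("mono-mono", "di-di",
#' "mono-tri", ...) from the `component_motifs` encoding, with component
#' unit sizes sorted ascending.
#'
#' @param component_motifs character vector in the `component_motifs`
#'   encoding of [classify_catalogue()].
#' @return character vector of subtype labels.
#' @export
compound_subtype <- function(component_motifs) {
  unit_names <- c("mono", "di", "tri", "tetra", "penta", "hexa")
  vapply(component_motifs, function(cm) {
    els <- strsplit(cm, ";", fixed = TRUE)[[1]]
    units <- vapply(els, function(e) {
      nchar(strsplit(e, "+", fixed = TRUE)[[1]][1L])
    }, integer(1))
    paste(unit_names[sort(units)], collapse = "-")
  }, character(1), USE.NAMES = FALSE)
}
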