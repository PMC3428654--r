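# Primer-pair enumeration and constraint filtering for SSR loci.
#
# Candidate primers are exhaustively enumerated in the flanks of a locus and
# filtered on length, GC content, melting temperature and product size; the
# product always spans the whole repeat tract.

#' Primer design constraints
#'
#' The acceptance windows applied to every candidate primer and product.
#'
#' @param primer_len length range of a primer in nt, default `c(18, 24)`.
#' @param gc_pct GC-content window in percent, default `c(40, 70)`.
#' @param tm_c melting-temperature window in degrees C, default `c(54, 63)`.
#' @param min_product_bp minimum product length in bp, default 100.
#' @param max_product_bp maximum product length in bp, default 400.
#' @return an object of class `primer_constraints`.
#' @export
primer_constraints <- function(primer_len = c(18L, 24L),
                               gc_pct = c(40, 70),
                               tm_c = c(54, 63),
                               min_product_bp = 100L,
                               max_product_bp = 400L) {
  stopifnot(length(primer_len) == 2L, length(gc_pct) == 2L,
            length(tm_c) == 2L)
  if (primer_len[1] > primer_len[2] || gc_pct[1] > gc_pct[2] ||
      tm_c[1] > tm_c[2]) {
    stop("constraint ranges must be non-empty")
  }
  if (min_product_bp <= 2L * primer_len[1]) {
    stop("min_product_bp must exceed twice the minimum primer length")
  }
  if (max_product_bp < min_product_bp) {
    stop("max_product_bp must be >= min_product_bp")
  }
  structure(
    list(primer_len = as.integer(primer_len), gc_pct = as.numeric(gc_pct),
         tm_c = as.numeric(tm_c), min_product_bp = as.integer(min_product_bp),
         max_product_bp = as.integer(max_product_bp)),
    class = "primer_constraints")
}

#' GC content of a sequence
#'
#' @param seq a single sequence over A,C,G,T.
#' @return percentage of G+C bases.
#' @examples
#' gc_content("ATGC")  # 50
#' @export
gc_content <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L) {
    stop("seq must be a single non-empty string")
  }
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) {
    stop("seq contains characters outside {A,C,G,T}")
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  100 * sum(chars %in% c("G", "C")) / length(chars)
}

#' Melting temperature of a primer
#'
#' The GC-fraction approximation
#' `Tm = 64.9 + 41 * (nGC - 16.4) / length` (degrees C), a standard
#' length/GC formula for oligo annealing.  It depends only on primer length
#' and GC count and carries no salt correction; it is the documented,
#' swappable Tm engine behind the constraint window.
#'
#' @param seq a single primer sequence over A,C,G,T, 10-40 nt.
#' @return melting temperature in degrees C.
#' @examples
#' melting_temp(paste0(strrep("AT", 5), strrep("GC", 5)))  # 51.78
#' @export
melting_temp <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L) {
    stop("seq must be a single string")
  }
  len <- nchar(seq)
  if (len < 10L || len > 40L) {
    stop("primer length out of range 10-40 nt: ", len)
  }
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) {
    stop("seq contains characters outside {A,C,G,T}")
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  ngc <- sum(chars %in% c("G", "C"))
  64.9 + 41 * (ngc - 16.4) / len
}

# Enumerate candidate windows on one flank.  Returns start (0-based), len,
# gc count, tm for windows whose bases are all A/C/G/T (a window touching N
# or any other character is silently disqualified).
enumerate_windows <- function(chars, lo, hi, constraints) {
  # windows [a, a+len) with lo <= a and a+len <= hi (0-based bounds)
  is_gc <- chars %in% c("G", "C")
  is_ok <- chars %in% DNA_BASES
  cgc <- c(0L, cumsum(is_gc))
  cok <- c(0L, cumsum(is_ok))
  out <- vector("list", 0L)
  for (len in constraints$primer_len[1]:constraints$primer_len[2]) {
    if (hi - lo < len) next
    a <- lo:(hi - len)
    valid <- (cok[a + len + 1L] - cok[a + 1L]) == len
    a <- a[valid]
    if (!length(a)) next
    ngc <- cgc[a + len + 1L] - cgc[a + 1L]
    gc <- 100 * ngc / len
    tm <- 64.9 + 41 * (ngc - 16.4) / len
    pass <- gc >= constraints$gc_pct[1] & gc <= constraints$gc_pct[2] &
      tm >= constraints$tm_c[1] & tm <= constraints$tm_c[2]
    if (any(pass)) {
      out[[length(out) + 1L]] <- data.frame(
        start = a[pass], len = len, gc = gc[pass], tm = tm[pass])
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), len = integer(0),
                      gc = numeric(0), tm = numeric(0)))
  }
  do.call(rbind, out)
}

#' Design primer pairs flanking an SSR locus
#'
#' Exhaustively scans left-flank and right-flank windows meeting the
#' constraints, pairs them so that the product spans the whole repeat tract
#' and lies within the product-size window, and ranks pairs by
#' `|Tm_left - Tm_right|` ascending, then product length ascending (ties
#' broken by position for determinism).  The right primer is reported
#' 5'->3' on the reverse strand, i.e. as synthesised.
#'
#' @param x a `transcript_set` (or single sequence) containing the locus.
#' @param locus one row of a locus data frame, or a list with
#'   `transcript_id`, `start`, `end` (0-based half-open).
#' @param constraints a [primer_constraints()].
#' @param top_k maximum number of pairs returned (default 3).
#' @return a data frame of primer pairs (possibly empty) with columns
#'   `transcript_id`, `locus_start`, `locus_end`, `left_seq`, `right_seq`,
#'   `left_start`, `right_end`, `product_length_bp`, `left_gc_pct`,
#'   `right_gc_pct`, `left_tm_c`, `right_tm_c`.  When no pair fits, the
#'   reason is attached as attribute `"reason"`.
#' @export
design_primers <- function(x, locus, constraints = primer_constraints(),
                           top_k = 3L) {
  x <- as_transcript_input(x)
  i <- match(locus$transcript_id[1L], x$id)
  if (is.na(i)) stop("locus transcript not in transcript set")
  seq <- x$seq[i]
  n <- nchar(seq)
  s <- as.integer(locus$start[1L]); e <- as.integer(locus$end[1L])
  if (s < 0L || e > n || s >= e) stop("locus does not lie within record")
  empty <- function(reason) {
    out <- data.frame(
      transcript_id = character(0), locus_start = integer(0),
      locus_end = integer(0), left_seq = character(0),
      right_seq = character(0), left_start = integer(0),
      right_end = integer(0), product_length_bp = integer(0),
      left_gc_pct = numeric(0), right_gc_pct = numeric(0),
      left_tm_c = numeric(0), right_tm_c = numeric(0))
    attr(out, "reason") <- reason
    out
  }
  min_len <- constraints$primer_len[1]
  if (s < min_len || n - e < min_len) {
    return(empty("flank shorter than minimum primer length"))
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  # windows restricted to the max-product neighbourhood of the tract
  left <- enumerate_windows(chars,
                            lo = max(0L, e - constraints$max_product_bp),
                            hi = s, constraints)
  right <- enumerate_windows(chars, lo = e,
                             hi = min(n, s + constraints$max_product_bp),
                             constraints)
  if (!nrow(left) || !nrow(right)) {
    return(empty("no flank window satisfies the primer constraints"))
  }
  idx <- expand.grid(l = seq_len(nrow(left)), r = seq_len(nrow(right)))
  left_start <- left$start[idx$l]
  right_end <- right$start[idx$r] + right$len[idx$r]
  product <- right_end - left_start
  keep <- product >= constraints$min_product_bp &
    product <= constraints$max_product_bp
  if (!any(keep)) return(empty("no pair within the product-size window"))
  idx <- idx[keep, , drop = FALSE]
  left_start <- left_start[keep]; right_end <- right_end[keep]
  product <- product[keep]
  dtm <- abs(left$tm[idx$l] - right$tm[idx$r])
  ord <- order(dtm, product, left_start, right_end)
  ord <- utils::head(ord, top_k)
  li <- idx$l[ord]; ri <- idx$r[ord]
  rs <- right$start[ri]
  data.frame(
    transcript_id = x$id[i],
    locus_start = s, locus_end = e,
    left_seq = substring(seq, left$start[li] + 1L,
                         left$start[li] + left$len[li]),
    right_seq = revcomp(substring(seq, rs + 1L, rs + right$len[ri])),
    left_start = left$start[li],
    right_end = rs + right$len[ri],
    product_length_bp = product[ord],
    left_gc_pct = left$gc[li],
    right_gc_pct = right$gc[ri],
    left_tm_c = left$tm[li],
    right_tm_c = right$tm[ri],
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Independently audit a designed primer pair
#'
#' Re-validates one row of a [design_primers()] result against the raw
#' transcript sequence and the constraints, using none of the enumerator's
#' machinery: primer sequences are re-extracted from the template, GC is
#' recounted with pattern matching, Tm re-evaluated from its definition, and
#' the product-span and coverage arithmetic rechecked.
#'
#' @param x the `transcript_set` (or sequence) the pair was designed on.
#' @param pair one row of a [design_primers()] result.
#' @param constraints the [primer_constraints()] used.
#' @return `TRUE` when every check passes, otherwise a character vector of
#'   failure descriptions.
#' @export
check_primer_pair <- function(x, pair, constraints = primer_constraints()) {
  x <- as_transcript_input(x)
  seq <- x$seq[match(pair$transcript_id, x$id)]
  issues <- character(0)
  note <- function(msg) issues <<- c(issues, msg)
  count_gc <- function(p) {
    hits <- gregexpr("[GC]", p)[[1]]
    if (hits[1] == -1L) 0L else length(hits)
  }
  tm_of <- function(p) 64.9 + 41 * (count_gc(p) - 16.4) / nchar(p)
  lw <- substr(seq, pair$left_start + 1L,
               pair$left_start + nchar(pair$left_seq))
  if (lw != pair$left_seq) note("left primer does not match template")
  rw <- substr(seq, pair$right_end - nchar(pair$right_seq) + 1L,
               pair$right_end)
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", rw), "")[[1]]),
              collapse = "")
  if (rc != pair$right_seq) {
    note("right primer is not the reverse complement of its window")
  }
  for (side in c("left", "right")) {
    p <- pair[[paste0(side, "_seq")]]
    len <- nchar(p)
    if (len < constraints$primer_len[1] || len > constraints$primer_len[2]) {
      note(paste(side, "primer length out of range"))
    }
    if (grepl("[^ACGT]", p)) note(paste(side, "primer has illegal base"))
    gc <- 100 * count_gc(p) / len
    if (gc < constraints$gc_pct[1] || gc > constraints$gc_pct[2]) {
      note(paste(side, "primer GC out of range"))
    }
    if (abs(gc - pair[[paste0(side, "_gc_pct")]]) > 1e-9) {
      note(paste(side, "reported GC disagrees with sequence"))
    }
    tm <- tm_of(p)
    if (tm < constraints$tm_c[1] || tm > constraints$tm_c[2]) {
      note(paste(side, "primer Tm out of range"))
    }
    if (abs(tm - pair[[paste0(side, "_tm_c")]]) > 1e-9) {
      note(paste(side, "reported Tm disagrees with sequence"))
    }
  }
  if (pair$product_length_bp != pair$right_end - pair$left_start) {
    note("product length arithmetic wrong")
  }
  if (pair$product_length_bp < constraints$min_product_bp ||
      pair$product_length_bp > constraints$max_product_bp) {
    note("product length out of range")
  }
  if (!(pair$left_start + nchar(pair$left_seq) <= pair$locus_start &&
        pair$right_end - nchar(pair$right_seq) >= pair$locus_end)) {
    note("product does not span the repeat tract")
  }
  if (length(issues)) issues else TRUE
}
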