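# Ground-truthed simulators.
#
# Transcript simulation plants SSR loci of known position, motif, copy
# number and classification into repeat-free background sequence.
# Backgrounds are square-free by construction: they contain no tandem
# square XX of any 1-6 bp unit X, so the only repeat runs in a simulated
# transcript are the planted ones (plus runs nested inside a planted tract,
# which the classifier's overlap resolution discards).  Planted loci are
# separated by at least 30 bp of clean flank, and every transcript is
# verified against its plant design before being accepted, so detector
# recall and precision against the ground truth are exact by construction,
# not approximate.

#' Default canonical-class weights for planted motifs
#'
#' A probability table over canonical motif classes shaped like the class
#' frequencies of published genic-SSR catalogues at the 18 bp threshold:
#' AG/CT-dominant di-nucleotides (48% in total), hexa- second (25%), then
#' tri- (21%), with the named di/tri families at their published shares and
#' the remainder spread over a handful of A-rich classes per unit size.
#'
#' @return named numeric vector of class weights summing to 1; names are
#'   canonical representatives.
#' @export
default_motif_class_weights <- function() {
  w <- c(A = 0.0057,
         AG = 0.3451, AC = 0.0765, AT = 0.0585,
         AAG = 0.0357, AAC = 0.0450, AAT = 0.0450, ACC = 0.0440,
         ATC = 0.0399,
         ACAT = 0.0106, AAAT = 0.0106,
         AAAAG = 0.0150, AAAAC = 0.0147,
         AAAAAG = 0.0837, AAAAAC = 0.0600, AAAATC = 0.0600,
         AAATCC = 0.0500)
  w / sum(w)
}

#' Default copy-number distributions per unit size
#'
#' Conditional copy-number weights per unit size, taken from the packaged
#' perfect-SSR copy-number fixture restricted to copy numbers whose tract
#' reaches `min_tract_bp`.
#'
#' @param min_tract_bp tract threshold the planted loci must pass.
#' @return named list (mono..hexa) of named weight vectors (names are copy
#'   numbers).
#' @export
default_copy_number_distribution <- function(min_tract_bp = 18L) {
  t4 <- load_fixture("table4")
  out <- lapply(1:6, function(k) {
    counts <- t4[[k + 1L]]
    keep <- counts > 0 & t4$copies * k >= min_tract_bp
    if (!any(keep)) {
      keep <- t4$copies * k >= min_tract_bp & t4$copies >= 2L
      return(stats::setNames(rep(1, sum(keep)) / sum(keep),
                             t4$copies[keep]))
    }
    stats::setNames(counts[keep] / sum(counts[keep]), t4$copies[keep])
  })
  names(out) <- c("mono", "di", "tri", "tetra", "penta", "hexa")
  out
}

#' Transcript simulation settings
#'
#' Defaults emulate the study conditions of published sesame genic-SSR
#' surveys: log-normal transcript lengths with mean about 1,127 bp, 40% GC
#' background, about 0.10 planted SSRs per transcript at the 18 bp
#' threshold, class weights per [default_motif_class_weights()],
#' copy numbers per [default_copy_number_distribution()], and a
#' classification mix of 82.75% perfect / 4.53% imperfect / 5.07%
#' compound-perfect / 7.66% compound-imperfect.
#'
#' @param n_transcripts number of transcripts to simulate.
#' @param mean_length_bp mean transcript length in bp (log-normal).
#' @param length_sdlog log-scale standard deviation of transcript length.
#' @param min_length_bp shortest transcript emitted.
#' @param gc_background background GC fraction.
#' @param ssr_plant_rate expected planted loci per transcript (Poisson).
#' @param min_tract_bp tract threshold every planted locus passes.
#' @param motif_class_weights named class-weight vector (canonical
#'   representatives).
#' @param copy_number_distribution per-unit copy-number weights.
#' @param classification_mix named probabilities over perfect, imperfect,
#'   compound_perfect, compound_imperfect.
#' @param seed integer seed; fully determines the output.
#' @return an object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_transcripts = 200L,
                            mean_length_bp = 1127,
                            length_sdlog = 1.0,
                            min_length_bp = 150L,
                            gc_background = 0.40,
                            ssr_plant_rate = 0.10,
                            min_tract_bp = 18L,
                            motif_class_weights = default_motif_class_weights(),
                            copy_number_distribution =
                              default_copy_number_distribution(min_tract_bp),
                            classification_mix = c(
                              perfect = 3674, imperfect = 201,
                              compound_perfect = 225,
                              compound_imperfect = 340) / 4440,
                            seed = 1L) {
  stopifnot(n_transcripts >= 1L, mean_length_bp > 0, length_sdlog > 0,
            gc_background > 0, gc_background < 1, ssr_plant_rate >= 0)
  if (abs(sum(motif_class_weights) - 1) > 1e-6) {
    stop("motif_class_weights must sum to 1")
  }
  bad <- names(motif_class_weights)[vapply(
    names(motif_class_weights),
    function(m) canonical_rep(m) != m || !is_primitive_motif(m),
    logical(1))]
  if (length(bad)) {
    stop("motif_class_weights names must be primitive canonical ",
         "representatives; offending: ", paste(bad, collapse = ", "))
  }
  if (abs(sum(classification_mix) - 1) > 1e-6) {
    stop("classification_mix must sum to 1")
  }
  # feasibility: planted material must fit typical transcripts
  if (ssr_plant_rate * 80 + 60 > 0.9 * mean_length_bp) {
    stop("infeasible spec: plant rate too high for the length distribution")
  }
  structure(
    list(n_transcripts = as.integer(n_transcripts),
         mean_length_bp = mean_length_bp,
         length_sdlog = length_sdlog,
         min_length_bp = as.integer(min_length_bp),
         gc_background = gc_background,
         ssr_plant_rate = ssr_plant_rate,
         min_tract_bp = as.integer(min_tract_bp),
         motif_class_weights = motif_class_weights,
         copy_number_distribution = copy_number_distribution,
         classification_mix = classification_mix,
         seed = as.integer(seed)),
    class = "simulation_spec")
}

# ---- square-free background sampling --------------------------------------

# Positions >= `from` (1-based) where a tandem square of any 1-6 bp unit
# ends in `chars`.
square_end_positions <- function(chars, from = 1L) {
  n <- length(chars)
  bad <- logical(n)
  for (u in 1:6) {
    if (n < 2L * u) next
    m <- chars[(u + 1L):n] == chars[seq_len(n - u)]
    cs <- c(0L, cumsum(m))
    t_end <- u:(n - u)
    full <- t_end[cs[t_end + 1L] - cs[t_end - u + 1L] == u]
    i_pos <- full + u
    bad[i_pos[i_pos >= from]] <- TRUE
  }
  which(bad)
}

# Bases that would complete a square ending at position i, given chars[1:(i-1)].
square_completing_bases <- function(chars, i) {
  out <- character(0)
  for (u in 1:6) {
    if (i < 2L * u) next
    pre_ok <- u == 1L ||
      all(chars[(i - u + 1L):(i - 1L)] == chars[(i - 2L * u + 1L):(i - u - 1L)])
    if (pre_ok) out <- c(out, chars[i - u])
  }
  unique(out)
}

# Append n square-free background characters after `context` (which may end
# with a planted run; squares ending inside the context are ignored, squares
# ending in the new region -- including ones that would extend the context's
# repeat -- are forbidden).  Returns the new characters only.
sample_background <- function(context, n, gc, max_iter = 120L) {
  if (n == 0L) return(character(0))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  ctx_len <- length(context)
  x <- c(context, sample(DNA_BASES, n, replace = TRUE, prob = p))
  for (it in seq_len(max_iter)) {
    bad <- square_end_positions(x, from = ctx_len + 1L)
    if (!length(bad)) return(x[(ctx_len + 1L):(ctx_len + n)])
    x[bad] <- sample(DNA_BASES, length(bad), replace = TRUE, prob = p)
  }
  # stubborn case: grow base by base
  x <- context
  guard <- 0L
  while (length(x) < ctx_len + n) {
    i <- length(x) + 1L
    allowed <- setdiff(DNA_BASES, square_completing_bases(x, i))
    if (!length(allowed)) {
      x <- x[seq_len(max(ctx_len, length(x) - 4L))]
      guard <- guard + 1L
      if (guard > 1000L) stop("background sampler failed to converge")
      next
    }
    x <- c(x, sample(allowed, 1L, prob = p[allowed]))
  }
  x[(ctx_len + 1L):(ctx_len + n)]
}

# Repair the tail of `chars` so that a run starting right after it is
# left-maximal and starts no cross-junction square: the final character must
# avoid the first (up to) 6 characters of the run and must not complete a
# square of its own.
fix_tail_for_run <- function(chars, run_seq, gc) {
  i <- length(chars)
  if (i == 0L) return(chars)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  head_chars <- unique(strsplit(substr(run_seq, 1L, 6L), "",
                                fixed = TRUE)[[1]])
  for (attempt in 1:20) {
    forbidden <- union(head_chars, square_completing_bases(chars, i))
    if (!(chars[i] %in% forbidden)) return(chars)
    allowed <- setdiff(DNA_BASES, forbidden)
    if (length(allowed)) {
      chars[i] <- sample(allowed, 1L, prob = p[allowed])
      return(chars)
    }
    # over-constrained: loosen the previous character and retry
    if (i >= 2L) {
      chars[i - 1L] <- sample(DNA_BASES, 1L, prob = p)
    } else break
  }
  # last resort: only guarantee left-maximality of the run's own unit
  chars[i] <- sample(setdiff(DNA_BASES, head_chars[1L]), 1L)
  chars
}

# ---- plant design ----------------------------------------------------------

sample_class_member <- function(class_rep) {
  members <- unique(c(rotations(class_rep), rotations(revcomp(class_rep))))
  members[sample.int(length(members), 1L)]
}

sample_from <- function(weights) {
  names(weights)[sample.int(length(weights), 1L, prob = weights)]
}

sample_class_of_unit <- function(weights, unit, exclude = character(0)) {
  cand <- weights[nchar(names(weights)) == unit &
                    !(names(weights) %in% exclude)]
  if (!length(cand)) {
    # fall back to any primitive canonical class of this unit
    pool <- c("C", "CG", "ACG", "AACG", "AACCG", "AACCGG")[unit]
    return(pool)
  }
  sample_from(cand)
}

# A plant design is a list of runs (motif, copies, unit) and the gaps (bp)
# between consecutive runs, plus the target classification.
design_plant <- function(spec) {
  w <- spec$motif_class_weights
  M <- spec$min_tract_bp
  cls <- sample_from(spec$classification_mix)
  pick_copies <- function(unit, lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L
  if (cls == "perfect") {
    class_rep <- sample_from(w)
    unit <- nchar(class_rep)
    cn <- spec$copy_number_distribution[[unit]]
    copies <- as.integer(sample_from(cn))
    runs <- list(list(motif = sample_class_member(class_rep),
                      copies = copies, unit = unit))
    gaps <- integer(0)
  } else if (cls == "imperfect") {
    imix <- c(mono = 77, di = 123, tri = 1) / 201
    unit <- match(sample_from(imix), c("mono", "di", "tri"))
    class_rep <- sample_class_of_unit(w, unit)
    lohi <- list(c(5L, 10L), c(3L, 6L), c(2L, 4L))[[unit]]
    # component runs must stay below the threshold on their own, or the
    # pair would classify as a same-class compound instead
    cap <- (M - 1L) %/% unit
    lohi <- pmin(lohi, cap)
    c1 <- pick_copies(unit, lohi[1], lohi[2])
    c2 <- pick_copies(unit, lohi[1], lohi[2])
    g <- sample.int(4L, 1L)
    while ((c1 + c2) * unit + g < M) c2 <- c2 + 1L
    runs <- list(
      list(motif = sample_class_member(class_rep), copies = c1, unit = unit),
      list(motif = sample_class_member(class_rep), copies = c2, unit = unit))
    gaps <- g
  } else {
    sub_counts <- if (cls == "compound_perfect") {
      c("mono-mono" = 22, "di-di" = 193, "tri-tri" = 4, "mono-di" = 3,
        "mono-tri" = 2, "di-tri" = 1)
    } else {
      c("mono-mono" = 12, "di-di" = 318, "tri-tri" = 6, "mono-di" = 1,
        "mono-tri" = 1, "di-tri" = 2)
    }
    sub <- sample_from(sub_counts / sum(sub_counts))
    units <- match(strsplit(sub, "-", fixed = TRUE)[[1]],
                   c("mono", "di", "tri"))
    u1 <- units[1]; u2 <- units[2]
    lohi <- list(c(7L, 14L), c(4L, 8L), c(3L, 5L))
    if (cls == "compound_perfect") {
      if (u1 == u2 && u1 == 1L) {
        # mono-mono: same A/T class, each tract passing the threshold
        rep1 <- rep2 <- "A"
        c1 <- M + sample.int(4L, 1L); c2 <- M + sample.int(4L, 1L)
      } else {
        rep1 <- sample_class_of_unit(w, u1)
        rep2 <- sample_class_of_unit(w, u2,
                                     exclude = if (u1 == u2) rep1 else
                                       character(0))
        c1 <- pick_copies(u1, lohi[[u1]][1], lohi[[u1]][2])
        c2 <- pick_copies(u2, lohi[[u2]][1], lohi[[u2]][2])
      }
      g <- sample.int(8L, 1L)
      while (c1 * u1 + g + c2 * u2 < M) c2 <- c2 + 1L
      runs <- list(
        list(motif = sample_class_member(rep1), copies = c1, unit = u1),
        list(motif = sample_class_member(rep2), copies = c2, unit = u2))
      gaps <- g
    } else {
      # compound_imperfect: first component interrupted, second a clean run
      # of a different class
      rep1 <- sample_class_of_unit(w, u1)
      rep2 <- sample_class_of_unit(w, u2,
                                   exclude = if (u1 == u2) rep1 else
                                     character(0))
      cap1 <- (M - 1L) %/% u1   # interrupted components stay sub-threshold
      c1a <- pick_copies(u1, min(lohi[[u1]][1], cap1),
                         min(lohi[[u1]][2], cap1))
      c1b <- pick_copies(u1, min(lohi[[u1]][1], cap1),
                         min(lohi[[u1]][2], cap1))
      c2 <- pick_copies(u2, lohi[[u2]][1], lohi[[u2]][2])
      g1 <- sample.int(4L, 1L)
      g2 <- sample.int(8L, 1L)
      while ((c1a + c1b) * u1 + g1 + g2 + c2 * u2 < M) c2 <- c2 + 1L
      runs <- list(
        list(motif = sample_class_member(rep1), copies = c1a, unit = u1),
        list(motif = sample_class_member(rep1), copies = c1b, unit = u1),
        list(motif = sample_class_member(rep2), copies = c2, unit = u2))
      gaps <- c(g1, g2)
    }
  }
  list(classification = cls, runs = runs, gaps = gaps,
       width = sum(vapply(runs, function(r) r$copies * r$unit, numeric(1))) +
         sum(gaps))
}

# Ground-truth locus row, mirroring classify_catalogue()'s output format.
truth_row <- function(id, start, plant) {
  runs <- plant$runs
  tracts <- vapply(runs, function(r) r$copies * r$unit, integer(1))
  starts <- integer(length(runs))
  pos <- start
  for (i in seq_along(runs)) {
    starts[i] <- pos
    pos <- pos + tracts[i] + if (i < length(runs)) plant$gaps[i] else 0L
  }
  end <- starts[length(runs)] + tracts[length(runs)]
  motifs <- vapply(runs, `[[`, character(1), "motif")
  reps <- vapply(motifs, canonical_rep, character(1), USE.NAMES = FALSE)
  copies <- sum(vapply(runs, `[[`, integer(1), "copies"))
  cls <- plant$classification
  if (cls == "perfect") {
    comp <- ""; motif <- motifs[1]; canon <- reps[1]
    unit <- runs[[1]]$unit
  } else if (cls == "imperfect") {
    comp <- paste(motifs, collapse = "+"); motif <- motifs[1]
    canon <- reps[1]; unit <- runs[[1]]$unit
  } else if (cls == "compound_perfect") {
    comp <- paste(motifs, collapse = ";"); motif <- comp
    canon <- paste(reps, collapse = ";"); unit <- NA_integer_
  } else {
    comp <- paste0(motifs[1], "+", motifs[2], ";", motifs[3])
    motif <- comp
    canon <- paste(c(reps[1], reps[3]), collapse = ";")
    unit <- NA_integer_
  }
  list(row = data.frame(
         transcript_id = id, start = start, end = end, motif = motif,
         canonical_class = canon, unit_size = unit, copies = copies,
         tract_length = end - start, classification = cls,
         component_motifs = comp, stringsAsFactors = FALSE),
       run_table = data.frame(start = starts, end = starts + tracts,
                              unit = vapply(runs, `[[`, integer(1), "unit"),
                              tract = tracts))
}

# Verify a built transcript against its plant design: every planted run must
# be detected exactly, and every other detected run must be a strictly
# smaller run overlapping a planted one (a nested interior repeat that
# overlap resolution discards).
verify_plant <- function(seq, expected_runs, min_tract_bp) {
  runs <- find_perfect_runs(seq)
  if (nrow(expected_runs)) {
    key_exp <- paste(expected_runs$start, expected_runs$end,
                     expected_runs$unit)
    key_obs <- paste(runs$start, runs$end, runs$unit_size)
    if (!all(key_exp %in% key_obs)) return(FALSE)
    extra <- runs[!key_obs %in% key_exp, , drop = FALSE]
  } else {
    extra <- runs
  }
  if (!nrow(extra)) return(TRUE)
  if (!nrow(expected_runs)) return(FALSE)
  for (i in seq_len(nrow(extra))) {
    ov <- expected_runs$start < extra$end[i] &
      expected_runs$end > extra$start[i]
    if (!any(ov)) return(FALSE)
    if (extra$tract_length[i] >= max(expected_runs$tract[ov])) return(FALSE)
    if (extra$tract_length[i] >= min_tract_bp) return(FALSE)
  }
  TRUE
}

build_transcript <- function(id, len, plants, gc, min_tract_bp) {
  m <- length(plants)
  widths <- vapply(plants, `[[`, numeric(1), "width")
  need <- sum(widths) + 30L * (m + 1L)
  while (m > 0L && need > len) {          # drop plants that do not fit
    plants <- plants[-m]; m <- m - 1L
    widths <- widths[seq_len(m)]
    need <- sum(widths) + 30L * (m + 1L)
  }
  extra <- len - (if (m > 0L) need else 0L)
  outer_gaps <- if (m > 0L) {
    30L + as.integer(stats::rmultinom(1L, extra, rep(1, m + 1L)))
  } else len
  chars <- character(0)
  truth <- vector("list", m)
  for (b in seq_len(m + 1L)) {
    ctx <- if (length(chars)) chars[max(1L, length(chars) - 11L):length(chars)]
      else character(0)
    chars <- c(chars, sample_background(ctx, outer_gaps[b], gc))
    if (b > m) break
    plant <- plants[[b]]
    # lay the block down run by run
    for (r in seq_along(plant$runs)) {
      run_seq <- strrep(plant$runs[[r]]$motif, plant$runs[[r]]$copies)
      chars <- fix_tail_for_run(chars, run_seq, gc)
      if (r == 1L) block_start <- length(chars)
      chars <- c(chars, strsplit(run_seq, "", fixed = TRUE)[[1]])
      if (r < length(plant$runs)) {
        ctx <- chars[max(1L, length(chars) - 11L):length(chars)]
        chars <- c(chars, sample_background(ctx, plant$gaps[r], gc))
      }
    }
    truth[[b]] <- truth_row(id, block_start, plant)
  }
  seq <- paste(chars, collapse = "")
  expected <- if (m > 0L) {
    do.call(rbind, lapply(truth, `[[`, "run_table"))
  } else {
    data.frame(start = integer(0), end = integer(0), unit = integer(0),
               tract = integer(0))
  }
  if (!verify_plant(seq, expected, min_tract_bp)) return(NULL)
  list(seq = seq,
       truth = if (m > 0L) do.call(rbind, lapply(truth, `[[`, "row")) else
         NULL)
}

#' Simulate a transcript set with planted, ground-truthed SSR loci
#'
#' Generates `spec$n_transcripts` transcripts of log-normal length with
#' square-free (repeat-free) background sequence and Poisson-many planted
#' SSR loci per transcript, each locus drawn from the configured class,
#' copy-number and classification distributions and always passing
#' `spec$min_tract_bp`.  Each transcript is verified against its plant
#' design (and regenerated if needed), so
#' `classify_catalogue(result$transcripts)` recovers the ground truth
#' exactly.  Output is fully determined by `spec$seed`.
#'
#' @param spec a [simulation_spec()].
#' @return a list with elements `transcripts` (a [transcript_set()]),
#'   `truth` (a locus data frame in [classify_catalogue()] format) and
#'   `spec`.
#' @export
generate_transcripts <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  local_seed(spec$seed, {
    meanlog <- log(spec$mean_length_bp) - spec$length_sdlog^2 / 2
    lens <- pmax(spec$min_length_bp,
                 as.integer(round(stats::rlnorm(spec$n_transcripts,
                                                meanlog, spec$length_sdlog))))
    ids <- sprintf("tx%05d", seq_len(spec$n_transcripts))
    seqs <- character(spec$n_transcripts)
    truth <- vector("list", spec$n_transcripts)
    for (i in seq_len(spec$n_transcripts)) {
      n_plants <- stats::rpois(1L, spec$ssr_plant_rate)
      built <- NULL
      for (attempt in 1:25) {
        plants <- replicate(n_plants, design_plant(spec), simplify = FALSE)
        built <- build_transcript(ids[i], lens[i], plants,
                                  spec$gc_background, spec$min_tract_bp)
        if (!is.null(built)) break
      }
      if (is.null(built)) {
        stop("could not realise plant design for ", ids[i],
             " after 25 attempts")
      }
      seqs[i] <- built$seq
      truth[[i]] <- built$truth
    }
    truth <- do.call(rbind, truth)
    if (is.null(truth)) truth <- empty_locus_df()
    rownames(truth) <- NULL
    list(transcripts = transcript_set(ids, seqs),
         truth = truth, spec = spec)
  })
}

#' Simulate genotype band matrices with known allele frequencies
#'
#' Each accession draws one allele per marker from the marker's frequency
#' vector; allele `i` of marker `j` is reported as a distinct band size.
#' With `method = "sample"` draws are independent; with
#' `method = "balanced"` allele counts are apportioned to the frequencies
#' by largest remainder (every allele with nonzero frequency is observed
#' when `n_accessions` permits) and then shuffled across accessions.
#'
#' @param n_accessions number of accessions (>= 2).
#' @param markers named list of allele-frequency vectors, each summing
#'   to 1.
#' @param seed integer seed.
#' @param method "sample" (default) or "balanced".
#' @return a list with elements `matrix` (a [genotype_matrix()]) and
#'   `truth` (per-marker frequency vectors, band sizes and true PIC).
#' @export
generate_genotypes <- function(n_accessions, markers, seed = 1L,
                               method = c("sample", "balanced")) {
  method <- match.arg(method)
  stopifnot(n_accessions >= 2L, is.list(markers), length(markers) >= 1L)
  if (is.null(names(markers))) {
    names(markers) <- sprintf("M%03d", seq_along(markers))
  }
  for (m in names(markers)) {
    p <- markers[[m]]
    if (!is.numeric(p) || any(p <= 0) || abs(sum(p) - 1) > 1e-6) {
      stop("allele frequencies of ", m, " must be positive and sum to 1")
    }
  }
  local_seed(seed, {
    acc <- sprintf("S%04d", seq_len(n_accessions))
    rows <- vector("list", length(markers))
    truth <- vector("list", length(markers))
    for (j in seq_along(markers)) {
      p <- markers[[j]]
      k <- length(p)
      band_sizes <- 100L + 10L * seq_len(k)
      alleles <- if (method == "sample") {
        sample.int(k, n_accessions, replace = TRUE, prob = p)
      } else {
        base <- floor(p * n_accessions)
        rem <- n_accessions - sum(base)
        if (rem > 0L) {
          frac <- p * n_accessions - base
          base[order(-frac)[seq_len(rem)]] <- base[order(-frac)[seq_len(rem)]] + 1L
        }
        sample(rep.int(seq_len(k), base))
      }
      rows[[j]] <- data.frame(marker = names(markers)[j], accession = acc,
                              band = band_sizes[alleles],
                              stringsAsFactors = FALSE)
      truth[[j]] <- list(freqs = p, band_sizes = band_sizes,
                         true_pic = 1 - sum(p^2))
    }
    names(truth) <- names(markers)
    bands <- do.call(rbind, rows)
    list(matrix = genotype_matrix(bands, accessions = acc,
                                  markers = names(markers)),
         truth = truth)
  })
}
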