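# Independent oracles and fixture builders used across the suite.
# The oracles deliberately share no code with the package internals.

# Primitivity by direct divisor check.
oracle_primitive <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L &&
        paste(rep(substr(motif, 1L, d), k / d), collapse = "") == motif) {
      return(FALSE)
    }
  }
  TRUE
}

# Brute-force perfect-SSR scan: tests every start position and unit size,
# extends copy by copy by substring comparison, and keeps left-anchored
# maximal runs of primitive motifs.
oracle_perfect_ssrs <- function(seq, min_tract, units = 1:6) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  rows <- list()
  for (k in units) {
    if (n < 2L * k) next
    for (p in seq_len(n - 2L * k + 1L)) {
      motif <- substr(seq, p, p + k - 1L)
      if (grepl("[^ACGT]", motif) || !oracle_primitive(motif)) next
      cc <- 1L
      while (p + (cc + 1L) * k - 1L <= n &&
             substr(seq, p + cc * k, p + (cc + 1L) * k - 1L) == motif) {
        cc <- cc + 1L
      }
      if (cc < 2L || cc * k < min_tract) next
      # left-anchored: the period must break just before p
      if (p > 1L && chars[p - 1L] != "N" &&
          chars[p - 1L] == chars[p - 1L + k]) next
      rows[[length(rows) + 1L]] <-
        data.frame(start = p - 1L, end = p - 1L + cc * k, unit_size = k,
                   motif = motif, copies = cc, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      unit_size = integer(0), motif = character(0),
                      copies = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$unit_size), , drop = FALSE]
}

locus_key <- function(df) paste(df$start, df$end, df$unit_size, df$motif)

# Compare detector and oracle over a character vector of sequences;
# returns indices of disagreement (empty = agreement everywhere).
detector_oracle_mismatches <- function(seqs, min_tract) {
  cfg <- mining_config(min_tract_bp = min_tract)
  ids <- sprintf("s%06d", seq_along(seqs))
  ts <- transcript_set(ids, seqs)
  det <- find_perfect_ssrs(ts, cfg)
  det_split <- split(det, factor(det$transcript_id, levels = ids))
  which(vapply(seq_along(seqs), function(i) {
    ora <- oracle_perfect_ssrs(seqs[i], min_tract)
    !identical(sort(locus_key(det_split[[i]])), sort(locus_key(ora)))
  }, logical(1)))
}

# All strings of the given lengths over an alphabet.
enumerate_strings <- function(alphabet, lengths) {
  unlist(lapply(lengths, function(L) {
    grid <- do.call(expand.grid,
                    c(rep(list(alphabet), L),
                      list(stringsAsFactors = FALSE)))
    do.call(paste0, grid)
  }))
}

random_seqs <- function(n, max_len, alphabet = c("A", "C", "G", "T", "N"),
                        weights = c(3, 3, 3, 3, 1)) {
  lens <- sample(12:max_len, n, replace = TRUE)
  vapply(lens, function(L) {
    paste(sample(alphabet, L, replace = TRUE, prob = weights),
          collapse = "")
  }, character(1))
}

# Clade leaf-sets of an ssr_dendro tree (internal nodes only).
dendro_clades <- function(tree) {
  res <- list()
  walk <- function(node) {
    if (!is.null(node$leaf)) return(node$leaf)
    leaves <- sort(c(walk(node$children[[1]]), walk(node$children[[2]])))
    res[[length(res) + 1L]] <<- leaves
    leaves
  }
  walk(tree)
  res[order(vapply(res, paste, character(1), collapse = "|"))]
}

dendro_heights <- function(tree) {
  if (!is.null(tree$leaf)) return(numeric(0))
  c(tree$height, dendro_heights(tree$children[[1]]),
    dendro_heights(tree$children[[2]]))
}

# Clade leaf-sets of an hclust object.
hclust_clades <- function(hc) {
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    get1 <- function(j) if (j < 0) hc$labels[-j] else members[[j]]
    members[[i]] <- sort(c(get1(hc$merge[i, 1]), get1(hc$merge[i, 2])))
  }
  members[order(vapply(members, paste, character(1), collapse = "|"))]
}

# An exactly ultrametric similarity matrix with known clade structure:
# random agglomeration with strictly decreasing merge similarities.
random_ultrametric_sim <- function(n, seed) {
  set.seed(seed)
  labels <- sprintf("L%02d", seq_len(n))
  sims <- sort(runif(n - 1L, 0.1, 0.95), decreasing = TRUE)
  S <- diag(1, n); dimnames(S) <- list(labels, labels)
  clusters <- as.list(seq_len(n))
  clades <- list()
  for (step in seq_len(n - 1L)) {
    pick <- sample.int(length(clusters), 2L)
    a <- clusters[[pick[1]]]; b <- clusters[[pick[2]]]
    S[a, b] <- sims[step]; S[b, a] <- sims[step]
    merged <- c(a, b)
    clades[[length(clades) + 1L]] <- sort(labels[merged])
    clusters <- c(clusters[-pick], list(merged))
  }
  list(S = S,
       clades = clades[order(vapply(clades, paste, character(1),
                                    collapse = "|"))])
}

# Random flanking sequence at 50% GC for primer tests.
random_flank <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
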