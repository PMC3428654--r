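# Marker polymorphism and genetic-similarity analysis: allele scoring, PIC,
# Jaccard band similarity, UPGMA clustering and Newick export.

#' Construct a genotype (band) matrix
#'
#' Band observations for a panel of accessions scored with SSR markers, in
#' long format: one row per (marker, accession, band size).  A row with a
#' missing band, or the absence of any row for a (marker, accession) pair,
#' means no amplification — which is distinct from two accessions sharing
#' no bands.
#'
#' @param bands data frame with columns `marker`, `accession`, `band`
#'   (band size in bp, positive integer, or NA for no amplification).
#' @param accessions optional ordered accession ids (default: order of
#'   first appearance).
#' @param markers optional ordered marker ids.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(bands, accessions = NULL, markers = NULL) {
  stopifnot(is.data.frame(bands),
            all(c("marker", "accession", "band") %in% names(bands)))
  bands <- data.frame(marker = as.character(bands$marker),
                      accession = as.character(bands$accession),
                      band = suppressWarnings(as.integer(bands$band)),
                      stringsAsFactors = FALSE)
  if (any(!is.na(bands$band) & bands$band <= 0L)) {
    stop("band sizes must be positive")
  }
  if (is.null(accessions)) accessions <- unique(bands$accession)
  if (is.null(markers)) markers <- unique(bands$marker)
  if (length(accessions) < 2L) stop("at least 2 accessions required")
  if (length(markers) < 1L) stop("at least 1 marker required")
  if (!all(bands$accession %in% accessions) ||
      !all(bands$marker %in% markers)) {
    stop("bands reference unknown accession or marker ids")
  }
  structure(list(bands = bands, accessions = accessions, markers = markers),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", length(x$accessions), " accessions x ",
      length(x$markers), " markers, ", sum(!is.na(x$bands$band)),
      " band observations\n", sep = "")
  invisible(x)
}

#' Polymorphism information content
#'
#' `PIC = 1 - sum(p_i^2)` over allele frequencies `p_i` of a marker; 0 for
#' a monomorphic marker, at most `1 - 1/k` for `k` alleles.
#'
#' @param allele_freqs positive numeric vector of allele frequencies
#'   summing to 1 (tolerance 1e-6).
#' @return the PIC value.
#' @examples
#' pic(c(0.5, 0.3, 0.2))  # 0.62
#' @export
pic <- function(allele_freqs) {
  if (!is.numeric(allele_freqs) || !length(allele_freqs) ||
      any(allele_freqs <= 0)) {
    stop("allele_freqs must be positive")
  }
  if (abs(sum(allele_freqs) - 1) > 1e-6) {
    stop("allele frequencies must sum to 1")
  }
  1 - sum(allele_freqs^2)
}

#' Score alleles and per-marker polymorphism
#'
#' For each marker, the alleles are the distinct band sizes observed among
#' amplifying accessions; allele frequency is the fraction of band
#' observations carrying that allele (non-amplification is treated as
#' missing data, not as a null allele).  Markers with no amplifying
#' accession are excluded with a warning.
#'
#' @param gm a [genotype_matrix()].
#' @return an object of class `marker_polymorphism`: a data frame with
#'   columns `marker`, `n_alleles`, `pic`, plus attributes `allele_freqs`
#'   (named list of frequency vectors) and `mean_alleles` (mean alleles per
#'   marker, rounded half-up to 2 decimals).
#' @export
score_alleles <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  obs <- gm$bands[!is.na(gm$bands$band), , drop = FALSE]
  dropped <- setdiff(gm$markers, unique(obs$marker))
  if (length(dropped)) {
    warning("marker(s) with no amplifying accession excluded: ",
            paste(dropped, collapse = ", "))
  }
  markers <- gm$markers[gm$markers %in% unique(obs$marker)]
  freqs <- lapply(markers, function(m) {
    sub <- obs[obs$marker == m, , drop = FALSE]
    # one observation per accession-allele pair
    sub <- unique(sub[, c("accession", "band")])
    tab <- table(sub$band)
    stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  })
  names(freqs) <- markers
  out <- data.frame(
    marker = markers,
    n_alleles = vapply(freqs, length, integer(1), USE.NAMES = FALSE),
    pic = vapply(freqs, function(p) 1 - sum(p^2), numeric(1),
                 USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  attr(out, "allele_freqs") <- freqs
  attr(out, "mean_alleles") <- round_half_up(mean(out$n_alleles), 2)
  class(out) <- c("marker_polymorphism", "data.frame")
  out
}

#' @export
print.marker_polymorphism <- function(x, ...) {
  cat("marker polymorphism: ", nrow(x), " marker(s), ",
      sum(x$n_alleles), " alleles total, mean ",
      sprintf("%.2f", attr(x, "mean_alleles")), " alleles/marker, mean PIC ",
      sprintf("%.2f", round_half_up(mean(x$pic), 2)), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' Jaccard similarity between accessions
#'
#' Bands are scored as binary presence characters (one character per
#' observed marker-band combination).  For accessions x and y,
#' `S = a / (a + b + c)` with `a` shared bands and `b`, `c` the bands
#' unique to each.  Markers at which either accession failed to amplify
#' are excluded pairwise (missing data, not absence).  A pair with an
#' empty band union gets similarity 0 with a warning.
#'
#' @param gm a [genotype_matrix()].
#' @return a symmetric similarity matrix in \[0,1\] with unit diagonal,
#'   accessions in panel order.
#' @export
jaccard_similarity <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  acc <- gm$accessions
  if (length(acc) < 2L) stop("at least 2 accessions required")
  obs <- gm$bands[!is.na(gm$bands$band), , drop = FALSE]
  items <- unique(obs[, c("marker", "band")])
  item_id <- paste(items$marker, items$band, sep = "@")
  pres <- matrix(FALSE, nrow = length(acc), ncol = nrow(items),
                 dimnames = list(acc, item_id))
  if (nrow(obs)) {
    pres[cbind(match(obs$accession, acc),
               match(paste(obs$marker, obs$band, sep = "@"), item_id))] <- TRUE
  }
  amplified <- matrix(FALSE, nrow = length(acc), ncol = length(gm$markers),
                      dimnames = list(acc, gm$markers))
  if (nrow(obs)) {
    amplified[cbind(match(obs$accession, acc),
                    match(obs$marker, gm$markers))] <- TRUE
  }
  item_marker <- match(items$marker, gm$markers)
  S <- diag(1, length(acc))
  dimnames(S) <- list(acc, acc)
  warned <- FALSE
  for (i in seq_len(length(acc) - 1L)) {
    for (j in (i + 1L):length(acc)) {
      usable <- amplified[i, item_marker] & amplified[j, item_marker]
      xi <- pres[i, ] & usable
      xj <- pres[j, ] & usable
      u <- sum(xi | xj)
      if (u == 0L) {
        if (!warned) {
          warning("accession pair(s) with empty band union; similarity 0")
          warned <- TRUE
        }
        s <- 0
      } else {
        s <- sum(xi & xj) / u
      }
      S[i, j] <- S[j, i] <- s
    }
  }
  S
}

#' UPGMA clustering of a similarity matrix
#'
#' Agglomerates the pair of clusters with maximal similarity; the merged
#' cluster's similarity to any other is the size-weighted arithmetic mean
#' of its members' similarities (unweighted pair-group method).  Node
#' heights are the similarity at the merge, so heights are non-increasing
#' from leaves (height 1) to the root — the ultrametric property on the
#' similarity scale.  Ties are broken deterministically by the
#' lexicographically smallest pair of cluster leaf labels.
#'
#' @param sim symmetric similarity matrix in \[0,1\] with unit diagonal and
#'   accession ids as dimnames; at least 2 accessions.
#' @return the root `ssr_dendro` node: a leaf is
#'   `list(leaf = <id>)`; an internal node is
#'   `list(children = list(left, right), height = <similarity>, size = n)`.
#' @examples
#' S <- matrix(c(1, .9, .5, .9, 1, .7, .5, .7, 1), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' tree <- upgma(S)
#' tree$height  # root joins C at (0.5 + 0.7) / 2 = 0.6
#' @export
upgma <- function(sim) {
  stopifnot(is.matrix(sim), nrow(sim) == ncol(sim), nrow(sim) >= 2L)
  ids <- rownames(sim)
  if (is.null(ids)) stop("similarity matrix needs accession ids as dimnames")
  if (max(abs(sim - t(sim))) > 1e-9) stop("similarity matrix not symmetric")
  if (any(abs(diag(sim) - 1) > 1e-9)) stop("diagonal must be exactly 1")
  if (any(sim < -1e-12 | sim > 1 + 1e-12)) stop("similarities must lie in [0,1]")
  nodes <- lapply(ids, function(id) structure(list(leaf = id),
                                              class = "ssr_dendro"))
  sizes <- rep(1L, length(ids))
  keys <- ids                      # min leaf label per cluster
  S <- sim
  active <- seq_along(ids)
  while (length(active) > 1L) {
    best <- NULL; best_s <- -Inf
    for (ii in seq_len(length(active) - 1L)) {
      for (jj in (ii + 1L):length(active)) {
        i <- active[ii]; j <- active[jj]
        s <- S[i, j]
        if (s > best_s + 1e-12) {
          best_s <- s; best <- c(i, j)
        } else if (abs(s - best_s) <= 1e-12) {
          k1 <- sort(c(keys[i], keys[j]))
          k2 <- sort(c(keys[best[1]], keys[best[2]]))
          if (k1[1] < k2[1] || (k1[1] == k2[1] && k1[2] < k2[2])) {
            best <- c(i, j)
          }
        }
      }
    }
    i <- best[1]; j <- best[2]
    merged <- structure(
      list(children = list(nodes[[i]], nodes[[j]]), height = S[i, j],
           size = sizes[i] + sizes[j]),
      class = "ssr_dendro")
    for (k in setdiff(active, c(i, j))) {
      S[i, k] <- S[k, i] <-
        (sizes[i] * S[i, k] + sizes[j] * S[j, k]) / (sizes[i] + sizes[j])
    }
    nodes[[i]] <- merged
    sizes[i] <- sizes[i] + sizes[j]
    keys[i] <- min(keys[i], keys[j])
    active <- setdiff(active, j)
  }
  nodes[[active]]
}

#' @export
print.ssr_dendro <- function(x, ...) {
  if (!is.null(x$leaf)) {
    cat("ssr_dendro leaf:", x$leaf, "\n")
  } else {
    cat("ssr_dendro: ", x$size, " leaves, root merge at similarity ",
        sprintf("%.4f", x$height), "\n", sep = "")
  }
  invisible(x)
}

#' Leaf labels of a dendrogram
#'
#' @param tree an `ssr_dendro` node.
#' @return character vector of leaf labels in tree order.
#' @export
dendro_leaves <- function(tree) {
  if (!is.null(tree$leaf)) return(tree$leaf)
  c(dendro_leaves(tree$children[[1]]), dendro_leaves(tree$children[[2]]))
}

#' Export a dendrogram to Newick
#'
#' Heights are converted from the similarity scale to a distance scale
#' (`d = 1 - s`) and split evenly between the two sides of each merge, the
#' usual ultrametric convention: a node that merged at similarity `s` sits
#' at depth `(1 - s) / 2` from the leaves.  Branch length is parent depth
#' minus child depth; re-parsing reproduces the topology and heights.
#'
#' @param tree an internal `ssr_dendro` node (a bare leaf is an error).
#' @param path optional output path; when `NULL` the Newick string is
#'   returned only.
#' @return the Newick string, invisibly when written to `path`.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "ssr_dendro"))
  if (!is.null(tree$leaf)) stop("tree must have at least one merge")
  depth <- function(node) {
    if (!is.null(node$leaf)) 0 else (1 - node$height) / 2
  }
  fmt <- function(x) format(x, digits = 10, scientific = FALSE, trim = TRUE)
  build <- function(node) {
    if (!is.null(node$leaf)) return(node$leaf)
    parts <- vapply(node$children, function(ch) {
      paste0(build(ch), ":", fmt(depth(node) - depth(ch)))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  nwk <- paste0(build(tree), ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}
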