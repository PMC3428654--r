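# Allele scoring, PIC, Jaccard similarity, UPGMA and Newick export.

test_that("pic follows its closed form", {
  expect_equal(pic(1.0), 0)
  expect_equal(pic(c(0.5, 0.5)), 0.5)
  expect_equal(pic(c(0.5, 0.3, 0.2)), 0.62)
  for (k in 2:5) expect_equal(pic(rep(1 / k, k)), 1 - 1 / k)
  expect_error(pic(c(0.5, 0.4)), "sum to 1")
  expect_error(pic(c(1.2, -0.2)), "positive")
})

test_that("pic is permutation-invariant and maximised at equal frequencies", {
  set.seed(14)
  for (k in 2:5) {
    for (rep in 1:40) {
      p <- as.numeric(stats::rmultinom(1, 500, runif(k)) / 500)
      if (any(p == 0)) next
      expect_equal(pic(p), pic(sample(p)))
      expect_lte(pic(p), 1 - 1 / k + 1e-12)
    }
  }
})

test_that("score_alleles counts distinct bands and treats missing as missing", {
  bands <- rbind(
    data.frame(marker = "M1", accession = sprintf("a%02d", 1:10),
               band = rep(c(200L, 210L), each = 5)),
    data.frame(marker = "M2", accession = sprintf("a%02d", 1:10),
               band = 150L),
    data.frame(marker = "M3", accession = sprintf("a%02d", 1:10),
               band = NA_integer_))
  gm <- genotype_matrix(bands)
  expect_warning(sc <- score_alleles(gm), "M3")
  expect_equal(sc$n_alleles[sc$marker == "M1"], 2L)
  expect_equal(unname(attr(sc, "allele_freqs")$M1), c(0.5, 0.5))
  # monomorphic marker has PIC 0
  expect_equal(sc$pic[sc$marker == "M2"], 0)
})

test_that("74 alleles over 32 markers give a mean of 2.31", {
  alleles_per_marker <- c(rep(2L, 23), rep(3L, 8), 4L)  # sums to 74
  expect_equal(sum(alleles_per_marker), 74L)
  markers <- lapply(alleles_per_marker,
                    function(k) rep(1 / k, k))
  gg <- generate_genotypes(24, markers, seed = 233, method = "balanced")
  sc <- score_alleles(gg$matrix)
  expect_equal(sum(sc$n_alleles), 74L)
  expect_equal(attr(sc, "mean_alleles"), 2.31)
})

test_that("estimated PIC converges to the generator truth", {
  gg <- generate_genotypes(5000, list(M1 = c(0.5, 0.3, 0.2)), seed = 7)
  sc <- score_alleles(gg$matrix)
  expect_lt(abs(sc$pic - 0.62), 0.01)
  # larger randomized sweep at n = 200+ within binomial error
  set.seed(88)
  for (rep in 1:5) {
    k <- sample(2:4, 1)
    p <- as.numeric(stats::rmultinom(1, 50, runif(k, 0.5, 1)) / 50)
    p <- p[p > 0]
    gg <- generate_genotypes(400, list(M = p), seed = 1000 + rep)
    sc <- score_alleles(gg$matrix)
    expect_lt(abs(sc$pic - (1 - sum(p^2))), 0.08)
  }
})

test_that("jaccard similarity follows a/(a+b+c) and its invariants", {
  bands <- rbind(
    data.frame(marker = "M1", accession = "x", band = c(100L, 110L)),
    data.frame(marker = "M1", accession = "y", band = c(100L, 120L)),
    data.frame(marker = "M2", accession = "x", band = 200L),
    data.frame(marker = "M2", accession = "y", band = 200L))
  S <- jaccard_similarity(genotype_matrix(bands))
  # a = 2 (100, 200), b = 1 (110), c = 1 (120)
  expect_equal(S["x", "y"], 0.5)
  expect_equal(diag(S), c(x = 1, y = 1))
  expect_equal(S, t(S))

  # identical and disjoint profiles
  b2 <- rbind(
    data.frame(marker = "M1", accession = c("p", "q", "r"),
               band = c(100L, 100L, 130L)),
    data.frame(marker = "M2", accession = c("p", "q", "r"),
               band = c(200L, 200L, 230L)))
  S2 <- jaccard_similarity(genotype_matrix(b2))
  expect_equal(S2["p", "q"], 1)
  expect_equal(S2["p", "r"], 0)

  # adding a shared band never decreases similarity
  b3 <- rbind(b2, data.frame(marker = "M3", accession = c("p", "r"),
                             band = c(300L, 300L)))
  S3 <- jaccard_similarity(genotype_matrix(b3))
  expect_gte(S3["p", "r"], S2["p", "r"])
})

test_that("jaccard warns on empty band unions and errors on one accession", {
  bands <- rbind(
    data.frame(marker = "M1", accession = "x", band = 100L),
    data.frame(marker = "M1", accession = "y", band = NA_integer_),
    data.frame(marker = "M2", accession = "x", band = NA_integer_),
    data.frame(marker = "M2", accession = "y", band = 200L))
  expect_warning(S <- jaccard_similarity(genotype_matrix(bands)), "union")
  expect_equal(S["x", "y"], 0)
  expect_error(genotype_matrix(
    data.frame(marker = "M1", accession = "x", band = 1L)), "2 accessions")
})

test_that("jaccard agrees with the vegan oracle on complete data", {
  skip_if_not_installed("vegan")
  set.seed(9)
  acc <- sprintf("a%02d", 1:8)
  rows <- list()
  for (m in sprintf("M%02d", 1:12)) {
    sizes <- 100L + 10L * (1:3)
    for (a in acc) {
      rows[[length(rows) + 1L]] <- data.frame(
        marker = m, accession = a,
        band = sample(sizes, sample(1:2, 1)))
    }
  }
  gm <- genotype_matrix(do.call(rbind, rows), accessions = acc)
  S <- jaccard_similarity(gm)
  # binary presence matrix for vegan built directly from the band table
  obs <- unique(gm$bands)
  items <- unique(paste(obs$marker, obs$band))
  X <- matrix(0L, length(acc), length(items),
              dimnames = list(acc, items))
  X[cbind(obs$accession, paste(obs$marker, obs$band))] <- 1L
  D <- as.matrix(vegan::vegdist(X, method = "jaccard", binary = TRUE))
  expect_equal(unname(S), unname(1 - D), tolerance = 1e-12)
})

test_that("upgma reproduces hand-worked merges", {
  S2 <- matrix(c(1, .8, .8, 1), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgma(S2)
  expect_equal(t2$height, 0.8)
  expect_equal(write_newick(t2), "(A:0.1,B:0.1);")

  S3 <- matrix(c(1, .9, .5, .9, 1, .7, .5, .7, 1), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgma(S3)
  expect_equal(t3$height, 0.6)             # (0.5 + 0.7) / 2
  expect_equal(sort(dendro_heights(t3)), c(0.6, 0.9))
  expect_equal(dendro_clades(t3),
               list(c("A", "B"), c("A", "B", "C")))
})

test_that("upgma trees are ultrametric and match the hclust oracle", {
  set.seed(23)
  for (rep in 1:5) {
    n <- sample(5:9, 1)
    P <- matrix(runif(n * 4), n)
    D <- as.matrix(dist(P)); D <- D / max(D) * 0.9
    S <- 1 - D; diag(S) <- 1
    dimnames(S) <- list(sprintf("L%02d", 1:n), sprintf("L%02d", 1:n))
    tr <- upgma(S)
    # similarities non-increasing from the leaves toward the root:
    # every child merged at a similarity at least its parent's
    check_mono <- function(node, parent_h) {
      if (!is.null(node$leaf)) return(invisible())
      expect_gte(node$height, parent_h - 1e-12)
      for (ch in node$children) check_mono(ch, node$height)
    }
    check_mono(tr, tr$height)
    hc <- stats::hclust(stats::as.dist(1 - S), method = "average")
    expect_equal(sort(1 - dendro_heights(tr)), sort(hc$height),
                 tolerance = 1e-12)
    expect_equal(dendro_clades(tr), hclust_clades(hc))
  }
})

test_that("upgma recovers a planted ultrametric topology; ties break lexicographically", {
  for (seed in c(3, 17, 29)) {
    gt <- random_ultrametric_sim(10, seed)
    tr <- upgma(gt$S)
    expect_equal(dendro_clades(tr), gt$clades)
  }
  # exact tie: first merge must pick the lexicographically smallest pair
  S <- diag(1, 4)
  dimnames(S) <- list(c("D", "C", "B", "A"), c("D", "C", "B", "A"))
  S["D", "C"] <- S["C", "D"] <- 0.8
  S["B", "A"] <- S["A", "B"] <- 0.8
  S[S == 0] <- 0.2
  tr <- upgma(S)
  first <- dendro_clades(tr)[[1]]
  expect_equal(first, c("A", "B"))
})

test_that("newick export round-trips through the ape parser", {
  skip_if_not_installed("ape")
  gt <- random_ultrametric_sim(8, 5)
  tr <- upgma(gt$S)
  f <- tempfile(fileext = ".nwk")
  write_newick(tr, f)
  ph <- ape::read.tree(f)
  expect_setequal(ph$tip.label, sprintf("L%02d", 1:8))
  expect_true(ape::is.ultrametric(ph, tol = 1e-8))
  # leaf depth equals (1 - root similarity) / 2
  depths <- ape::node.depth.edgelength(ph)[seq_along(ph$tip.label)]
  expect_equal(unname(depths), rep((1 - tr$height) / 2, 8),
               tolerance = 1e-9)
  # clades survive the round trip
  parts <- ape::prop.part(ph)
  got <- lapply(parts, function(idx) sort(attr(parts, "labels")[idx]))
  got <- got[order(vapply(got, paste, character(1), collapse = "|"))]
  want <- gt$clades
  want <- want[vapply(want, length, integer(1)) < 8 |
                 vapply(want, length, integer(1)) == 8]
  expect_true(all(vapply(got, function(g)
    any(vapply(want, identical, logical(1), g)), logical(1))))
  # a bare leaf cannot be exported
  expect_error(write_newick(structure(list(leaf = "A"),
                                      class = "ssr_dendro")), "merge")
})
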