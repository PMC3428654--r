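# SSR detection and classification.

FLANK_L <- "CTGTCGTCAGTCGTACGTGT"   # 20 bp, square-free
FLANK_R <- "CTGTCGTACGATCGTACGAT"   # 20 bp, square-free

test_that("perfect detection reproduces the survey's longest tracts", {
  # 52 bp (AG/CT) di-nucleotide tract
  loc <- find_perfect_ssrs(paste0(FLANK_L, strrep("AG", 26), FLANK_R),
                           mining_config(18))
  expect_equal(nrow(loc), 1L)
  expect_equal(loc$unit_size, 2L)
  expect_equal(loc$tract_length, 52L)
  expect_equal(loc$copies, 26L)
  expect_equal(loc$canonical_class, "AG")

  # 25 bp poly-A at the 15 bp threshold
  loc <- find_perfect_ssrs(paste0(FLANK_L, strrep("A", 25), FLANK_R),
                           mining_config(15))
  expect_equal(nrow(loc), 1L)
  expect_equal(loc$unit_size, 1L)
  expect_equal(loc$tract_length, 25L)

  # (AT)x7 = 14 bp stays below the 15 bp threshold
  loc <- find_perfect_ssrs(paste0(FLANK_L, strrep("AT", 7), FLANK_R),
                           mining_config(15))
  expect_equal(nrow(loc), 0L)
})

test_that("runs of non-primitive units are reported under the primitive unit only", {
  loc <- find_perfect_ssrs(paste0(FLANK_L, strrep("AGAG", 6), FLANK_R),
                           mining_config(18))
  expect_equal(loc$motif, "AG")
  expect_equal(loc$unit_size, 2L)
  expect_equal(loc$copies, 12L)
})

test_that("detector equals the brute-force oracle on exhaustive small inputs", {
  seqs <- enumerate_strings(c("A", "C"), 6:10)
  expect_length(detector_oracle_mismatches(seqs, min_tract = 6), 0L)
})

test_that("detector equals the brute-force oracle on random sequences", {
  set.seed(2024)
  seqs <- random_seqs(200, max_len = 60)
  expect_length(detector_oracle_mismatches(seqs, min_tract = 12), 0L)
})

test_that("no reported perfect locus is extendable by one unit", {
  set.seed(91)
  seqs <- random_seqs(60, max_len = 60, weights = c(4, 4, 1, 1, 0))
  ts <- transcript_set(sprintf("s%03d", seq_along(seqs)), seqs)
  loc <- find_perfect_ssrs(ts, mining_config(8))
  expect_gt(nrow(loc), 0L)
  for (i in seq_len(nrow(loc))) {
    s <- ts$seq[match(loc$transcript_id[i], ts$id)]
    k <- loc$unit_size[i]
    if (loc$start[i] >= k) {
      expect_false(substr(s, loc$start[i] - k + 1L, loc$start[i]) ==
                     loc$motif[i])
    }
    if (loc$end[i] + k <= nchar(s)) {
      expect_false(substr(s, loc$end[i] + 1L, loc$end[i] + k) ==
                     loc$motif[i])
    }
  }
})

test_that("threshold is monotone: loci at 18 bp are a subset of loci at 15 bp", {
  set.seed(55)
  seqs <- random_seqs(80, max_len = 120, weights = c(4, 4, 2, 2, 0))
  ts <- transcript_set(sprintf("s%03d", seq_along(seqs)), seqs)
  l18 <- find_perfect_ssrs(ts, mining_config(18))
  l15 <- find_perfect_ssrs(ts, mining_config(15))
  key <- function(d) paste(d$transcript_id, d$start, d$end, d$unit_size)
  expect_true(all(key(l18) %in% key(l15)))
})

test_that("runs never cross N", {
  loc <- find_perfect_ssrs(paste0(FLANK_L, strrep("AG", 8), "N",
                                  strrep("AG", 8), FLANK_R),
                           mining_config(16))
  expect_equal(loc$tract_length, c(16L, 16L))
})

test_that("imperfect loci join same-class runs across short interruptions", {
  # 8 A's, one G, 9 A's: one imperfect mono locus spanning 18 bp
  loc <- classify_catalogue(paste0(FLANK_L, "AAAAAAAAG", "AAAAAAAAA",
                                   FLANK_R), mining_config(15))
  expect_equal(nrow(loc), 1L)
  expect_equal(loc$classification, "imperfect")
  expect_equal(loc$tract_length, 18L)
  expect_equal(loc$copies, 17L)
  expect_equal(loc$component_motifs, "A+A")

  # gap of 6 bp exceeds the 4 bp limit: not joined (and the 16 bp
  # components neither pass the threshold alone nor qualify as compound)
  s6 <- paste0(FLANK_L, strrep("AG", 8), "TCTGCT", strrep("AG", 8), FLANK_R)
  expect_equal(nrow(classify_catalogue(s6, mining_config(18))), 0L)
  expect_equal(nrow(detect_imperfect_ssrs(s6, mining_config(18))), 0L)
  # the same two runs, each passing the threshold on its own, are a
  # same-class compound instead (precedence compound > imperfect)
  s6b <- paste0(FLANK_L, strrep("AG", 9), "TCTGCT", strrep("AG", 9), FLANK_R)
  expect_equal(classify_catalogue(s6b, mining_config(18))$classification,
               "compound_perfect")

  # a single clean run is never imperfect
  loc <- classify_catalogue(paste0(FLANK_L, strrep("GAA", 6), FLANK_R),
                            mining_config(18))
  expect_equal(loc$classification, "perfect")
  expect_identical(
    nrow(detect_imperfect_ssrs(paste0(FLANK_L, strrep("GAA", 6), FLANK_R))),
    0L)
})

test_that("compound loci join nearby components and take precedence", {
  # different di classes, 2 bp spacer
  s <- paste0(FLANK_L, strrep("AG", 8), "TG", strrep("CA", 8), FLANK_R)
  loc <- classify_catalogue(s, mining_config(18))
  expect_equal(nrow(loc), 1L)
  expect_equal(loc$classification, "compound_perfect")
  expect_equal(compound_subtype(loc$component_motifs), "di-di")
  expect_equal(loc$tract_length, 34L)
  # precedence: the component runs are not also reported as perfect
  expect_equal(sum(loc$classification == "perfect"), 0L)

  # mono + tri with 1 bp spacer
  s <- paste0(FLANK_L, strrep("A", 16), "G", strrep("GAA", 6), FLANK_R)
  loc <- classify_catalogue(s, mining_config(18))
  expect_equal(loc$classification, "compound_perfect")
  expect_equal(compound_subtype(loc$component_motifs), "mono-tri")

  # components 11 bp apart stay separate
  s <- paste0(FLANK_L, strrep("AG", 10), "TGCTAGCTGAT", strrep("CA", 10),
              FLANK_R)
  loc <- classify_catalogue(s, mining_config(18))
  expect_equal(loc$classification, c("perfect", "perfect"))

  # a compound with an interrupted component is compound_imperfect
  s <- paste0(FLANK_L, strrep("AG", 4), "T", strrep("AG", 4), "TG",
              strrep("CA", 8), FLANK_R)
  loc <- classify_catalogue(s, mining_config(18))
  expect_equal(loc$classification, "compound_imperfect")
  expect_equal(loc$component_motifs, "AG+AG;CA")
})

test_that("classification counts are disjoint and bases belong to one locus", {
  sim <- generate_transcripts(simulation_spec(n_transcripts = 150,
                                              ssr_plant_rate = 1.5,
                                              seed = 600))
  loc <- classify_catalogue(sim$transcripts, mining_config(18))
  # disjoint classes sum to the catalogue size
  expect_equal(sum(table(loc$classification)), nrow(loc))
  # no two loci of a transcript overlap
  for (id in unique(loc$transcript_id)) {
    sub <- loc[loc$transcript_id == id, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1L) {
      expect_true(all(sub$start[-1L] >= sub$end[-nrow(sub)]))
    }
  }
  # classification counts match the planted ground truth
  expect_equal(table(loc$classification), table(sim$truth$classification))
})

test_that("mining_config validates its parameters", {
  expect_error(mining_config(unit_sizes = c(1, 9)), "subset")
  expect_error(mining_config(min_tract_bp = 4, unit_sizes = 1:6), "at least")
  expect_error(mining_config(imperfect_max_gap_bp = -1), ">= 0")
})
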