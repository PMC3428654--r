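---
title: "Genic-SSR mining and marker analysis with ssrmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genic-SSR mining and marker analysis with ssrmine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Simple sequence repeats (SSRs, microsatellites) — tandem repetitions of a
1-6 bp motif — are the workhorse codominant markers of crop genetics,
and SSRs mined from transcribed sequence ("genic-" or EST-SSRs) transfer
well across germplasm because their flanks are conserved.  A genic-SSR
marker programme has four computational stages, and `ssrmine` implements
all of them on plain R data structures:

1. **mining** — detect and classify repeat tracts in transcript FASTA;
2. **cataloguing** — summarise counts, frequencies, copy-number spectra,
   repeat density and incidence;
3. **primer screening** — enumerate and filter primer pairs flanking each
   locus;
4. **marker analysis** — score alleles from band matrices, compute PIC,
   Jaccard similarities and a UPGMA dendrogram.

A fifth module simulates ground-truthed inputs for every stage, which is
how the package tests itself.

## Repeat detection semantics

A *perfect* locus is a maximal tandem run: at least two full copies of a
primitive unit, extendable by no further unit-aligned copy on either
side.  Runs are always reported under their primitive unit — an
`(AGAG)n` tract is an `(AG)n` locus — and a left-anchored convention
fixes the start of a tract whose phase is ambiguous.  `N` matches no
base, so runs never cross an `N`.  Coordinates are 0-based half-open
internally; the GFF3 export converts to the standard 1-based inclusive
convention.

Motifs are identified up to cyclic rotation and reverse complement:
`TC`, `CT`, `GA` and `AG` tracts all belong to one class, represented by
the lexicographically smallest member (`AG`, displayed `AG/CT`).  Some
published tables label families by a non-minimal member (`CA/TG` rather
than `AC/GT`); class membership, not the label, is what the code tests.

```{r}
library(ssrmine)
canonical_motif_class("TC")$display_pair
canonical_motif_class("GTAT")$representative  # same class as ATAC
```

Beyond perfect runs the catalogue distinguishes, with precedence
compound > imperfect > perfect so that every base belongs to at most one
locus:

* **imperfect** — two or more runs of the *same* class, each with at
  least `imperfect_min_run_copies` (default 2) copies, joined across
  interruptions of 1-`imperfect_max_gap_bp` (default 4) bp.  Only units
  1-3 participate by default, matching what genic-SSR surveys observe.
* **compound** — adjacent components within
  `compound_max_spacer_bp` (default 10) bp whose classes differ, or whose
  classes match while each component passes the length threshold on its
  own.  A compound locus is `compound_imperfect` when any component is
  itself interrupted.

The classical operational criteria for "imperfect" repeats are cited in
the survey literature but never restated precisely, so these parameters
are design choices — each is exposed in `mining_config()` so an
alternative convention is one argument away.  Two further choices are
ours:

* overlapping runs of different unit sizes (a poly-A inside an A-rich
  tetra context, say) are resolved by *longer tract wins, ties to the
  smaller unit*, which is what makes the classification counts disjoint;
* a compound component must itself span at least
  `compound_min_component_bp` (default 6) bp.  Without such a floor any
  doubled base within spacer range of a real SSR would promote it to a
  compound locus, which no published catalogue supports.  The floor is
  deliberately below the 2-copy spans of all unit sizes above 2, so it
  only suppresses incidental 1-2 bp micro-runs.

The length threshold (`min_tract_bp`, conventionally 18 or 15 bp)
applies to the *total span* of imperfect and compound loci, matching the
"SSRs ≥ 18 bp" phrasing of survey tables, not to each component.

```{r}
classify_catalogue(paste0("CTGTCGTCAGTCGTACGTGT",
                          "AAAAAAAAG", "AAAAAAAAA",
                          "CTGTCGTACGATCGTACGAT"),
                   mining_config(min_tract_bp = 15))
```

## Catalogue statistics

`summarize_catalogue()` produces the standard survey tables: counts by
classification, unit size, canonical class and copy number, with
consistent marginals.  Three conventions matter:

* percentages are computed exactly and rounded **half-up to 2 decimals
  only at presentation** (`round_half_up()`), reproducing how printed
  tables are formatted (base R's `round()` rounds half to even);
* *density* is kb of surveyed sequence per SSR;
* *incidence* is the count ratio `100 * n_ssrs / n_transcripts`.  This is
  how surveys print it, and it is a per-transcript rate rather than the
  fraction of transcripts containing at least one SSR — a transcript
  with two loci counts twice.  `incidence_pct()` implements the ratio
  and its documentation flags the ambiguity.

`apply_length_threshold()` connects the two conventional thresholds: the
≥18 bp census per unit size is exactly the ≥15 bp copy-number histogram
filtered by `copies × unit ≥ 18`.  The package ships the printed count
tables of a published sesame genic-SSR survey as fixtures
(`load_fixture()`), and the test suite reproduces every statistic that
is arithmetic over those counts — densities 6.55 and 10.81 kb/SSR,
incidences 17.21% and 10.43%, the unit-size and motif-class shares, and
the threshold-filter reconstruction (21 / 1,764 / 770 / 78 / 109 / 932).

## Primer screening

Candidates are enumerated exhaustively over both flanks and filtered on
the four classical criteria: primer length 18-24 nt, GC 40-70%,
annealing temperature 54-63 °C, product ≥ 100 bp (≤ 400 bp by default;
the upper bound is a configurable choice, since published pipelines
rarely state theirs).  The product always spans the whole repeat tract,
and the right primer is reported 5'→3' on the reverse strand, i.e. in
synthesis order.  Pairs are ranked by |Tm~left~ − Tm~right~|, then
product length, with positional tie-breaks for determinism.

The melting temperature is the GC-fraction approximation
`Tm = 64.9 + 41 (nGC − 16.4) / L` °C.  Production pipelines use
thermodynamic nearest-neighbour engines, so absolute primer yields are
not comparable across tools — the constraint *window* is what the
package reproduces, and the Tm engine is a single documented function
that can be swapped.  No dimer or hairpin screening is attempted; it is
not part of the stated criteria.  `check_primer_pair()` re-validates any
emitted pair from the raw sequence with none of the enumerator's code,
and the tests audit every designed pair through it.

## Marker diversity

`score_alleles()` treats each marker's distinct band sizes among
amplifying accessions as its alleles; frequency is the fraction of band
observations carrying the allele.  Non-amplification is treated as
missing data, not as a null allele — genic-SSR surveys do not genotype
null homozygotes, so this is the conservative reading.  PIC is
`1 − Σ p²`; with `k` alleles it is bounded by `1 − 1/k`.

`jaccard_similarity()` scores bands as binary presence characters
(`S = a / (a + b + c)`), the SIMQUAL convention for dominant-scored gel
data, with pairwise deletion of markers at which either accession failed
to amplify.  The two encodings thus coexist the way practitioners use
them: co-dominant allele counts feed PIC, binary bands feed similarity.

`upgma()` merges the most similar pair, averaging similarities weighted
by cluster size, with a deterministic lexicographic tie-break so trees
are reproducible.  Node heights are similarities at the merge, making
the tree ultrametric on the similarity scale.  `write_newick()` converts
to a distance scale (`d = 1 − s`) split evenly across the two sides of
each merge, so a pair merged at similarity 0.8 sits at depth 0.1 —
re-parsing with any Newick reader reproduces topology and heights.  The
package implements UPGMA (the agglomeration actually used for
similarity-matrix dendrograms in this literature) and not
neighbour-joining; the test suite cross-checks it against
`hclust(method = "average")`.

```{r}
S <- matrix(c(1, .9, .5, .9, 1, .7, .5, .7, 1), 3, 3,
            dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
write_newick(upgma(S))
```

## What the simulator emulates — and what it does not

`generate_transcripts()` emulates the study conditions of a genic-SSR
transcriptome survey: log-normal transcript lengths with mean 1,127 bp,
40% GC background, class weights shaped like the published ≥18 bp
distribution (di-dominant at 48% with AG/CT at 34.5%, hexa- 25%,
tri- 21%), copy numbers drawn from the packaged ≥15 bp histogram
conditioned on the threshold, and a classification mix of 82.75%
perfect / 4.53% imperfect / 5.07% compound-perfect / 7.66%
compound-imperfect.  The default plant rate of 0.10 loci per transcript
matches the published ≥18 bp incidence; tests that need dense ground
truth raise it explicitly.

Backgrounds are *square-free by construction*: sampled in blocks and
resampled at any position where a tandem square of a 1-6 bp unit would
end, with junction constraints where planted tracts are inserted
(the base before a planted run may neither extend the run's phase nor
complete a square).  Every transcript is then verified against its plant
design — each planted run must be detected at its exact coordinates, and
any other run must be a strictly smaller repeat nested inside a planted
tract (which overlap resolution discards) — and regenerated otherwise.
Planted loci are separated by at least 30 bp of clean flank.  This is
why the recall/precision tests can demand exactly 100%: the synthetic
data admit no ambiguity about what the right answer is.

That is also the honest limit of what passing tests show.  Real
transcriptomes have base-composition structure, A-rich untranslated
regions, sequencing and assembly artefacts, and repeats that shade
continuously from perfect to decayed; the generator's clean flanks and
parameterised interruptions emulate none of that.  The recovery results
validate the algorithms' correctness under their own definitions, not
any claim about real-data sensitivity — which is exactly why the
packaged survey counts are fixtures for arithmetic tests rather than
targets the detector is expected to regenerate (the surveyed
transcriptome itself is not deposited, and the survey's own
imperfect/compound criteria are not recoverable in operational detail).

`generate_genotypes()` draws one allele per accession per marker from
stated frequencies (`method = "sample"`), or apportions counts to the
frequencies by largest remainder and shuffles (`method = "balanced"`) —
the latter guarantees every allele is observed, which is what an
arithmetic check on allele totals needs; the former is the right choice
for sampling-error studies such as PIC convergence.

## Numerical and scale choices

* Ties: run-overlap resolution (tract length, then unit size, then
  position), UPGMA merges (lexicographic pair), primer ranking
  (positional) are all deterministic; every stochastic component is a
  pure function of a seed.
* Degenerate inputs: empty catalogues summarise to zeros; zero-SSR
  density is `NA` with a warning; markers with no amplification are
  excluded with a warning; an accession pair with an empty band union
  gets similarity 0 with a warning.
* Detector validation runs the brute-force oracle over exhaustive
  enumerations of the repeat-densest alphabets — all `{A,C}` strings to
  12 bp and `{A,C,G}` strings to 8 bp — plus 200 seeded random `ACGTN`
  sequences to 60 bp.  A two-letter alphabet maximises tandem-repeat
  density per base, so it exercises the maximality, anchoring and
  primitivity logic far harder than sparse four-letter strings of the
  same length; full four-letter enumeration to 12 bp (16.7M strings)
  adds nothing but runtime.
* The standard recovery experiment uses 1,000 transcripts with an
  expected 1,500 planted loci (about 1.1 Mb), PIC recovery uses 5,000
  draws, and topology recovery 12 taxa — sizes at which binomial error
  bounds are decisive while a full run stays interactive.

## Known limitations

* Approximate, alignment-scored repeat finding (Tandem Repeats
  Finder-style) is out of scope; interruptions are parameterised gaps,
  not scored edits.
* The Tm model carries no salt or nearest-neighbour correction, so
  primer yields are not comparable with thermodynamic engines.
* Band-size scoring uses exact integer equality, appropriate for
  synthetic data; real gel data need the upstream binning the band
  matrix is assumed to have received.
* Incidence is a count ratio (see above); per-transcript presence
  fractions must be computed from the catalogue directly if needed.
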