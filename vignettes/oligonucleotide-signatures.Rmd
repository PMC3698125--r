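---
title: "Oligonucleotide signatures as a taxonomic signal: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oligonucleotide signatures as a taxonomic signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligosig)
```

## The signal

Microbial genomes carry persistent biases in their usage of short DNA
words, from mononucleotide (G+C) content up to words well beyond ten
bases. Because these biases are roughly homogeneous along a genome and
drift slowly between relatives, the *oligonucleotide signature* — the
vector of relative frequencies of all `4^k` overlapping words of length
`k` — is a taxonomic signal that needs no marker gene. That matters most
in metagenomics, where assembled scaffolds usually lack rRNA and
homology search fails for poorly represented clades.

`oligosig` computes these signatures, compares them, and quantifies how
much taxonomic resolution each word length buys.

## Signatures

`count_words()` slides a window of length `k` (1–9) over the forward
strand at every offset, counting each word into bins indexed
lexicographically (A < C < G < T). Three conventions are fixed here and
used everywhere:

* **Windows containing any non-ACGT character are skipped**, not the whole
  record. This keeps the maximal amount of signal from draft-quality
  sequence and is deterministic.
* **Forward strand only.** No reverse-complement canonicalization is
  applied; some other tools sum both strands, and results are not
  interchangeable. This is the literal reading of a sliding-window count,
  and the choice is symmetric across all comparisons so it does not bias
  any of the evaluations in this package.
* **Windows never bridge record boundaries** when a signature is
  accumulated over a multi-record input (`signature_from_sequences()`).

Counts become percentages, `pct[i] = 100 * counts[i] / n_windows`, which
sum to 100 whenever at least one valid window exists; a zero-window input
is an explicit error, never a silent division by zero. The percent scale
(rather than fractions) is used for all downstream distances and
normalization factors. `k` is capped at 9 because the bin count grows as
`4^k` and longer words add little resolution for rapidly growing cost.

An optional `drop_plasmids` flag on `read_fasta()` removes records whose
header contains the keyword "plasmid", restricting analyses to
chromosomal composition.

## Distances and genus normalization

The distance between two signatures is plain Euclidean distance over all
`4^k` percentage bins. Raw distances shrink as `k` grows (the same 100%
of mass is spread over more bins), so cross-`k` comparisons use the
*genus-normalized* distance: every entry divided by the largest distance
observed between two distinct organisms sharing a genus, computed per
word length from the dataset at hand. The factor is stored on the result
(`normalization_factor` attribute) for reproducibility; the maximal
same-genus pair maps to exactly 1.0, and same-species pairs count as
same-genus. Self-pairs are excluded from the factor search (they are zero
and uninformative). When no two organisms share a genus the normalization
is undefined and the function says so rather than guessing.

Matrices interoperate with classic phylogenetics tooling through a
square PHYLIP writer/reader. One deviation from the strict format:
labels longer than 10 characters (such as the synthetic community's
systematic ids) are written in relaxed PHYLIP (label plus two spaces)
because truncation to 10 characters would collide; the reader accepts
both layouts.

## Cladograms and nearest-neighbor scoring

`neighbor_joining()` implements Saitou–Nei neighbor joining with
Studier–Keppler Q-updates — the algorithm behind the classic `neighbor`
program — and returns an `ape::phylo` object. Determinism is guaranteed
by breaking Q-ties on the first minimal pair in row-major order. NJ can
produce negative branch lengths on non-additive input; they are kept in
the Newick output (fidelity) but clamped to zero when computing leaf
path distances (so nearest neighbors stay well-defined). On additive
matrices the implementation recovers the source tree's topology and path
distances to numerical precision, which the test suite verifies against
simulated trees and against `ape::nj` as an independent cross-check.

A leaf's *nearest neighbor* is the other leaf at minimal branch-length
path distance, ties resolved by the lexicographically smaller label.
Branch-length (rather than node-count) path distance is used because the
branch lengths are the signature distances — the quantity of interest.
`taxonomic_agreement_profile()` scores a nearest-neighbor map
cumulatively: the value at rank *r* is the percentage of leaves whose
neighbor shares rank *r* or better, so the profile is non-decreasing
from species toward domain. It also emits the four-way coloring classes
used for cladogram figures (species/genus; family–phylum; same domain;
different domain).

## Evaluation experiments

**Leave-one-out histograms.** All distinct organism pairs (each counted
once; proportions are identical under ordered counting, so unordered
halves the work) are binned by genus-normalized distance into 30
equal-width bins spanning `[0, max observed]` — not a fixed `[0, 1]`,
because real distributions extend beyond 1; bin edges are returned so
truncation is a display decision. Per-bin proportions over the seven
comparison levels estimate the probability that a given distance implies
a given shared rank.

**Fragment experiment.** For each fragment length (defaults 1,000 to
50,000 bp), one uniform random fragment per genome is taken, a cladogram
is built per word length, and the same-genus nearest-neighbor percentage
is recorded. `replicates` defaults to 1 (one fragment per genome per
length); the packaged regression uses 10 replicates and averages, since
single draws are noisy at short lengths.

**Chunk profiles.** Genomes are cut into non-overlapping consecutive
chunks (trailing remainder discarded, avoiding a short-chunk length
bias) and mean chunk-to-chunk distances are reported per organism pair.
Self-comparisons include the zero diagonal, so one whole-sequence chunk
gives mean 0; mean self-distance falls as chunks lengthen, which
quantifies the within-genome sampling noise floor of a signature at a
given fragment size.

**Best-hit binning.** Each query signature is assigned the reference
with minimal distance (ties to the lexicographically smaller label).
Agreement is scored against ground-truth labels; in the synthetic
setting the truth is the generating genome, standing in for an external
homology-based assignment.

**Identity scatter.** Given a pre-aligned marker-gene multi-FASTA,
`percent_identity()` is plain column identity with gap columns (either
sequence) excluded — a deliberate simplification, since a model-based
distance cannot be reconstructed into "percent identity" unambiguously —
and `identity_distance_scatter()` emits (identity, distance, shared
level) triples.

## The mutation experiment

`mutation_trajectory()` mutates a sequence one base at a time: uniform
position, replacement drawn uniformly from **all four** bases, so a
quarter of mutations are silent. That is the literal protocol
re-implemented here; `exclude_same = TRUE` gives the three-base variant.
Counts are maintained incrementally — only the at most `k` windows
overlapping the mutated site change — together with a running sum of
squared count differences, so each snapshot distance costs O(1) and the
full-scale run (1 Mb, 10^6 iterations, snapshots every 100) takes about
a second. The incremental state is proven equal to a from-scratch
recount at random checkpoints in the tests.

"Saturation" needs an operational definition; `plateau_onset()` uses the
first snapshot after which every later distance stays within a relative
tolerance (default 0.02) of the final snapshot's distance. The tolerance
is a documented parameter, not a constant of nature. Replicate onsets at
full scale scatter noticeably (roughly ±12% around their median — the
individual onsets are printed by `scripts/acceptance.R` on every run),
because late small excursions move the "last exit from the band"
backwards or forwards; the regression test therefore checks the median
of several seeded runs against a band of 600,000 ± 100,000 iterations
rather than a tighter interval the estimator could not reliably meet.

## The synthetic community

Real multi-genome collections are replaced by a generative stand-in: a
balanced taxonomy (domains → phyla → orders → families → genera →
species) in which every taxon owns an order-`m` Markov sequence model.
A root logit matrix is drawn with Gaussian jitter; each child's logits
are its parent's plus Gaussian noise of magnitude `sigma[rank]`,
renormalized by a row-wise softmax — so probabilities stay valid at any
magnitude, and divergence accumulates with taxonomic depth. Requiring
`sigma` non-increasing from domain to species makes signatures conserved
within genera and increasingly distinct at higher ranks, which is the
empirical pattern the package is built to measure.

The frozen reference spec is 1 domain / 3 phyla / 6 genera / 12 species,
Markov order 5, 200 kb genomes, seed 101 (genomes drawn with seed 202,
fragment experiments with seed 303). Choices and reasons:

* **Markov order 5**: heptamer frequencies are then not fully determined
  by the model context, leaving genuine resolution differences between
  `k = 4` and `k = 7` for the experiments to detect.
* **200 kb genomes**: a desk-scale stand-in for Mb-scale chromosomes that
  keeps the full pipeline in seconds while leaving the per-bin sampling
  noise at `k = 7` (about 0.3 distance units at this length) well below
  the between-genus model signal.
* **Divergence magnitudes** `(0.50, 0.35, 0.25, 0.18, 0.15, 0.02)` from
  domain to species: calibrated once so the reference community behaves
  like a real collection — at least 80% of organisms get a same-genus
  nearest neighbor at `k = 7`, agreement rises from mono- to
  tetranucleotide words, and heptanucleotide fragments outperform
  tetranucleotide fragments at every tested length — and then frozen as
  a regression test. They were not revisited afterwards.

What the generator does **not** emulate: gene content and codon
structure, GC skew, repeats, rRNA operons, horizontal transfer,
strain-level pangenome variation, or unbalanced taxon sampling. A green
test therefore establishes that the pipeline's machinery measures
rank-structured compositional divergence correctly — not that any
particular real community will reach the same accuracy numbers.

## Numerical and degenerate-input conventions

* Rank comparison is exact string equality after whitespace trimming and
  case folding; inconsistent hierarchies (same genus under different
  families) are resolved by the "all ranks from that level upward must
  match" rule rather than curated away.
* Signature percentage sums are asserted to 1e-6; distance oracles to
  1e-9 relative; NJ additive recovery to 1e-6; Newick round-trips to
  1e-9.
* Empty sequences count zero windows (valid); an all-ambiguous input
  yields an explicit empty-signature error.
* A distance matrix whose entries are all zero cannot be
  genus-normalized (the factor would be zero) and errors.
* All stochastic entry points take explicit seeds and leave the caller's
  RNG state untouched (`withr::with_seed`); pipeline stages refuse to
  run stochastic work without a seed.

## Limitations

Dense `4^k` vectors are the accepted cost of simplicity: at `k = 9` each
signature holds 262,144 doubles, mirroring the practical ceiling of the
method. The package deliberately does not implement alternative
dissimilarities (correlation-based tetranucleotide z-score statistics,
Manhattan distance), strand-canonical counting as a default, tree
rooting or bootstrap support, or any network-dependent data retrieval.
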