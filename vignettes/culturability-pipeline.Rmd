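---
title: "Scoring the culturability of rumen bacterial OTUs"
author: "rumencult"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the culturability of rumen bacterial OTUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Most rumen bacteria are known only from 16S rRNA gene surveys: they have
never been isolated, so nothing direct is known about their physiology, and
they have no reference genome. Prioritising which organisms to isolate and
sequence next requires putting every observed OTU (operational taxonomic
unit, a cluster of 16S sequences at 97% identity) on a common map with
three coordinates:

* **novelty** — how far the OTU sits, phylogenetically, from the nearest
  bacterium that already exists in laboratory culture;
* **abundance** — its average share of the community across surveys, after
  between-survey normalisation;
* **prevalence** — the fraction of surveys in which it occurs at all.

`rumencult` implements that meta-analysis as a reusable pipeline: several
16S amplicon surveys plus a pool of cultured-isolate reference sequences go
in; a per-OTU table of scaled novelty, scaled abundance, prevalence,
core/abundant/novel flags and cultivation/sequencing candidates comes out.

## The pipeline, stage by stage

### Cleaning (`orient_reads`, `derive_anchors`, `trim_to_anchors`)

Survey reads arrive in mixed orientation and cover different, overlapping
windows of the 16S gene. Orientation is resolved by k-mer voting against a
reference sequence (default k = 12): a read is kept in whichever
orientation shares more distinct k-mers with the reference, and reads with
no signal either way are dropped. Homologous windows are then established
by locating two conserved anchor motifs — the consensus of the first and
last run of near-invariant alignment columns — and every read is trimmed
to the region strictly between its best anchor matches (Hamming matching,
at most 2 mismatches by default, leftmost/rightmost tie-breaks so the
retained span is maximal). Reads missing an anchor, with anchors out of
order, or shorter after trimming than the dataset minimum (default: half
the median trimmed length) are excluded.

The column-conservation cutoff for anchor discovery defaults to 0.97.
Anchors are, by definition, the near-invariant flanks of the homologous
region; at permissive cutoffs ordinary columns qualify by chance, the
"anchors" then inherit sequence-specific variation, and legitimate
sequences get discarded for exceeding the mismatch budget. A stringent
cutoff makes the discovered anchors coincide with the truly conserved
motifs. Both the cutoff and the anchors themselves are configurable.

### Clustering and universal OTUs (`greedy_cluster`, `detect_chimeras`, `build_universal_otus`)

Each survey is clustered separately at 97% identity with a deterministic
greedy incremental algorithm: reads are processed longest-first (ties by
id), each read joins the first existing cluster whose representative it
matches at the threshold, otherwise it founds a new cluster. Identity is
computed from a global affine-gap alignment (match +1, mismatch −1, gap
open −5, extend −1) divided by the shorter sequence length — the
convention that makes a perfect substring score 1, which is what lets
surveys with different window sizes merge later.

Chimeric PCR artefacts are screened among cluster representatives: a
sequence is flagged when its prefix matches one more-abundant parent and
its suffix another at ≥ 99% identity while its full-length identity to
both stays ≤ 97%, with candidate parents required to be at least twice as
abundant. A chimera that is ≥ 97% identical to one parent over its full
length is simply absorbed into that parent's cluster during clustering —
it never becomes a representative, creates no spurious OTU, and is
deliberately not flagged.

The second tier merges all surviving survey representatives with the
cultured-pool representatives, clustering them at the same threshold into
*universal OTUs*. Per-survey read tallies are aggregated, and an OTU
*contains a cultured isolate* when any cultured representative merged into
it. The two-tier design lets each survey be clustered on its full read
length while the merge operates on the shared window.

### Phylogeny and the novelty axis (`nj_tree`, `nearest_cultured_distances`)

A tree over the universal OTU representatives provides path distances.
The self-contained default is neighbour joining on alignment p-distances
(mismatches over compared positions, gaps excluded); an externally
estimated tree in newick format can be ingested instead and is preferred
when available, since likelihood-based trees estimate branch lengths
better. Raw branch-length path sums are used without transformation.

Each OTU's novelty is its path distance to the nearest tip whose OTU
contains a cultured isolate, computed exactly by a two-pass dynamic
programme (a post-order pass finds the best cultured tip inside each
subtree, a pre-order pass propagates the best route through the parent),
linear in tree size and checked in the test suite against brute-force
minimisation over the full distance matrix. Two rules matter:

* **zero rule** — an OTU whose own cluster contains a cultured isolate has
  distance exactly 0 (it *is* cultured, whatever the tree says);
* **ties** go to the lexicographically smallest tip id, for determinism.

`prune_tree` produces survey-only trees while preserving all kept-pair
path distances (merged edges sum their lengths), and `partition_clades`
cuts the tree into monophyletic clades by a maximum within-clade
tip-to-tip distance — an automated, reproducible stand-in for subdividing
a large tree into clades by eye. The threshold is a required analysis
choice with no claimed equivalence to any manual subdivision (default 0.5
substitutions/site in the pipeline wrapper).

### Abundance and prevalence (`tmm_factors`, `summarize_abundance`)

Raw per-survey library sizes are not comparable, so counts are scaled by
the trimmed mean of M-values (TMM): against a reference survey (the one
whose upper-quartile relative abundance is closest to the mean of upper
quartiles), log2 abundance ratios over shared OTUs are doubly trimmed
(30% on M, 5% on A) and combined by a precision-weighted mean; factors
are rescaled to geometric mean 1. The implementation delegates to edgeR's
published implementation; the test suite pins it against a hand-evaluated
transcription of the formula. An OTU's reported abundance is its mean
percentage across **all** surveys — absence counts as zero, the reading
most consistent with averaging "across all the datasets"; the alternative
(mean over surveys of occurrence) can be obtained from the attached
per-survey percentage matrix. Prevalence is the fraction of surveys with
a nonzero count and ignores normalisation entirely.

### Classification (`scale_metrics`, `classify_otus`, `select_candidates`)

Distance and abundance are mapped to [0, 1] as ratios to the dataset-wide
maxima, giving every OTU a position on a unit plane whose Euclidean
distance from the origin ranks "abundant-and-novel" jointly (the rank is
descriptive; no threshold is applied to it). Flags are independent and may
overlap:

* **core** — present in at least ⌈5/7 · D⌉ of the D surveys (the
  five-of-seven rule, kept integral for other survey counts);
* **abundant** — scaled abundance strictly greater than 0.25;
* **novel** — scaled distance strictly greater than 0.25.

Boundary values are excluded on purpose ("greater than" is strict).
Among flagged OTUs, those with > 93% identity to a cultured rumen isolate
nominate that isolate for genome sequencing (de-duplicated per isolate,
keeping the highest-similarity OTU); the rest are reported as requiring
cultivation effort. Taxonomic assignments and percent identities are
inputs, not something the package computes.

## The synthetic community generator

Real survey read sets are large, external downloads; `simulate_surveys`
generates statistically analogous inputs with complete ground truth so
that every stage is testable offline. The model:

* a random master 16S-like reference (800 nt) carrying two invariant
  12-nt anchor motifs (positions 41 and 431) flanking a 378-nt homologous
  region;
* a cultured pool of 40 references, each at 0.05 substitutions/site from
  the master (so the pool has a radius of about 0.05 and members are
  ~0.10 apart — distinct OTUs at 97%);
* 40 community taxa in three classes, each non-novel taxon descended from
  a *distinct* cultured parent so that taxa map one-to-one onto OTUs:
  cultured-matching taxa at 0.02 from their parent (inside the 97%
  radius, hence distance 0 after the merge), uncultured "mid" taxa at
  0.035 (outside the OTU radius but close in the tree), and 6 novel
  lineages at 0.30 straight from the master (about six times the pool
  radius). On the scaled axis mid taxa land below ~0.2 and novel lineages
  above ~0.85, so the 0.25 cutoff separates the planted classes by
  construction rather than by luck;
* half the taxa are core (planted in all surveys); the rest occur in
  fewer surveys than the core rule requires, so the planted core set is
  exactly the truth core set;
* log-normal abundances (σ = 1 across taxa) with per-survey resampling
  (σ = 0.3) around means shared across surveys;
* 7 surveys × 2000 reads by default, each survey slicing its own window
  (always containing both anchors); 2% chimeras spliced from two
  abundance-weighted parents at a split point in the middle half of the
  window; 10% of reads reverse-complemented; optional per-base
  substitution errors (0 by default, so all planted identities are
  exact).

The truth table records, per read, its source taxon / parents / flip
state, and per taxon the realized nearest-cultured divergence and the
core/novel/abundant labels *under the configured thresholds* (novelty is
re-derived from realized divergence, so degenerate configurations such as
`novel_divergence = 0` label nothing novel). Everything is a deterministic
function of the seed.

What the generator does **not** emulate: PCR/primer bias, indels and
quality profiles, within-taxon 16S polymorphism, realistic taxonomic
correlation structure. Passing the end-to-end tests therefore shows the
pipeline's logic is sound under its stated assumptions — not that it
reproduces any particular real-world survey.

## Numerical and design choices

* Determinism everywhere: canonical processing order in clustering,
  lexicographic tie-breaks in the tree searches, a single seed driving
  the generator; reruns produce byte-identical artifacts (the stage
  runner writes an md5 manifest to prove it).
* Negative NJ branch lengths are clamped to 0; missing newick branch
  lengths become 1.0 with a warning rather than a silent 0.
* Whole-percent tables round half away from zero.
* Problem sizes in the test suite: property checks use up to 500 tips /
  450 reads with brute-force oracles; the end-to-end checks run the full
  default conditions (7 × 2000 reads) for three fixed seeds.

## Limitations

* The greedy clustering reproduces the *semantics* of the usual 97%
  tools, not any tool's byte-exact output; one algorithm is used for all
  datasets.
* NJ on p-distances is a pragmatic default; for publication-grade novelty
  distances an externally estimated maximum-likelihood tree should be
  ingested.
* The chimera screen needs abundance context and positional homology; it
  is not a full de-novo chimera model.
* With no spike-ins or absolute calibration, all abundance statements are
  relative.
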