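---
title: "Gene-content dendrograms from protein profiles: methods and design"
author: "ProfileTree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-content dendrograms from protein profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProfileTree)
```

## The model

For mobile genetic elements such as plasmids, no single gene is
universally present, so marker-gene phylogenies cover only a fraction of
the taxa of interest. `ProfileTree` instead treats *gene content* as the
phylogenetic signal: two replicons are similar to the extent that they
carry proteins from the same homolog families. The pipeline maps each
taxon to a binary vector over homolog clusters and builds a
neighbor-joining dendrogram from pairwise profile distances.

The method assumes (i) that homology within a family is detectable by
pairwise local alignment, (ii) that presence/absence — not copy number —
carries the signal, and (iii) that profile distance is a usable proxy for
relatedness. None of these is exact for real data: gene gain/loss is not
clock-like, horizontal transfer produces mosaicism, and annotation
quality varies. The dendrogram is therefore a similarity summary, not an
inferred evolutionary history.

## The similarity score

Every pairwise comparison uses one statistic,

$$ S(a, b) = \frac{L \cdot I}{|a| + |b|} \in [0, 0.5], $$

with $L$ the aligned-column count (gap columns included) of the optimal
Smith–Waterman local alignment, $I$ the fraction of identical columns in
that alignment, and $|a|, |b|$ the full sequence lengths. Putting *both*
lengths in the denominator makes the score robust to length mismatch: a
perfect local hit of a short peptide inside a long protein is diluted by
the long protein's length. $S = 0.5$ exactly iff the sequences are an
exact match (full-length alignment, identity 1, equal lengths) — this
anchor is what fixes the identity term as a fraction rather than a
percentage.

The score is consumed at two thresholds:

* $S \ge 0.45$ — within-proteome **duplicate** (comparison is `>=`);
* $S > 0.2$ — **cluster membership** when profiling a new taxon
  (comparison is strictly `>`).

The two comparison directions are deliberate and are covered by tests;
note $0.2 = \tfrac{1}{2}\cdot 0.4$ is the score of a full-length,
equal-length alignment at 40% identity, making the membership cutoff the
score-space analogue of the clustering identity threshold.

## Alignment engine and prefilter

Alignment is Smith–Waterman through `Biostrings::pairwiseAlignment`
(BLOSUM62, gap open 10, gap extend 1, a gap of length $L$ costing
$10 + L$). These are BLAST-family defaults; both matrix and penalties are
configurable via `scoringConfig()`. When no positive-scoring local
alignment exists the result is defined as $L = 0$, $I = 0$, score 0. The
test suite checks the engine's optimal scores against an independent,
unoptimized full-DP implementation of the same recurrences on hundreds of
random short pairs.

All-against-all alignment is quadratic, so candidate pairs are first
seeded by an exact-match word index: only pairs sharing at least one
exact $k$-mer ($k = 4$ by default) are aligned. Any alignment containing
a gapless identical run of $\ge k$ residues implies a shared $k$-mer, so
at the divergences the pipeline targets (tens of percent identity over
most of the sequence) the prefilter is lossless in practice; for the
$\ge 0.45$ duplicate threshold it is lossless by a pigeonhole argument
(a 90%-identity full-length alignment must contain runs $\ge 4$).

## Homolog clustering

A homology edge requires all three of:

* identity $\ge$ `minIdentity` (default **0.40**) over aligned columns;
* alignment length $\ge$ `minAlnLen` (default **20** columns);
* alignment covering $\ge$ `minCoverage` (default **0.60**) of the
  shorter sequence.

The coverage condition is the package's own guard, added after measuring
that optimal local alignments between *unrelated* random proteins
(uniform composition, lengths 80–300) reach 40% identity over 20+ columns
in roughly 1% of pairs — frequent enough to corrupt components at any
realistic problem size — while requiring 60% coverage of the shorter
sequence drove the measured false-edge rate to 0 in 3,000 random pairs
without losing any of 500 true homolog pairs simulated at 5% per-copy
divergence. Tools that cluster pan-genomes take the same precaution
(coverage thresholds alongside identity thresholds).

Clusters are connected components of the edge graph with $\ge 2$ members;
singletons are dropped. Components are a deterministic closure of the
pairwise relation — unlike greedy or seed-based heuristics they are
invariant to input order. The cost is single-linkage chaining: one
promiscuous protein can bridge two families. At the divergences the
generator plants, chaining does not occur (families are mutually at
background identity); on real data it is a known failure mode to audit.
Cluster ids are assigned `1..m` ordered by each component's
lexicographically smallest `taxon|protein` key, so ids are reproducible
across runs and machine word orders.

## Profiles, distances, trees

The profile matrix sets bit $(i, j)$ iff taxon $i$ has $\ge 1$ protein in
cluster $j$ — presence, not count, so paralogs do not inflate similarity.
Distances are Jaccard, $d = (q+r)/(p+q+r)$ (shared absences carry no
information), or Euclidean, $\sqrt{q+r}$ on binary rows (unnormalized;
equivalently the square root of the Hamming distance). The two are
monotonically related pair-by-pair only through their shared numerator
$q + r$; they can and do produce slightly different trees, and both are
always available. Two all-zero profiles are defined to be at Jaccard
distance 0 (identical emptiness) with a warning rather than NaN, keeping
neighbor joining well-defined.

Neighbor joining is the canonical Saitou–Nei agglomeration (via
`ape::nj`), exact on additive matrices — the property tests generate
random edge-weighted trees on 4–12 leaves and require zero
Robinson–Foulds distance and path-length agreement within $10^{-9}$.
Profile distances are not additive, so NJ can produce negative branch
lengths; these are clamped to 0 and the total deficit logged (no
compensating transfer to the sibling edge — the simplest auditable
convention). Newick labels are restricted to `[A-Za-z0-9_.-]`, other
characters mapped to `_` with a logged mapping, for viewer compatibility.

## Insertion via the correlation filter

The saved library is the profile matrix *plus all member sequences*. A
new taxon is profiled by aligning its proteins against cluster members
(prefiltered, batched) and setting bit $j$ when some protein scores
$S > 0.2$ against some member of cluster $j$. The profile is then
correlated (Pearson) with every library row. Design choices:

* **Zero-variance vectors** (all-0 or all-1 profiles or rows) have no
  defined Pearson coefficient; the comparison is reported as 0 with a
  warning. An all-ones row genuinely carries no discriminating signal
  under this statistic.
* **Acceptance** is purely `best coefficient >= threshold` (default 0.5).
  Corroborating biological evidence (e.g. that the plasmid comes from the
  expected host group) is intentionally out of machine scope and is
  surfaced in the report text for human review.
* **No new clusters** are created at insertion; proteins matching nothing
  are ignored. The library is knowingly incomplete, and the remedy is a
  full rebuild, not incremental cluster creation.
* **Batch semantics**: all candidates are profiled and correlated against
  the *original* library; accepted rows are then appended together and
  the tree rebuilt once. Decisions therefore do not depend on batch
  order.
* After rebuilding, each inserted taxon's nearest original leaf by tree
  path is compared with its best-correlated taxon; a mismatch is a
  warning, not an error — with several taxa inserted at once the nearest
  neighbour can legitimately be another newcomer.

Tree augmentation recomputes the full distance matrix and NJ tree; no
incremental topology editing is attempted.

## The synthetic-proteome generator

`generateFixtures()` emulates the study conditions every stage is
validated under: `nFamilies` ancestral proteins (uniform-random residues,
lengths 80–300, comfortably above the 20-column alignment floor), each
present per taxon with probability 0.8, each copy independently mutated
at 5% per residue (pairwise family identity ≈ 90%), 5 private random
proteins per taxon, and with probability 0.2 a within-taxon duplicate of
a present copy differing by exactly one substitution — which guarantees
the duplicate pair scores $\ge 0.45$ by construction. Uniform amino-acid
composition is a simplification; identity thresholds are
composition-robust at these divergences. The generator emits ground truth
(family labels, duplicate pairs, expected incidence matrix, expected
cluster ordering), and the same seed reproduces byte-identical FASTA
output.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate about real data: non-uniform residue composition and
length distributions, domain-level mosaicism and chimeric fusions,
gradual divergence continua straddling the 40% threshold, annotation
noise (fragmented or missed ORFs), and horizontal transfer between
lineages. Families whose post-dedup members span fewer than two taxa are
recorded as expected singletons (dropped), keeping the truth tables exact
even at extreme parameter corners.

## Problem sizes and determinism

The shipped validation uses desk-scale sizes chosen to exercise every
code path: 6 taxa × 10 families for end-to-end recovery and insertion,
200 random pairs (length ≤ 30) for the alignment oracle, 50 random
additive matrices (4–12 leaves) for NJ, 20 independent disjoint-pool
draws for the exclusion property, and 1,000 random triples for the metric
inequalities. All randomness is seeded; run manifests contain parameters
and input digests but no timestamps, so identical inputs produce
byte-identical outputs, including the versioned JSON library archive.

## Known limitations

Single-linkage chaining (above); quadratic growth of candidate pairs with
total proteome size (the prefilter mitigates but does not bound it);
Pearson correlation degenerating on all-present profiles; clamped
negative branch lengths slightly biasing path lengths on strongly
non-additive matrices; and the score's length normalization penalizing
genuine homology between a full-length protein and a fragment — a
fragment at 100% identity over its whole length scores
$|b| / (|a| + |b|) < 0.5$, below the duplicate cutoff once the fragment
is shorter than ~82% of the full protein.
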