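---
title: "Identifying drifting fish eggs from COI barcodes: models and design choices"
author: "fisheggs package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying drifting fish eggs from COI barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fisheggs)
```

## The problem

Fish eggs drifting down a river carry almost no diagnostic morphology, yet
their species composition through the spawning season is exactly what a
fisheries manager needs: which species are reproducing, and in which
months. DNA barcoding solves the identification step — a short fragment of
the mitochondrial COI gene (here a 569-bp trimmed frame of the standard
~648-bp amplicon) is sequenced from each egg and compared against a
reference library of known species — provided three conditions hold: a
*barcoding gap* (within-species divergence well under 1%, between-species
divergence above it), an adequately sampled reference library, and an
explicit, reproducible decision rule for turning percent-identity matches
into taxonomic names.

`fisheggs` implements that full decision pipeline: exhaustive similarity
search of each query barcode against a local reference library, a
hierarchical assignment cascade, independent verification by
distance-based tree building and lineage clustering, and month-resolved
community summaries. A survey simulator with known truth closes the loop,
letting every stage be tested end to end.

## The assignment cascade

Each query is ranked against every reference by percent identity (matches
over compared columns of an ends-free pairwise alignment). Best and
second-best identities are *per species*: the runner-up is the best hit
among species other than the top species, the convention used by curated
barcode databases for "interspecific matches". The cascade then applies,
in strict order:

* **P1** — best species identity > 99% and second-best < 99%: the query
  takes the best species' name.
* **P1-genus** — best and second-best both > 99% within one genus: the
  query is identified to that genus.
* **P2** — all of the top 100 hits are one species (and the best hit
  clears 99%): that species. The identity guard is our addition; an
  unguarded consensus rule would assign species names at arbitrary
  divergence, contradicting the 95% floor below.
* **F1** — top five hits one species, best identity > 99%: that species.
* **F2** — best identity > 95%: the majority genus among the top five
  (a tied majority resolves to unidentified).
* **F3** — otherwise unidentified.

All comparisons are strict: identity exactly at a threshold falls through
to the next rule ("more than 99%" means more than). One subtlety the test
suite documents: verdict levels are *not* globally monotone in the species
threshold. P1's "runner-up below the bound" clause becomes easier to
satisfy as the bound rises, so a query left unidentified by a tied genus
majority at a 95% bound can become a clean P1 species call at 99%. What
does hold, and is tested: a species call always requires the best identity
to clear the bound, and queries below the genus floor stay unidentified at
every bound.

An `ExclusionOverride` generalises the ecological tie-break that field
studies sometimes need: when a species known to be absent from the study
area (say, from recent surveys) either wins a verdict or blocks a species
call, its hits are removed and the cascade re-runs once, with the override
recorded in the audit trail.

## Alignment and identity

Queries and references are variable-length fragments of one locus, so the
aligner is semi-global with free end gaps on both sequences (overlap
alignment) and affine gap costs (match +1, mismatch −1, a gap run of
length $L$ costing $5 + 2L$). It is written in C++ because the search is
exhaustive by design — no seeding heuristics at desk scale — and the
full-pipeline runs align tens of thousands of pairs.

Identity is counted over *compared* columns only: gap columns and columns
with an IUPAC ambiguity code in either row are excluded from the
denominator, which keeps the 99%/95% thresholds independent of fragment
overhangs. Two degenerate cases are handled explicitly:

* **Spurious short overlaps.** Between unrelated sequences, the
  best-scoring overlap alignment can be a dozen perfectly matching bases —
  identity 1.0 on a meaningless region. Alignments with fewer than
  `min_overlap` comparable columns (default 100, shrinking to the shorter
  sequence for short inputs) therefore count as non-matches. Without this
  floor, strand orientation against reverse-complemented queries is
  unreliable.
* **Strand orientation.** Each query and its reverse complement are
  evaluated against the whole library; the strand with the higher best-hit
  identity wins, ties keeping the forward strand.

## Distances, trees and lineages

The Kimura two-parameter distance separates transitions ($P$, the A↔G and
C↔T proportion) from transversions ($Q$):

$$d = -\tfrac{1}{2}\,\ln\!\big[(1 - 2P - Q)\sqrt{1 - 2Q}\,\big].$$

Pairs outside the model's domain ($1-2P-Q \le 0$ or $1-2Q \le 0$) are
saturated; in the distance matrix they are flagged and set to twice the
largest finite distance, a documented fallback that keeps downstream
clustering defined. Sites are deleted pairwise, not listwise, preserving
signal on 569-bp fragments.

The neighbor-joining tree uses the canonical agglomeration (join the pair
minimising $Q(i,j) = (n-2)\,d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)$), with
two determinism choices the tests rely on: ties in the joining criterion
break to the lowest (row, column) index pair with new nodes appended last,
and negative branch lengths are clamped to zero. Bootstrap supports
resample alignment columns with replacement, rebuild the tree per
replicate, and label each internal edge with the percentage of replicates
containing the same bipartition.

"Independent lineages" — the tree-based cross-check on the cascade — are
operationalised as single-linkage clusters of the K2P matrix at the 1%
species boundary: two barcodes share a lineage exactly when a chain of
pairwise distances at or below the threshold connects them. Single linkage
is the right linkage here because it reproduces what a reader counts on a
tree: clades separated from everything else by more than the threshold.
On surveys with a real barcoding gap, lineage count equals species count
and clusters coincide with cascade verdicts; both facts are asserted in
the acceptance tests.

Multiple alignment is deliberately out of scope. The fixed-width frame
that distances need is built by *reference-anchored projection*: each
sequence is aligned to a designated anchor and read off column-by-column
against the anchor's coordinates (insertions relative to the anchor are
dropped, uncovered anchor positions become gaps). For near-identical
barcodes of one locus this is equivalent to a profile alignment at a tiny
fraction of the cost.

## The survey simulator

The generator emulates the statistical structure the analysis assumes,
with defaults set to the study conditions the pipeline is built for:

| parameter | default | meaning |
|---|---|---|
| `barcode_length` | 569 | trimmed COI frame width |
| `kappa` | 4 | transition/transversion rate ratio |
| `intraspecific_divergence` | 0.003 | expected within-species K2P |
| `interspecific_divergence` | 0.03 | minimum between-species K2P |
| `monthly_sampling` | 30 | expected eggs per active species per month |
| `dropout_rate` | 0.38 | specimen-level amplification failure |
| `unknown_species_fraction` | 0.01 | eggs from off-library taxa |
| `months` | May–September | the sampling season |

Species ancestors evolve along a random tree scaled so every
between-species distance exceeds the configured interspecific divergence;
reference individuals and eggs then diverge from their ancestors at half
the within-species divergence (so pairwise within-species distances have
the configured expectation). Substitutions follow the exact K2P transition
probabilities, making the estimated distance a consistent estimator of the
simulated one — the generator inverts the analysis model. The realised
barcoding gap is rejection-checked; base composition is uniform at the
root.

Design choices a user should know:

* **Dropout is specimen-level Bernoulli**, independent of species and
  month — failures in long-stored ethanol collections are a property of
  preservation, not of sequence content. Dropped eggs keep their metadata
  row but contribute no sequence, mirroring failed PCR.
* **`monthly_sampling` is per active species per month** (Poisson), which
  makes conditions like "at least 30 eggs per species per active month"
  directly expressible.
* **No indels are simulated**: the analysis frame is a clean fixed-width
  alignment, as after quality trimming; indel handling is exercised by the
  alignment unit tests instead.
* **Off-library taxa** are distant relatives of the same locus (evolved
  far beyond the species boundary from a library ancestor,
  rejection-checked to stay at least 5% from every reference), so
  unknown-species eggs exercise the genus floor and the unidentified
  verdict rather than degenerate alignments.

What passing tests on simulated data do *not* show: robustness to
contamination or chimeric reads, to reference misidentification, to
heterogeneous within-species structure (the simulator draws one
star-shaped cloud per species), or to rate variation across sites. Real
surveys should treat borderline identities near the thresholds with the
same caution the cascade encodes.

## Phenology summaries

Occurrence is presence/absence per taxon per month — at least one assigned
specimen, eggs and larvae both counting by default (a flag restricts to
eggs). Species-level verdicts keep their binomials; genus-level verdicts
pool as "Genus spp", splitting into numbered lineages when the lineage
partition separates them; unidentified queries become "Unknown species k"
per lineage. Monthly richness counts *all* taxon rows, matching the total
row of the familiar community-table layout, while the species-only count
is exposed separately. A spawning period is the set of months with
occurrences; it is "continuous" when no gap months interrupt the span.
Sparse sampling can only shrink inferred windows, never grow them — with
no dropout and dense sampling the tests require exact recovery of the
generator's windows, with sparse sampling a subset.

The package ships one plain-text fixture: the taxon-by-month community
table and specimen accounting of a published May–September drifting-egg
survey (19 taxon rows, of which 14 species-level; monthly richness
7/11/9/10/1; 641 selected eggs of which 397 yielded usable sequences, a
38% failure rate; 392 of the 397 high-quality eggs assigned to species).
The acceptance tests and `scripts/acceptance.R` recompute all of these
numbers from the fixture through the package's own functions.

## Problem sizes

The shipped test suite and acceptance script size their simulations for
desk-scale reproducibility: reference libraries of 10 species × 2–3
individuals, surveys of a few hundred to a few thousand eggs (about 31
eggs per species per active month for the recovery runs; roughly 10,000
specimens for the dropout realisation check), 200 random additive matrices
of 4–12 taxa for the neighbor-joining consistency sweep, and bootstrap
sweeps of 150–1500 replicates for the support self-consistency check.
These sizes were chosen so that every stochastic check sits comfortably
inside three standard errors of its target while a full run stays fast
enough to be re-run habitually.

## Known limitations

* Percent identity is aligner-dependent near the thresholds; parity with
  any online database's reported similarity percentages is not claimed,
  only with the rules applied to them.
* The saturated-distance fallback (twice the finite maximum) is a
  convention, adequate for libraries of congeners and confamilials but not
  for deeply divergent mixtures.
* The lineage count on a real survey depends on which specimens yielded
  sequences; it is a cross-check, not an estimator of species richness.
* Exit-code classification in the command-line driver distinguishes input
  errors (2) from internal failures (3) heuristically for errors raised
  outside the package's own condition classes.
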