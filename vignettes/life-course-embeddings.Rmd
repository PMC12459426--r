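---
title: "Life-course embeddings of register event histories: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Life-course embeddings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Nationwide health registers record, for every resident, a lifelong stream of
coded events: ICD-10 hospital diagnoses, ATC-coded prescription purchases,
SKS-coded procedures, and — where social registers are linked — annual
indicators of childhood adversity (material deprivation, loss or threat of
loss, familial dysfunction, all restricted to ages below 16). `lcembed`
treats each person's event history as a document and each coded event as a
word, learns a global vector representation for every code, and provides the
downstream exploratory machinery: cosine-similarity neighborhoods around
query terms (for example sleep-related diagnoses and medications),
hierarchical and consensus clustering of the selected terms, a
two-dimensional landscape projection with kernel density estimation,
neighborhood networks, and classical surveillance statistics (age-specific
incidence rates with within-term quantile categorization, and period
prevalence trends from aggregate count tables).

Because individual-level register data are access-restricted, the package
ships a synthetic register-cohort generator with *planted* co-occurrence
structure. Every downstream stage is tested against that known ground truth
or against independent small-scale oracles.

## From events to sentences

`buildSentences()` applies three transformations, in this order:

1. **Truncation.** Codes are reduced to the granularity at which register
   analyses usually pool them: ATC to 5 characters, SKS procedures to 6,
   ICD-10 to 4 significant characters. ICD-10 dots are stripped first, so
   `G47.3` and `G473` are the same token; the undotted form is the canonical
   internal representation (registers store undotted codes, printed output
   may re-insert dots).
2. **Vocabulary filtering.** Tokens with corpus-wide count below
   `minCount` (default 20) are removed *before* sentences are emitted, so a
   training window never spans a dropped token. Filtering first, then
   emitting, matches the usual embedding pipeline in which the vocabulary is
   pruned before training; it also makes the operation idempotent.
3. **Ordering.** Tokens are sorted by calendar year; ties within a
   (person, year) block are broken by a seeded uniformly random shuffle.
   Registers are annual, so within-year order is an artifact of recording
   delays; shuffling removes it (and incidentally decouples the sentence
   from the exact recording sequence). The shuffle happens once, at corpus
   construction, not per epoch; re-shuffling per epoch would be a sensible
   sensitivity analysis but changes nothing asserted here.

## The embedding model

`trainEmbeddings()` fits a skip-gram model with hierarchical softmax: each
token predicts its neighbors within a context window, and the output
distribution over the vocabulary is factorized along a Huffman tree built
from corpus frequencies, so one update costs O(log V) instead of O(V).
The trainer is implemented in C++ (single-threaded, driven by the classic
64-bit linear congruential generator), and follows the reference skip-gram
algorithm: uniform dynamic window (each position draws an effective window
from 1..`window`), linear learning-rate decay from the initial rate to
1/10,000 of it, and input-layer (hidden) vectors returned as the embedding.
Training is therefore bit-reproducible for a fixed corpus and seed.

Defaults follow the configuration used for nationwide life-course data:
`dim = 200`, `window = 100`, `epochs = 25`, `learningRate = 0.05`,
`minCount = 20`. A window of 100 covers most life-course sentence lengths —
`sentenceLengthDistribution(corpus, window = 100)` reports the exact
coverage (about 94% of sentences in the packaged synthetic cohort), so for
most persons every pair of lifetime events can appear as a training pair.
Two deliberate deviations from configurations described elsewhere:

* **Optimizer.** We use the reference implementation's linear
  learning-rate decay rather than an adaptive-gradient schedule; the
  cosine-geometry properties tested here are insensitive to this choice,
  and the linear schedule keeps the trainer simple and exactly
  reproducible.
* **Hidden-layer vectors.** The embedding is the input-layer ("hidden
  layer") matrix, not an average of input and output representations.

`trainAlternativeEmbeddings()` provides a second, genuinely different
co-occurrence algorithm for cross-model robustness checks: positive
pointwise mutual information (PPMI) weighting of the window co-occurrence
matrix followed by truncated SVD, with rows scaled by the square root of
the singular values. It is deterministic, covers the identical vocabulary,
and is O(V^2) in memory — fine for the vocabulary sizes used here (tens to
tens of thousands of terms), not for web-scale corpora.

## Similarity, clustering, networks

All geometry is cosine similarity,
cos(A, B) = sum(A_i B_i) / (||A|| ||B||), with cosine distance 1 − cos.
Zero-norm vectors raise an error rather than silently returning 0.
`nearestNeighbors()` is exact (no approximate indexing; the vocabulary is
small enough), with ties broken by vocabulary index so results are
deterministic. `closestAdversities()` ranks adversity tokens by their
*maximum* similarity over the queried sleep terms (reporting the arg-max
term); mean aggregation is available via `aggregate = "mean"` — max was
chosen as the default because an adversity tightly linked to one specific
sleep problem is more interesting here than one mildly related to all.

Hierarchical clustering uses UPGMA (average linkage) on the cosine distance
matrix. Cluster-number diagnostics (`clusterNumberDiagnostics()`) report the
Calinski-Harabasz index, mean silhouette width and the gap statistic for a
K-means clustering of the L2-normalized vectors; normalizing first makes
Euclidean K-means approximately equivalent to cosine geometry, so the
hierarchical and partitional methods see commensurable structure. The gap
statistic draws its reference datasets uniformly within the bounding box of
the data (B = 50 by default, seeded). The number of clusters is never chosen
automatically: diagnostics are reported, the cut is the analyst's.

`consensusCluster()` runs single-linkage, complete-linkage, K-means and
Gaussian-mixture clustering at a common k (K-means with 10 seeded restarts;
the mixture model via EM with hierarchical initialization) and records, for
each term pair, the fraction of *methods* that co-assigned them — each
method contributes one assignment, so a 2-of-4 disagreement is exactly 0.5.
A method that fails to deliver k non-empty clusters is excluded with a
warning rather than silently padded. The per-term consensus score is the
mean co-clustering frequency with the other members of the term's reference
cluster (UPGMA by default); on the synthetic cohort it reproduces the
qualitative pattern that rarer terms have shakier cluster membership.

`buildTermNetwork()` draws, by default, only seed-to-neighbor edges from the
k-NN queries (the `"knn"` rule); a `"threshold"` rule connecting every node
pair above a similarity cutoff is provided as the documented alternative,
since a figure of "the closest neighborhood" does not pin down which edges
are drawn. The graph is undirected, self-loops are impossible, duplicate
pairs are collapsed, and node degree is always recomputed from the edge
list (a class invariant).

## Landscape projection

`projectEmbedding()` reduces the embedding to two dimensions for
visualization. The packaged backend is deterministic PCA on L2-normalized,
mean-centered vectors. A neighbor-based manifold projection is the natural
alternative and the function's `nNeighbors`/`iterations` arguments document
that lineage, but no such backend is required: the projection is
visualization-only, no downstream statistic depends on it, and the tests
assert only aggregate topology (planted communities remain closer to their
own members in 2D than to others) — properties PCA satisfies while being
exactly reproducible everywhere. `landscapeDensity()` is a 2D Gaussian KDE
(normal-reference bandwidth by default, configurable) whose surface is
non-negative and integrates to ~1 over the padded grid (checked to 1% by
trapezoidal quadrature in the tests).

## Incidence and prevalence

`incidenceRates()` uses the first-ever-event convention: a person is at
risk for a term from birth until the year of their first event of that
term, inclusive, and exits the risk set afterwards (a `recurrent = TRUE`
switch counts every event with no exit). Age is event year minus birth
year; persons contribute whole-year increments to 5-year age bands (0-4
through 40-44 by default). Rates are events per 100,000 person-years.
Cells with zero person-years are flagged undefined, never reported as zero.
Censoring is annual: a person contributes person-years only for calendar
years inside the period and before the observation end. Within each term,
`quantileCategorize()` maps age-band IRs to q quantile bins by ranking
(ties averaged), so the categories are monotone in IR and invariant under
any strictly monotone transformation; all-identical IRs collapse to a
single bin. `prevalenceTrend()` is deliberately plain arithmetic on
aggregate tables — affected/population scaled per 1,000 or percent — since
published register aggregates arrive pre-weighted.

## Robustness diagnostics

`subsampleStability()` retrains the whole sentence-to-embedding pipeline on
person-level subsets (disjoint partition by default, bootstrap optionally),
each run with its own seed, and reports all pairwise Spearman correlations
between the runs' cosine distance matrices, computed on the vectorized
upper triangle (diagonal excluded) over the vocabulary shared by all runs.
`crossModelAgreement()` is the same statistic between two embedding
backends. Self-comparison is exactly 1; comparison of independent random
embeddings is ~0.

## The synthetic cohort generator

`generateCohort()` emulates what the real register cohort supplies: 5,000
persons born 1980-2015 and followed to 2022 (so ages 7-42 at end of
follow-up), a 60-code vocabulary spanning all four code systems, and
age-dependent rates (medication-like codes rising through adulthood,
apnea-like codes peaking late, early-life codes peaking in childhood;
adversities only before age 16). Events are Poisson: per person, year and
code, the count is drawn with rate `backgroundRate` times the code's
age-band weight. Co-occurrence structure is planted through three
communities of 20 codes each: every person belongs to each community
independently with probability `membershipRate` (default 0.25), and members
accrue member codes at `boost` (default 20) times the baseline rate,
implemented as an additional Poisson draw at (boost − 1) times baseline.

Two generator design choices deserve justification:

* **Membership-conditional boost.** An earlier formulation conditioned the
  boost on a person having drawn at least one member code at baseline.
  Over four decades of follow-up the probability of that trigger
  approaches 1 for every community, so every person receives every boost
  and the planted partition dissolves (and sentences balloon). A latent
  membership keeps the boost conditional — it is still a conditional
  Poisson superposition — while keeping the communities selective at any
  follow-up length.
* **Default rates.** `backgroundRate = 0.004` events per code per
  person-year yields roughly 20-50 lifetime register events per person at
  the 60-code scale, an order-of-magnitude-realistic scaled-down stand-in;
  real marginal code frequencies are unknown here and everything is
  configurable per code via the age profiles.

What the generator does *not* emulate: mortality and emigration (follow-up
ends at a fixed year for everyone), family linkage microstructure
(adversities are drawn directly as person-level events), code hierarchies
beyond truncation, and secular trends in coding practice. Passing tests on
this cohort therefore show that the pipeline recovers co-occurrence
structure of the planted kind — they do not validate conclusions drawn
from any particular real register, where confounding, censoring and coding
drift all operate.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline at the
packaged study conditions (5,000 persons, 60 codes, boost 20) with a
reduced training configuration — `dim = 50`, `window = 100`, `epochs = 5` —
which trains in about two minutes on one CPU and recovers the planted
communities exactly (adjusted Rand index 1.0 for both K-means and the
UPGMA 3-cut, within-community mean cosine ≈ 0.9 versus ≈ −0.2 across);
the package defaults remain `dim = 200`, `epochs = 25`. Smaller unit-test
fixtures use 200-800 persons. Other numerical conventions: k-NN ties break
by vocabulary index; K-means uses 10 seeded restarts; the gap statistic
uses 50 seeded uniform reference draws; PCA signs are fixed by making the
largest-magnitude loading of each component positive; quantile bins use
average ranks so ties share a bin; and every stochastic step takes an
explicit seed, with the C++ trainer using its own deterministic generator
independent of R's RNG state.

## Worked example

```{r example, eval = FALSE}
library(lcembed)

spec <- exampleCohortSpec(nIndividuals = 1000, seed = 7)
events <- generateCohort(spec)
corpus <- buildSentences(events, minCount = 10, seed = 7)
emb <- trainEmbeddings(corpus, dim = 50, window = 100, epochs = 5, seed = 7)

## neighborhoods of the packaged sleep-problem query terms
sleep <- resolveQueryTerms(emb)
nearestNeighbors(emb, "F510", k = 10)
closestAdversities(emb, unique(sleep$token), m = 3)

## clusters, diagnostics, consensus
d <- cosineDistanceMatrix(emb)
cl <- upgmaCluster(d, k = 5)
clusterNumberDiagnostics(emb, kRange = 2:8, seed = 7)
consensusCluster(emb, k = 5, seed = 7)

## landscape and incidence
proj <- projectEmbedding(emb)
dens <- landscapeDensity(proj)
inc <- quantileCategorize(
  incidenceRates(events, cohortCensus(spec),
                 terms = unique(sleep$token), period = c(2010, 2021)))
```

## Known limitations

* The PPMI-SVD alternative backend densifies the co-occurrence matrix;
  with very large vocabularies use the skip-gram backend only.
* Sub-annual timing is out of scope: the year is the atomic time unit
  throughout (sequences, incidence, prevalence).
* Survey-style prevalence inputs are taken as published aggregates; no
  weighting or representativeness adjustment is attempted.
* The consensus denominator counts methods, not method-by-restart runs;
  restart variability is absorbed into each method's single seeded
  assignment.
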