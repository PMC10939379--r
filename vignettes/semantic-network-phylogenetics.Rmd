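---
title: "Semantic-network phylogenetics: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic-network phylogenetics: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semphylo)
```

## Overview

semphylo compares species by the *functional content* of a gene set
rather than by sequence: each species' gene list is translated into a set
of enriched biological-process terms, the term sets are compared on a
bias-corrected ontology graph, and the resulting distance matrix drives
clustering, embedding and component analyses. This vignette is the
package's own account of the model: its assumptions, the tunable
parameters and their defaults, the numerical conventions, and what the
synthetic-data tests do and do not demonstrate.

## The ontology model

The ontology is a rooted directed acyclic graph of terms connected by
child-to-parent `is_a` links (`part_of` can be enabled when loading OBO
files; the default is `is_a` only, the conservative choice when the
provenance of other relation types is unclear). Exactly one root is
required, every term must reach it, obsolete terms are dropped, and
cycles are fatal.

Two structural statistics summarise each term *t*:

* **Information content** `IC(t) = -log2((D(t) + 1) / N)`, with `D(t)`
  the number of distinct descendants (self excluded) and `N` the universe
  size. The root has IC 0, leaves `log2(N)`. IC is purely structural —
  annotation frequencies play no role.
* **Semantic value** `SV(t) = sum over ancestors a of sw(a)`, where
  `sw(a) = 1 / (1 + exp(-1 / IC(a)))` is a logistic weight in (0.5, 1]
  that decreases with the ancestor's IC; `sw` at IC = 0 is defined by its
  analytic limit, 1, so the root always contributes exactly 1. SV grows
  strictly along any root-to-leaf path and is large both for deep terms
  and for terms inside densely described regions.

For `D` and `SV` a term is neither its own ancestor nor its own
descendant; for similarity computations (below) common-ancestor sets
*include* the terms themselves. The universe for IC can be restricted to
terms carrying at least one (propagated) annotation — the pipeline's
default, since unannotated terms can never appear in an enrichment result
— and the restricted universe is closed under ancestors so that
`IC(root) = 0` always holds. With a full-graph universe the values are
identical on graphs where every term is annotated.

## Standardization (graph pruning)

Terms strictly exceeding the `pct = 20` percentile of **both** the IC and
the SV distribution are trimmed: these are specific terms inside expanded
branches, exactly where annotation depth differs most across species.
Percentiles use the linear-interpolation quantile (R type 7); trimming
uses strict inequality on both metrics, so the root (the minimum of both
distributions) is always retained. Note the predicate's conjunction means
pruning is aggressive by design — typically 65–85% of terms are trimmed
on both synthetic graphs and real process ontologies — because only one
of the two criteria being high is tolerated.

Every term is mapped to its *most proximal retained ancestors*: each
parent path is ascended to the first retained node, and collected targets
that are strict ancestors of other targets are dropped. A retained term
maps to itself. Re-applying standardization to the retained sub-DAG with
the same stored thresholds (and the terms' metric values) retains
everything — the stored cutoffs, not re-derived percentiles, define the
graph's identity.

## Enrichment and profile selection

Annotations are first closed under ancestors (the true-path rule; the
root is not added). Enrichment of a species' gene list is the upper-tail
hypergeometric probability `P(X >= k)` for each term with at least one
annotated gene; the universe is the species' own annotated gene set.
Terms with raw p below `p_cut = 0.05` are then *prioritized* by an
empirical permutation rank: `R = 1000` same-size random gene draws from
the universe give `p_adj = (1 + #{p_perm <= p_obs}) / (1 + R)`. Because p
is strictly decreasing in the overlap at fixed margins, the rank is
computed on overlap counts — exact, with no floating-point comparisons.

The profile keeps terms passing both cuts (`adj_cut = 0.05`); if fewer
than `floor = 100` survive, the selection is extended down the ranking
(ordered by `p_adj`, then `p_hyper`, then term id — a total order) among
raw-passing terms. The floor keeps profile cardinalities comparable
across species with very different annotation depth; it never invents
candidates beyond the raw cut. Profiles are then mapped onto the
standardized graph, and mapped targets with `IC < ic_min = 0.1`
(near-root, uninformative processes) are dropped.

## Similarity and distance

A global similarity matrix is computed over the retained terms with IC,
SV and sw *recomputed on the pruned sub-DAG* (the comparison space is the
standardized graph, so its own metric geometry applies). Three pairwise
measures are averaged into a consensus score; since the source
formulations live on heterogeneous scales, each is normalised into [0,1]
and the normalisation is declared rather than inherited:

* Resnik: `IC(MICA) / IC_max`;
* XGraSM: mean IC of informative (IC > 0) common ancestors divided by
  `max(IC(a), IC(b))`, 0 when no informative common ancestor exists;
* AggregateIC: `2 * sum(sw(c), c in CA(a,b)) / (SV+(a) + SV+(b))` with
  `SV+` adding the term's own weight; self-similarity is exactly 1.

Enriched-term similarity is the mean of the matrix over the cross product
of two mapped target sets; species similarity is the best-match average
over the two enriched sets; distance is `1 - SSim` with the diagonal
forced to 0. The diagonal convention matters: Resnik and XGraSM
self-similarities are below 1, and a term mapping to several mutually
distant targets has cross-product self-similarity below 1, so
`1 - SSim(s, s)` would be positive and can even (rarely, by up to a few
hundredths) fall below a cross-species distance. Defining the self
distance as zero keeps the matrix a valid dissimilarity.

## Trees, embeddings, evaluation

Clustergrams use Ward's minimum-variance linkage (`ward.D2`) on the
precomputed semantic distances. Ward on a non-Euclidean dissimilarity is
technically off-model; it is applied deliberately as the method's
standard choice, with average and complete linkage available for
sensitivity checks. Cluster labels come from cutting the tree; Newick
export round-trips through `ape`.

Two-dimensional embeddings use metric MDS: classical scaling provides the
initial configuration and Sammon stress minimisation refines it.
Coincident species (distance 0) are collapsed before the fit — the stress
function divides by input distances — and re-expanded afterwards; a
degenerate initial configuration is jittered reproducibly under the
user's seed.

Agreement with reference taxa is measured by the entropy-based
homogeneity score `1 - H(truth | clusters) / H(truth)` (defined as 1 when
the reference has a single class, logged) and by the mean silhouette
width computed on the distance matrix itself, never on embedded
coordinates. Distance-matrix correlations (e.g. against sequence-derived
matrices) use Pearson correlation of upper-triangle entries, optionally
subsampling at most 80 species per group so large groups cannot dominate.

## Components and mechanism evaluation

Within a kingdom, a term is *quasi-omnipresent* when it appears (via the
standardized mapping) in strictly more than 90% of species; selected
terms whose selected descendants also qualify are removed, keeping the
most specific representatives. *Generic* terms sit at shortest-path
distance exactly 2 from the root (multi-path terms use the shortest
distance) and qualify when linked by descendancy to sub-threshold
enriched terms in strictly more than 50% of species.

The association matrix scores each selected term against each species by
`-log10` of the term's own adjusted p-value when enriched, else of the
minimum adjusted p-value among its enriched strict descendants, else 0;
own enrichment takes precedence even when a descendant is more extreme.
Log base 10 is used throughout and zero p-values are clamped to the
smallest representable double. An optional reduction into `G = 50`
semantic groups clusters the selected terms by consensus similarity
(average linkage on the original graph, so trimmed generic terms remain
comparable) and averages member scores; the exact grouping criterion is a
declared stand-in, since several choices would be defensible.

The matrix is factorized by non-negative matrix factorization with
Lee–Seung multiplicative updates (Frobenius objective, k = 3). The
error sequence is non-increasing; iteration stops at `max_iter = 500` or
relative improvement below `tol = 1e-8`. Initialisation uses
non-negative double SVD (the variant filling zeros with the matrix mean,
to avoid entries locked at zero under multiplicative updates) plus four
random restarts, keeping the lowest-error fit — multiplicative updates
alone are prone to local minima. Species are assigned to the component
with the largest coefficient.

Mechanism evaluation controls annotation-size bias before profiling: the
target extremity is the mean of the species' 10 lowest `log10`
hypergeometric p-values from the reference analysis, and an iterative
binary search finds the largest subset size whose single-probe minimum p
stays within the target's order of magnitude (`floor(log10 p)`, with a
configurable magnitude tolerance). One random probe per size is noisy by
construction; the 30-repetition outer loop absorbs it. Annotations under
10 genes are used whole. Consensus profiles keep terms enriched in
strictly more than 20% of 30 generated gene sets (the count of generated
sets is a declared default; the method's description does not fix it).
Component-exclusion analysis removes a component term set from every
profile's mappings, drops species whose profiles empty (logged), and
recomputes homogeneity and silhouette at k = 3.

## The synthetic generator

`generate_dag()` builds a rooted DAG in layers (default 150 terms, depth
6), each term attaching to 1–3 parents of shallower layers with the
parent-count distribution skewed toward single inheritance (0.7 / 0.25 /
0.05), roughly matching the tree-like character of real process
ontologies. `generate_kingdom_corpus()` plants a shared core module
(8 terms) and one 6-term module per kingdom. Kingdom modules are drawn
from *branch-exclusive* term pools — terms descending from a single
root-child — and the core from terms with no ancestry in those branches.
This mirrors the biological picture (lineage-specific biology occupies
distinct ontological regions) and is also what makes the planted signal
survive standardization: modules scattered uniformly across the graph
would be remapped onto shared ancestors and erased, by construction
rather than by any failure of the comparison method.

Each of the 60 species (20 per kingdom) gets its own namespaced universe
of 600 genes; each module term owns a dedicated block of 8 genes, the
remaining genes carry 1–2 random background terms, and each gene gains an
extra random term with probability `noise = 0.05`. The 80-gene query
takes `signal = 0.9` of its genes from the species' module blocks,
allocated evenly across module terms (a species expresses each of its
active processes), yielding per-term hypergeometric p-values around
1e-3 to 1e-4 — enriched, but far from degenerate. These defaults are the
study conditions for all end-to-end tests.

What the generator does *not* emulate: real GO topology statistics
(term counts in the tens of thousands, heavy multi-parent regions),
annotation sparsity and inter-species correlation of annotation depth,
gene-level homology structure, and enrichment signals entangled across
overlapping gene sets. Passing the planted-structure tests therefore
shows the machinery is correct and sensitive under honest noise, not that
any particular real dataset will separate taxa.

## Numerical conventions and edge cases

* `sw` at IC = 0 is 1 (analytic limit); IC values are floored at 0 when a
  restricted universe makes a ratio exceed 1.
* Percentile thresholds: quantile type 7; trimming strictly above both.
* Ties in profile ranking break by `(p_adj, p_hyper, term id)`.
* Boundary rules: coverage filter keeps `>= 75%` (inclusive — "above" is
  read inclusively for ties and documented); core `> 90%`, generic
  `> 50%`, consensus `> 20%` are all strict.
* Degenerate inputs: a standardization that trims everything but the root
  warns; an all-zero association matrix, an empty effective query, or a
  profile that empties after IC filtering are errors naming the species.
* Problem sizes in the test-suite simulations (ontologies up to 300
  terms, 60 species, permutation counts 99–199 against an analysis
  default of 1000) were chosen to exercise every code path at
  desk-scale; the reported statistics are insensitive to the permutation
  count beyond its resolution `1/(R+1)`.

## Known limitations

* The permutation prioritization is one concrete reading of
  "score-frequency reordering with permutation resampling"; the original
  algorithm is not fully specified by its description, so the empirical
  rank estimator is used and documented as such.
* The consensus averages metrics after per-metric normalisation; other
  normalisations are defensible and pluggable behind the same interface.
* Ward linkage assumes Euclidean geometry it is not given; trees are
  reproducible and useful in practice, but branch heights have no
  variance interpretation.
* Group-wise self-similarity is not exactly 1 (see the distance-diagonal
  note above); rankings of *different* species pairs are unaffected.
* A quantile threshold on a 150-term synthetic graph is coarser than on a
  20k-term ontology; retained fractions differ accordingly (about 30%
  versus about 13%).
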