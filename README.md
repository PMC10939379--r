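# semphylo

Functional phylogenetics from ontology annotations: **semphylo** builds
species trees not from sequences but from what genomes are annotated to
*do*. Given per-species gene lists (for example the genes of the
proteostasis network, or of any other conserved mechanism) and their
Gene Ontology Biological Process annotations, the package derives a
semantic profile for every species, compares profiles on a bias-corrected
ontology graph, and turns the resulting distances into clustergrams,
embeddings and functional-component decompositions.

It is aimed at molecular evolution researchers who want to ask: *does the
functional repertoire of a mechanism separate taxonomic groups, and which
parts of it are conserved versus lineage-specific?*

## The method

**1. Standardized ontology graph.** Annotation effort is uneven across
the ontology: heavily studied branches are deep and dense, which biases
any cross-species comparison. For every term *t* the package computes the
structural information content and the semantic value

    IC(t) = -log2( (D(t) + 1) / N )
    SV(t) = sum over ancestors a of t of  1 / (1 + exp(-1 / IC(a)))

where `D(t)` counts the distinct descendants of *t* and `N` is the size
of the term universe. Terms exceeding the 20th percentile of **both**
distributions — very specific terms inside expanded branches — are
trimmed, and every trimmed term is remapped to its most proximal retained
ancestors.

**2. Semantic profiles.** Each species' gene list is tested per term with
the upper-tail hypergeometric probability `P(X >= k)`; raw p < 0.05 terms
are prioritized by a permutation-adjusted p-value (rank of the observed
overlap among `R` same-size random draws from the annotated universe).
Terms passing both 0.05 cuts form the profile, extended down the ranking
to 100 terms when fewer pass. Profiles are then projected onto the
standardized graph and targets with IC < 0.1 are dropped.

**3. Species similarity.** Term pairs are scored by the consensus
(arithmetic mean) of Resnik, XGraSM and AggregateIC similarities on the
standardized graph; enriched-term pairs by the mean similarity over their
mapped target sets; and two species by the best-match average

    SSim(s1, s2) = [ sum_t max_u sim(t, u) + sum_u max_t sim(u, t) ] / (|N| + |M|)

Distance is `1 - SSim`. Ward's minimum-variance clustering yields the
phylogenetic clustergram; metric MDS gives 2-D embeddings; homogeneity
and silhouette scores quantify agreement with reference taxa.

**4. Components and mechanisms.** Per kingdom, quasi-omnipresent terms
(present in > 90% of species, redundancy-reduced) plus "generic"
ancestors at root-distance 2 covering > 50% of species define the
mechanism's components. A terms-by-species association matrix of
`-log10` adjusted p-values is factorized with non-negative matrix
factorization (k = 3) to expose conserved versus kingdom-specific parts,
and any ontology-defined mechanism can be evaluated as an evolutionary
marker with bias-controlled gene-set sizing.

## Worked example

The synthetic generator plants a shared core module and three
kingdom-specific modules in distinct ontology branches:

```r
library(semphylo)

cfg <- synth_config(n_species = 5, seed = 42)   # 3 kingdoms x 5 species
g   <- generate_dag(cfg)
sim <- generate_kingdom_corpus(cfg, g)
fit <- semantic_phylogeny(sim$gene_sets, sim$corpus, g,
                          truth = sim$truth, permutations = 500, seed = 42)
fit
#> semantic phylogeny: 15 species, 39/150 terms retained in the standardized graph
#> mean profile size: 13.4 enriched terms
summary(fit)
#> species: 15 | standardized graph: 39 of 150 terms
#> profile sizes: median 14 (range 11-16)
#> k = 3 clusters: homogeneity 1.000, silhouette 0.837
```

The pruned graph keeps 39 of 150 terms (the rest are remapped to retained
ancestors), profiles hold 11–16 enriched terms, and cutting the Ward tree
at k = 3 recovers the three planted kingdoms perfectly (homogeneity 1.0)
with well-separated clusters (silhouette 0.84). Individual profiles show
the enrichment evidence:

```r
head(fit$profiles[[1]]$terms, 3)
#>    term  k  K  n   U      p_hyper       p_adj
#> 1 T0013 31 86 80 600 2.989645e-09 0.001996008
#> 2 T0107  5 10 80 600 5.471064e-03 0.001996008
#> 3 T0063 10 31 80 600 4.260413e-03 0.003992016
to_newick(fit$tree)   # export the clustergram
plot(fit, type = "mds", seed = 1)
```

Real data enter through `load_obo()` (OBO 1.2/1.4), `load_annotations()`
(GAF 2.x or two-column TSV), `read_gene_list()` (one identifier per
line) and `read_matrix_tsv()` for externally computed distance matrices
(e.g. rRNA alignments). A thin command-line wrapper with subcommands
(`simulate`, `standardize`, `enrich`, `compare`, `tree`, `embed`,
`components`, `evaluate`) is installed under
`system.file("scripts", "semphylo.R", package = "semphylo")`.

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "semphylo",
                               load_package = "installed")'
```

The suite checks every module against independent oracles (brute-force
transitive closure for IC/SV, exhaustive draw enumeration for the
hypergeometric tail, best-match oracles for the group similarity) plus
end-to-end planted-structure recovery.

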