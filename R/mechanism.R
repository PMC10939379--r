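# Evaluation of arbitrary ontology-defined mechanisms as evolutionary
# markers: bias-controlled gene-set sizing, consensus profiles, and
# component-exclusion analysis.

#' Target enrichment magnitude from a reference analysis
#'
#' The average of the 10 lowest log10-transformed hypergeometric p-values
#' of a species' reference (proteostasis) enrichment; the extremity level
#' a mechanism's subsampled gene sets are calibrated against.
#'
#' @param records an `enrichment_records` for the reference gene set.
#' @param n_low number of lowest p-values averaged, default 10.
#' @return A (negative) number: the target log10 magnitude.
#' @export
target_magnitude <- function(records, n_low = 10L) {
  p <- sort(records$p_hyper)
  mean(log10(pmax(p[seq_len(min(n_low, length(p)))], .Machine$double.xmin)))
}

#' Bias-controlled optimal gene-subset size
#'
#' Mechanisms annotated with many genes would produce artificially extreme
#' enrichment p-values. The maximum subset size whose lowest hypergeometric
#' p-value stays within the target's order of magnitude is estimated by
#' iterative binary search: each probe draws one random subset of the
#' candidate size, runs the enrichment test, and compares the floor of
#' log10 of its minimum p-value against the floor of the target (a probe
#' is acceptable when it is not more extreme, within `mag_tol` orders of
#' magnitude). Annotations of fewer than `min_size` (10) genes are used
#' whole, without a search.
#'
#' @param annotation a `gene_set` (the mechanism's annotated genes).
#' @param target target log10 magnitude (see [target_magnitude()]).
#' @param corpus an `annotation_corpus`.
#' @param g optional `ontology`.
#' @param seed optional seed (one probe per size; the outer 30-repetition
#'   loop of [sizing_distribution()] absorbs probe noise).
#' @param min_size smallest searched size, default 10.
#' @param mag_tol tolerance in orders of magnitude, default 0.
#' @return An integer size in `[min_size, |annotation|]` (or
#'   `|annotation|` when smaller than `min_size`).
#' @export
optimal_subset_size <- function(annotation, target, corpus, g = NULL,
                                seed = NULL, min_size = 10L, mag_tol = 0L) {
  genes <- annotation$genes
  if (!length(genes)) stop_("empty annotation")
  if (length(genes) < min_size) return(length(genes))
  tmag <- floor(target)
  acceptable <- function(size) {
    sub <- gene_set(annotation$species, sample(genes, size),
                    label = "size probe")
    rec <- suppressMessages(hypergeometric_test(sub, corpus, g))
    pmin_ <- max(min(rec$p_hyper), .Machine$double.xmin)
    floor(log10(pmin_)) >= tmag - mag_tol
  }
  with_seed(seed, {
    lo <- min_size; hi <- length(genes)
    if (!acceptable(lo)) return(lo)
    while (lo < hi) {
      mid <- lo + ((hi - lo + 1L) %/% 2L)
      if (acceptable(mid)) lo <- mid else hi <- mid - 1L
    }
    lo
  })
}

#' Distribution of optimal subset sizes
#'
#' Repeats [optimal_subset_size()] `reps` times (default 30) to absorb the
#' randomness of single probes.
#'
#' @inheritParams optimal_subset_size
#' @param reps repetitions, default 30.
#' @return A `sizing_distribution`: list with `sizes` (integer vector),
#'   `target`, `species`, `mechanism`.
#' @export
sizing_distribution <- function(annotation, target, corpus, g = NULL,
                                reps = 30L, seed = NULL, min_size = 10L,
                                mag_tol = 0L) {
  seeds <- derive_seeds(seed, reps)
  sizes <- vapply(seq_len(reps), function(r)
    as.integer(optimal_subset_size(annotation, target, corpus, g,
                                   seed = seeds[[r]], min_size = min_size,
                                   mag_tol = mag_tol)), integer(1))
  structure(list(sizes = sizes, target = target,
                 species = annotation$species,
                 mechanism = annotation$label),
            class = "sizing_distribution")
}

#' Consensus mechanism profile from repeated subsampling
#'
#' Draws `draws` gene sets with sizes sampled from the sizing
#' distribution (forced to `min_size` when the distribution mean is below
#' it), runs the full prioritized enrichment per draw, and keeps the terms
#' enriched in strictly more than `consensus_frac` (20%) of the outputs.
#' For downstream comparison each consensus term carries the minimum
#' adjusted p-value observed across the draws that selected it.
#'
#' @param annotation a `gene_set`.
#' @param sizing a `sizing_distribution` (or integer vector of sizes);
#'   `NULL` uses the whole annotation for every draw (small-annotation
#'   rule).
#' @param corpus an `annotation_corpus`.
#' @param g optional `ontology`.
#' @param draws number of generated gene sets, default 30.
#' @param consensus_frac inclusion-frequency cut, default 0.20 (strict).
#' @param permutations,p_cut,adj_cut,floor enrichment parameters per draw.
#' @param seed optional seed.
#' @param min_size floor on sampled sizes, default 10.
#' @return A `semantic_profile` whose `terms` carry `freq` (inclusion
#'   frequency) alongside the enrichment columns.
#' @export
build_mechanism_profile <- function(annotation, sizing, corpus, g = NULL,
                                    draws = 30L, consensus_frac = 0.20,
                                    permutations = 1000L, p_cut = 0.05,
                                    adj_cut = 0.05, floor = 100L,
                                    seed = NULL, min_size = 10L) {
  sizes <- if (is.null(sizing)) rep(length(annotation$genes), draws)
  else if (inherits(sizing, "sizing_distribution")) sizing$sizes
  else as.integer(sizing)
  use_all <- length(annotation$genes) < min_size
  if (!use_all && mean(sizes) < min_size) sizes <- rep(min_size, length(sizes))
  seeds <- derive_seeds(seed, 2L * draws)
  profs <- vector("list", draws)
  for (r in seq_len(draws)) {
    size <- if (use_all) length(annotation$genes) else
      min(with_seed(seeds[[r]], sample(sizes, 1L)), length(annotation$genes))
    sub <- gene_set(annotation$species,
                    with_seed(seeds[[r]], sample(annotation$genes, size)),
                    label = annotation$label)
    rec <- suppressMessages(hypergeometric_test(sub, corpus, g))
    cand <- rec[rec$p_hyper < p_cut, , drop = FALSE]
    if (!nrow(cand)) next
    cand <- permutation_prioritize(cand, corpus, R = permutations,
                                   seed = seeds[[draws + r]],
                                   species = annotation$species)
    profs[[r]] <- tryCatch(build_profile(cand, p_cut, adj_cut, floor,
                                         species = annotation$species),
                           error = function(e) NULL)
  }
  profs <- profs[!vapply(profs, is.null, logical(1))]
  if (!length(profs)) stop_("no draw produced a non-empty profile")
  all_terms <- unlist(lapply(profs, function(p) p$terms$term),
                      use.names = FALSE)
  freq <- table(all_terms) / draws
  keep <- names(freq)[freq > consensus_frac]
  if (!length(keep)) stop_("no term exceeds the consensus frequency")
  rows <- do.call(rbind, lapply(profs, `[[`, "terms"))
  rows <- rows[rows$term %in% keep, , drop = FALSE]
  agg <- do.call(rbind, lapply(split(rows, rows$term), function(b)
    b[which.min(b$p_adj), , drop = FALSE]))
  agg$freq <- as.numeric(freq[agg$term])
  agg <- agg[order(agg$p_adj, agg$p_hyper, agg$term), , drop = FALSE]
  rownames(agg) <- NULL
  structure(list(species = annotation$species, terms = agg,
                 mapping = NULL, updated = FALSE,
                 mechanism = annotation$label, draws = length(profs)),
            class = "semantic_profile")
}

#' Component-exclusion analysis
#'
#' Measures how much of a mechanism's phylogenetic signal resides in a
#' given component term set (e.g. the proteostasis components): clustering
#' quality (homogeneity, silhouette at `k` clusters) is computed before
#' and after removing the component terms from every species' mapped
#' profile. Mapped targets falling in the component set are dropped;
#' enriched terms whose whole mapping disappears are removed; species with
#' emptied profiles are dropped (logged).
#'
#' @param profiles named list of updated `semantic_profile`s.
#' @param component_terms character vector (or `component_terms` frame) of
#'   term ids to exclude.
#' @param truth named reference classes per species.
#' @param S a `similarity_matrix` over the standardized graph.
#' @param k number of clusters, default 3.
#' @return List with `before`, `after` (each `c(HS, SS)`),
#'   `dropped_species`, and the two distance matrices.
#' @export
component_exclusion_eval <- function(profiles, component_terms, truth, S,
                                     k = 3L) {
  if (inherits(component_terms, "component_terms"))
    component_terms <- unique(component_terms$term)
  eval_at <- function(profs) {
    D <- build_distance_matrix(profs, S)
    cl <- cut_clusters(ward_tree(D), k)
    list(D = D, scores = evaluate_clustering(cl, truth[names(cl)], D))
  }
  before <- eval_at(profiles)
  pruned <- lapply(profiles, function(p) {
    maps <- lapply(p$mapping, setdiff, y = component_terms)
    keep <- lengths(maps) > 0L
    if (!any(keep)) return(NULL)
    p$terms <- p$terms[keep, , drop = FALSE]
    p$mapping <- maps[keep]
    p
  })
  dropped <- names(profiles)[vapply(pruned, is.null, logical(1))]
  if (length(dropped))
    message("species emptied by component exclusion: ",
            paste(dropped, collapse = ", "))
  pruned <- pruned[!vapply(pruned, is.null, logical(1))]
  if (length(pruned) < 2L)
    stop_("fewer than two species survive component exclusion")
  after <- eval_at(pruned)
  list(before = before$scores, after = after$scores,
       dropped_species = dropped,
       distance_before = before$D, distance_after = after$D)
}
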