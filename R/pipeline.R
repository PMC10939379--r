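#' Run the full semantic-network phylogenetics pipeline
#'
#' Orchestrates every stage: annotation propagation, IC/SV metrics on the
#' (annotated-universe) ontology, standardized-graph construction,
#' per-species prioritized enrichment, projection of profiles onto the
#' standardized graph, the global term-similarity matrix, best-match-
#' average species similarities, the semantic distance matrix and the Ward
#' clustergram.
#'
#' @param gene_sets named list of `gene_set`s (one per species).
#' @param corpus an `annotation_corpus` covering those species.
#' @param g the `ontology`.
#' @param truth optional named reference classes (kingdoms) used by
#'   [summary.semphylo()].
#' @param percentile trimming percentile for the standardized graph (20).
#' @param p_cut,adj_cut,floor profile-selection parameters (0.05/0.05/100).
#' @param ic_min IC floor for mapped targets (0.1).
#' @param permutations permutation count for adjusted p-values (1000).
#' @param metric pairwise term-similarity metric ("consensus").
#' @param universe `"annotated"` (default) restricts the IC/SV universe to
#'   terms with at least one propagated annotation; `"graph"` uses all
#'   terms.
#' @param propagate_annotations close annotations under ancestors first
#'   (default TRUE).
#' @param seed master seed for the permutation draws.
#' @return A `semphylo` object: list with `ontology`, `metrics`, `sg`
#'   (standardized graph), `profiles` (updated), `S` (term similarity),
#'   `distance`, `tree` (`hclust`), `truth`, `params`.
#' @examples
#' cfg <- synth_config(n_species = 3, seed = 7)
#' g <- generate_dag(cfg)
#' sim <- generate_kingdom_corpus(cfg, g)
#' fit <- semantic_phylogeny(sim$gene_sets, sim$corpus, g,
#'                           truth = sim$truth, permutations = 50,
#'                           seed = 7)
#' summary(fit)
#' @export
semantic_phylogeny <- function(gene_sets, corpus, g, truth = NULL,
                               percentile = 20, p_cut = 0.05,
                               adj_cut = 0.05, floor = 100L, ic_min = 0.1,
                               permutations = 1000L, metric = "consensus",
                               universe = c("annotated", "graph"),
                               propagate_annotations = TRUE, seed = NULL) {
  universe <- match.arg(universe)
  stopifnot(inherits(g, "ontology"), inherits(corpus, "annotation_corpus"))
  if (propagate_annotations) corpus <- propagate(corpus, g)
  uni <- if (universe == "annotated") {
    sort(unique(unlist(lapply(corpus$species, function(sp)
      unlist(sp$gene2terms, use.names = FALSE)), use.names = FALSE)))
  } else NULL
  m <- compute_metrics(g, universe = uni)
  sg <- build_standardized_graph(g, m, pct = percentile)

  seeds <- derive_seeds(seed, length(gene_sets))
  profiles <- vector("list", length(gene_sets))
  names(profiles) <- names(gene_sets)
  for (i in seq_along(gene_sets)) {
    q <- gene_sets[[i]]
    rec <- suppressMessages(hypergeometric_test(q, corpus, g))
    cand <- rec[rec$p_hyper < p_cut, , drop = FALSE]
    if (!nrow(cand))
      stop_("no enriched terms for species ", q$species)
    cand <- permutation_prioritize(cand, corpus, R = permutations,
                                   seed = seeds[[i]], species = q$species)
    prof <- build_profile(cand, p_cut, adj_cut, floor, species = q$species)
    profiles[[i]] <- update_profile(prof, sg, m, ic_min = ic_min)
  }

  S <- term_similarity_matrix(sg, metric = metric)
  D <- build_distance_matrix(profiles, S)
  tree <- ward_tree(D)

  structure(list(ontology = g, metrics = m, sg = sg, profiles = profiles,
                 S = S, distance = D, tree = tree, truth = truth,
                 params = list(percentile = percentile, p_cut = p_cut,
                               adj_cut = adj_cut, floor = floor,
                               ic_min = ic_min,
                               permutations = permutations,
                               metric = metric, universe = universe,
                               seed = seed)),
            class = "semphylo")
}

#' @export
print.semphylo <- function(x, ...) {
  cat(sprintf(paste0("semantic phylogeny: %d species, %d/%d terms retained",
                     " in the standardized graph\n"),
              length(x$profiles), length(x$sg$retained), x$ontology$n_terms))
  cat(sprintf("mean profile size: %.1f enriched terms\n",
              mean(vapply(x$profiles, function(p) nrow(p$terms), numeric(1)))))
  invisible(x)
}

#' @export
summary.semphylo <- function(object, k = 3L, ...) {
  cl <- cut_clusters(object$tree, k)
  scores <- if (!is.null(object$truth))
    evaluate_clustering(cl, object$truth[names(cl)], object$distance)
  else c(HS = NA_real_,
         SS = evaluate_clustering(cl, cl, object$distance)[["SS"]])
  out <- list(n_species = length(object$profiles),
              n_retained = length(object$sg$retained),
              n_terms = object$ontology$n_terms,
              profile_sizes = vapply(object$profiles, function(p)
                nrow(p$terms), numeric(1)),
              k = k, clusters = cl, scores = scores)
  class(out) <- "summary.semphylo"
  out
}

#' @export
print.summary.semphylo <- function(x, ...) {
  cat(sprintf("species: %d | standardized graph: %d of %d terms\n",
              x$n_species, x$n_retained, x$n_terms))
  cat(sprintf("profile sizes: median %.0f (range %d-%d)\n",
              stats::median(x$profile_sizes), min(x$profile_sizes),
              max(x$profile_sizes)))
  cat(sprintf("k = %d clusters: homogeneity %.3f, silhouette %.3f\n",
              x$k, x$scores[["HS"]], x$scores[["SS"]]))
  invisible(x)
}

#' @export
plot.semphylo <- function(x, type = c("tree", "mds"), k = 3L, seed = NULL,
                          ...) {
  type <- match.arg(type)
  if (type == "tree") {
    plot(x$tree, hang = -1, xlab = "", sub = "",
         main = "semantic clustergram", ...)
  } else {
    emb <- mds_embed(x$distance, seed = seed)
    grp <- if (!is.null(x$truth))
      as.integer(factor(x$truth[rownames(emb$points)]))
    else cut_clusters(x$tree, k)
    plot(emb$points, col = grp, pch = 19,
         main = sprintf("MDS embedding (stress %.3g)", emb$stress), ...)
  }
  invisible(x)
}
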