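#' Hypergeometric term enrichment for one species
#'
#' For every term with at least one annotated gene in the species'
#' (typically propagated) annotation, computes the upper-tail
#' hypergeometric probability of the observed query overlap:
#' `p = P(X >= k)` drawing `n` query genes from a universe of `U`
#' annotated genes of which `K` carry the term. Query genes outside the
#' universe are dropped with a message.
#'
#' @param query a `gene_set`.
#' @param corpus an `annotation_corpus` containing the query's species.
#' @param g optional `ontology`; terms absent from it are ignored.
#' @param species species id; defaults to `query$species`.
#' @return An `enrichment_records` data frame with columns
#'   `term, k, K, n, U, p_hyper`, sorted by `p_hyper`.
#' @export
hypergeometric_test <- function(query, corpus, g = NULL,
                                species = query$species) {
  stopifnot(inherits(query, "gene_set"), inherits(corpus, "annotation_corpus"))
  sp <- corpus$species[[species]]
  if (is.null(sp)) stop_("species not in corpus: ", species)
  eff <- intersect(query$genes, sp$universe)
  if (length(eff) < length(query$genes))
    message(length(query$genes) - length(eff),
            " query gene(s) outside the annotated universe dropped")
  if (!length(eff)) stop_("empty effective query for species ", species)

  t2g <- term_gene_index(sp, g)
  U <- length(sp$universe)
  n <- length(eff)
  K <- lengths(t2g)
  k <- vapply(t2g, function(gs) sum(gs %in% eff), integer(1))
  p <- stats::phyper(k - 1L, K, U - K, n, lower.tail = FALSE)
  out <- data.frame(term = names(t2g), k = unname(k), K = unname(K),
                    n = n, U = U, p_hyper = unname(p),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_hyper, out$term), ]
  rownames(out) <- NULL
  structure(out, species = species,
            class = c("enrichment_records", "data.frame"))
}

# term -> character vector of genes carrying it, for one species entry
term_gene_index <- function(sp, g = NULL) {
  gene <- rep(names(sp$gene2terms), lengths(sp$gene2terms))
  term <- unlist(sp$gene2terms, use.names = FALSE)
  if (!is.null(g)) {
    ok <- term %in% g$terms
    gene <- gene[ok]; term <- term[ok]
  }
  split(gene, term)
}

#' Permutation-based adjusted p-values (prioritization)
#'
#' Re-draws `R` random gene sets of the query's size from the species'
#' annotated universe and, for each record's term, ranks the observed
#' hypergeometric p-value within the permutation distribution:
#' `p_adj = (1 + #{r : p_perm(r) <= p_obs}) / (1 + R)`. Because p is a
#' strictly decreasing function of the overlap at fixed (K, n, U), the
#' comparison is carried out on overlap counts, which is exact.
#'
#' @param records an `enrichment_records` (possibly subset).
#' @param corpus the `annotation_corpus` used for the observed test.
#' @param query_size number of (effective) query genes; defaults to the
#'   `n` recorded in `records`.
#' @param R number of permutations (>= 1), default 1000.
#' @param seed optional integer for reproducible draws.
#' @param species species id; defaults to the records' attribute.
#' @return `records` with a `p_adj` column appended.
#' @export
permutation_prioritize <- function(records, corpus,
                                   query_size = records$n[1L],
                                   R = 1000L, seed = NULL,
                                   species = attr(records, "species")) {
  stopifnot(R >= 1L, nrow(records) > 0L)
  sp <- corpus$species[[species]]
  if (is.null(sp)) stop_("species not in corpus: ", species)
  uni <- sp$universe
  nrec <- nrow(records)
  # gene -> indices of record terms it carries
  rec_of_term <- seq_len(nrec)
  names(rec_of_term) <- records$term
  gene2rec <- lapply(sp$gene2terms, function(ts) {
    r <- rec_of_term[ts]
    unname(r[!is.na(r)])
  })
  k_obs <- records$k
  counts <- integer(nrec)
  with_seed(seed, {
    for (r in seq_len(R)) {
      draw <- sample.int(length(uni), query_size)
      kk <- tabulate(unlist(gene2rec[draw], use.names = FALSE), nbins = nrec)
      counts <- counts + (kk >= k_obs)
    }
  })
  records$p_adj <- (1 + counts) / (1 + R)
  records
}

#' Select a species' semantic profile from enrichment records
#'
#' Keeps terms passing both the raw hypergeometric cut (`p_hyper < p_cut`)
#' and the adjusted cut (`p_adj < adj_cut`). If fewer than `floor` terms
#' survive, the selection is extended down the prioritized ranking
#' (ordered by `p_adj`, then `p_hyper`, then term id) among terms passing
#' the raw cut, up to `min(floor, #raw-passing terms)`.
#'
#' @param records an `enrichment_records` with `p_adj`.
#' @param p_cut raw hypergeometric cut, default 0.05 (strict).
#' @param adj_cut adjusted-p cut, default 0.05 (strict).
#' @param floor minimum profile cardinality to aim for, default 100.
#' @param species species id.
#' @return A `semantic_profile`: list with `species`, `terms` (the selected
#'   records), `mapping` (filled by [update_profile()]), `updated` flag.
#' @export
build_profile <- function(records, p_cut = 0.05, adj_cut = 0.05,
                          floor = 100L, species = attr(records, "species")) {
  if (is.null(records$p_adj)) stop_("records lack p_adj; run permutation_prioritize first")
  cand <- records[records$p_hyper < p_cut, , drop = FALSE]
  if (!nrow(cand)) stop_("no terms pass the raw hypergeometric cut for ",
                         species %||% "query")
  cand <- cand[order(cand$p_adj, cand$p_hyper, cand$term), , drop = FALSE]
  sel <- cand$p_adj < adj_cut
  n_keep <- if (sum(sel) >= floor) sum(sel) else min(floor, nrow(cand))
  # ranking is (p_adj, p_hyper, term): the first n_keep rows contain every
  # term passing both cuts plus the extension
  keep <- cand[seq_len(n_keep), , drop = FALSE]
  rownames(keep) <- NULL
  structure(list(species = species, terms = keep,
                 mapping = NULL, updated = FALSE),
            class = "semantic_profile")
}

#' @export
print.semantic_profile <- function(x, ...) {
  cat(sprintf("semantic profile [%s]: %d enriched terms%s\n",
              x$species %||% "?", nrow(x$terms),
              if (isTRUE(x$updated)) " (standardized, IC-filtered)" else ""))
  invisible(x)
}

#' Project a profile onto the standardized graph and filter by IC
#'
#' Each enriched term is annotated with its standardized mapping
#' ([map_to_standard()]); mapped targets with `IC < ic_min` are dropped
#' (such targets are very generic processes that would mask differences
#' between species), and terms whose whole mapping falls below the cut are
#' removed.
#'
#' @param profile a `semantic_profile`.
#' @param sg a `standardized_ontology`.
#' @param m a `term_metrics` supplying the IC values for the filter
#'   (defaults to the metrics stored in `sg`).
#' @param ic_min IC floor, default 0.1.
#' @return The updated `semantic_profile` (`mapping` filled, `updated`
#'   set); errors if every term is removed.
#' @export
update_profile <- function(profile, sg, m = sg$metrics, ic_min = 0.1) {
  stopifnot(inherits(profile, "semantic_profile"),
            inherits(sg, "standardized_ontology"))
  ic <- metric_lookup(m, "ic")
  maps <- lapply(profile$terms$term, function(t) {
    tg <- map_to_standard(sg, t)
    tg[ic[tg] >= ic_min]
  })
  keep <- lengths(maps) > 0L
  if (!any(keep))
    stop_("profile of species ", profile$species,
          " is empty after standardization/IC filtering")
  profile$terms <- profile$terms[keep, , drop = FALSE]
  rownames(profile$terms) <- NULL
  profile$mapping <- maps[keep]
  names(profile$mapping) <- profile$terms$term
  profile$updated <- TRUE
  profile
}

#' Write a profile table as TSV
#'
#' @param profile a `semantic_profile` (updated or not).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  tab <- profile$terms
  tab <- cbind(species = profile$species, tab)
  tab$targets <- if (is.null(profile$mapping)) NA_character_ else
    vapply(profile$mapping, paste, character(1), collapse = ",")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
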