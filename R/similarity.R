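# Consensus pairwise term similarity and group-wise (best-match-average)
# species similarity on the standardized graph.

# Shared precomputation: inclusive ancestor index sets, ic/sv/sw vectors,
# over either a plain ontology or the retained sub-DAG of a standardized
# ontology (metrics recomputed on the pruned graph in that case).
sim_context <- function(x, metrics = NULL) {
  g <- if (inherits(x, "standardized_ontology")) as_ontology(x) else x
  stopifnot(inherits(g, "ontology"))
  m <- metrics %||% compute_metrics(g)
  m <- m[match(g$terms, m$term), ]
  anc <- anc_sets(g)
  ancp <- lapply(seq_len(g$n_terms), function(i) sort(c(anc[[i]], i)))
  list(g = g, ic = m$ic, sw = m$sw, svp = m$sv + m$sw,
       ic_max = max(m$ic), ancp = ancp)
}

term_pair_sim <- function(ctx, i, j, metric) {
  ca <- intersect(ctx$ancp[[i]], ctx$ancp[[j]])  # inclusive common ancestors
  ic_ca <- ctx$ic[ca]
  res <- if (ctx$ic_max > 0) max(ic_ca) / ctx$ic_max else 0
  pos <- ic_ca > 0
  xg <- if (any(pos)) {
    denom <- max(ctx$ic[i], ctx$ic[j])
    if (denom > 0) mean(ic_ca[pos]) / denom else 0
  } else 0
  aic <- 2 * sum(ctx$sw[ca]) / (ctx$svp[i] + ctx$svp[j])
  switch(metric,
         resnik = res, xgrasm = xg, aic = aic,
         consensus = (res + xg + aic) / 3,
         stop_("unknown metric: ", metric))
}

#' Pairwise semantic similarity of two terms
#'
#' Three pairwise measures on the (standardized) ontology graph, all in
#' \[0,1\], plus their consensus (arithmetic mean):
#' * `resnik`: IC of the most informative common ancestor, normalized by
#'   the graph's maximum IC;
#' * `xgrasm`: mean IC of the informative (IC > 0) common ancestors,
#'   divided by `max(IC(a), IC(b))`; 0 when no informative common ancestor
#'   exists;
#' * `aic`: `2 * sum of sv_weight over common ancestors / (SV+(a) + SV+(b))`
#'   where `SV+` adds the term's own weight to its SV.
#'
#' Common-ancestor sets are inclusive (a term is among its own ancestors
#' here), so `aic(t, t) = 1`. When `x` is a `standardized_ontology`, IC/SV
#' are recomputed on the retained sub-DAG.
#'
#' @param x an `ontology` or `standardized_ontology`.
#' @param a,b term identifiers (retained terms if `x` is standardized).
#' @param metric one of `"resnik"`, `"xgrasm"`, `"aic"`, `"consensus"`.
#' @return A similarity in \[0,1\].
#' @export
pairwise_term_similarity <- function(x, a, b, metric = "consensus") {
  ctx <- sim_context(x)
  i <- term_index(ctx$g, a); j <- term_index(ctx$g, b)
  term_pair_sim(ctx, i, j, metric)
}

#' Global term-similarity matrix
#'
#' Computes the pairwise similarity for all (or a subset of) terms of the
#' standardized graph; the matrix feeding every downstream group-wise
#' comparison.
#'
#' @inheritParams pairwise_term_similarity
#' @param terms optional subset of term ids (default: all).
#' @return A symmetric `similarity_matrix` with term dimnames.
#' @export
term_similarity_matrix <- function(x, terms = NULL, metric = "consensus") {
  ctx <- sim_context(x)
  ids <- terms %||% ctx$g$terms
  ix <- term_index(ctx$g, ids)
  n <- length(ix)
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n)) {
    for (b in a:n) {
      s <- term_pair_sim(ctx, ix[a], ix[b], metric)
      S[a, b] <- s; S[b, a] <- s
    }
  }
  structure(S, metric = metric, class = c("similarity_matrix", "matrix"))
}

#' Mean cross-set similarity of two mapped term sets
#'
#' The similarity of two enriched terms is the arithmetic mean of the
#' global matrix over the full cross product of their standardized
#' mappings.
#'
#' @param map_a,map_b non-empty character vectors of retained terms.
#' @param S a `similarity_matrix` covering their union.
#' @return A similarity value.
#' @export
enriched_term_similarity <- function(map_a, map_b, S) {
  if (!length(map_a) || !length(map_b)) stop_("empty mapped term set")
  mean(S[map_a, map_b, drop = FALSE])
}

# n_matrix_terms x n_enriched indicator matrix, columns scaled to mean
# weights, so that t(M1) %*% S %*% M2 is the matrix of cross-set means.
profile_indicator <- function(profile, S) {
  if (!isTRUE(profile$updated))
    stop_("profile of species ", profile$species,
          " not updated onto the standardized graph")
  ids <- rownames(S)
  M <- matrix(0, length(ids), length(profile$mapping),
              dimnames = list(ids, names(profile$mapping)))
  for (j in seq_along(profile$mapping)) {
    tg <- profile$mapping[[j]]
    M[tg, j] <- 1 / length(tg)
  }
  M
}

#' Best-match-average similarity of two species profiles
#'
#' `SSim(s1, s2) = (sum over t in GO1 of max_u sim(t, u) +
#' sum over u in GO2 of max_t sim(u, t)) / (|GO1| + |GO2|)`, where GO1 and
#' GO2 are the species' enriched term sets and `sim` the mean cross-set
#' similarity of their standardized mappings.
#'
#' @param p1,p2 updated `semantic_profile`s.
#' @param S a `similarity_matrix` over the standardized graph.
#' @return A similarity in \[0,1\].
#' @export
species_similarity <- function(p1, p2, S) {
  M1 <- profile_indicator(p1, S)
  M2 <- profile_indicator(p2, S)
  C <- crossprod(M1, S %*% M2)  # sim(t, u) for all enriched pairs
  (sum(apply(C, 1L, max)) + sum(apply(C, 2L, max))) / (ncol(M1) + ncol(M2))
}

#' Semantic distance matrix over species
#'
#' `d(i, j) = 1 - SSim(i, j)` for each unordered species pair, diagonal
#' forced to 0 (pairwise self-similarities of the component metrics can be
#' below 1, but a species is at distance 0 from itself by definition).
#'
#' @param profiles named list of updated `semantic_profile`s (>= 2).
#' @param S a `similarity_matrix` over the standardized graph.
#' @return A `semantic_distance` matrix (symmetric, zero diagonal,
#'   entries in \[0,1\]).
#' @export
build_distance_matrix <- function(profiles, S) {
  if (length(profiles) < 2L) stop_("need at least two species")
  ids <- names(profiles) %||% vapply(profiles, `[[`, character(1), "species")
  n <- length(ids)
  Ms <- lapply(profiles, profile_indicator, S = S)
  SM <- lapply(Ms, function(M) S %*% M)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      C <- crossprod(Ms[[i]], SM[[j]])
      s <- (sum(apply(C, 1L, max)) + sum(apply(C, 2L, max))) /
        (ncol(Ms[[i]]) + ncol(Ms[[j]]))
      if (is.na(s) || s < -1e-9 || s > 1 + 1e-9)
        stop_("species similarity outside [0,1] for pair ",
              ids[i], " / ", ids[j])
      D[i, j] <- D[j, i] <- 1 - min(max(s, 0), 1)
    }
  }
  structure(D, class = c("semantic_distance", "matrix"))
}

#' Write / read a square distance or similarity matrix as TSV
#'
#' The dialect (header row of ids, first column of ids) also reads
#' externally produced matrices, e.g. sequence-derived distances.
#'
#' @param m a square matrix with dimnames.
#' @param path TSV path.
#' @return `path` / the matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  tab <- cbind(id = rownames(m), as.data.frame(m, check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m) || !all(rownames(m) == colnames(m)))
    stop_("not a square labelled matrix: ", path)
  m
}
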