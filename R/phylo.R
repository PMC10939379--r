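#' Ward clustergram from a distance matrix
#'
#' Agglomerative hierarchical clustering with Ward's minimum-variance
#' criterion (`stats::hclust`, method `ward.D2`) on the precomputed
#' semantic (or sequence) distances.
#'
#' @param d symmetric distance matrix with species dimnames (or a `dist`).
#' @param method linkage; `"ward.D2"` (default), `"average"` or
#'   `"complete"` for sensitivity checks.
#' @return An `hclust` tree.
#' @export
ward_tree <- function(d, method = "ward.D2") {
  dd <- stats::as.dist(d)
  if (any(!is.finite(dd))) stop_("non-finite distances")
  stats::hclust(dd, method = method)
}

#' Cut a tree into k clusters
#'
#' @param tree an `hclust`.
#' @param k number of clusters, `1 <= k <=` number of leaves.
#' @return Named integer vector of cluster labels.
#' @export
cut_clusters <- function(tree, k) {
  n <- length(tree$labels %||% tree$order)
  if (k < 1L || k > n) stop_("k must be in [1, ", n, "]")
  stats::cutree(tree, k = k)
}

#' Export a tree as a Newick string
#'
#' @param tree an `hclust`.
#' @return A Newick string (round-trips through standard parsers).
#' @export
to_newick <- function(tree) {
  ape::write.tree(ape::as.phylo(tree))
}

#' Metric MDS embedding of a distance matrix
#'
#' Two-stage metric multidimensional scaling: classical scaling
#' (`stats::cmdscale`) provides the initial configuration, refined by
#' Sammon stress minimization (`MASS::sammon`). Species at distance zero
#' from one another are collapsed before the fit (the stress function is
#' undefined on coincident input points) and re-expanded to coincident
#' coordinates afterwards.
#'
#' @param d symmetric distance matrix with dimnames.
#' @param dims embedding dimension, default 2.
#' @param seed optional seed (used to jitter a degenerate initial
#'   configuration, otherwise the fit is deterministic).
#' @return List with `points` (species x dims matrix) and `stress`
#'   (final Sammon stress; 0 for exactly representable configurations).
#' @export
mds_embed <- function(d, dims = 2L, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  ids <- rownames(d) %||% paste0("s", seq_len(n))
  # collapse coincident species (off-diagonal zero distances)
  group <- integer(n)
  rep_idx <- integer(0)
  for (i in seq_len(n)) {
    hit <- which(vapply(rep_idx, function(r) d[i, r] == 0, logical(1)))
    if (length(hit)) group[i] <- hit[1L]
    else { rep_idx <- c(rep_idx, i); group[i] <- length(rep_idx) }
  }
  du <- d[rep_idx, rep_idx, drop = FALSE]
  m <- length(rep_idx)
  if (m == 1L) {
    pts_u <- matrix(0, 1L, dims); stress <- 0
  } else if (m == 2L) {
    pts_u <- rbind(rep(0, dims), c(du[1, 2], rep(0, dims - 1L))); stress <- 0
  } else {
    init <- stats::cmdscale(du, k = dims)
    if (ncol(init) < dims)
      init <- cbind(init, matrix(0, nrow(init), dims - ncol(init)))
    if (any(duplicated(as.data.frame(init)))) {
      with_seed(seed, init <- init + matrix(stats::rnorm(length(init),
                                                         sd = 1e-6),
                                            nrow(init)))
    }
    fit <- tryCatch(MASS::sammon(stats::as.dist(du), y = init, k = dims,
                                 trace = FALSE),
                    error = function(e) NULL)
    if (is.null(fit)) {
      pts_u <- init
      stress <- sammon_stress(du, init)
    } else {
      pts_u <- fit$points
      stress <- fit$stress
    }
  }
  pts <- pts_u[group, , drop = FALSE]
  rownames(pts) <- ids
  colnames(pts) <- paste0("dim", seq_len(dims))
  list(points = pts, stress = stress)
}

sammon_stress <- function(d, y) {
  dd <- d[upper.tri(d)]
  e <- as.matrix(stats::dist(y))[upper.tri(d)]
  pos <- dd > 0
  sum((dd[pos] - e[pos])^2 / dd[pos]) / sum(dd[pos])
}

#' Homogeneity and silhouette of a clustering
#'
#' Homogeneity (HS) follows the conditional-entropy definition
#' `1 - H(truth | cluster) / H(truth)`; it is 1 when every cluster
#' contains members of a single reference class and, by convention, 1
#' when the reference has a single class (logged). Silhouette (SS) is the
#' mean silhouette width computed on the precomputed distance matrix, not
#' on embedded coordinates.
#'
#' @param labels named cluster assignment (integer/character).
#' @param truth named reference classes over the same species.
#' @param d distance matrix (needed for SS; `NULL` returns `SS = NA`).
#' @return Named numeric vector `c(HS = ..., SS = ...)`.
#' @export
evaluate_clustering <- function(labels, truth, d = NULL) {
  ids <- names(labels) %||% names(truth)
  if (!is.null(names(labels)) && !is.null(names(truth))) {
    if (!setequal(names(labels), names(truth)))
      stop_("labels and truth cover different species")
    truth <- truth[names(labels)]
  }
  hs <- homogeneity_score(labels, truth)
  ss <- NA_real_
  if (!is.null(d)) {
    d <- as.matrix(d)
    if (!is.null(names(labels))) d <- d[names(labels), names(labels)]
    cl <- as.integer(factor(labels))
    if (length(unique(cl)) > 1L) {
      sil <- cluster::silhouette(cl, dmatrix = d)
      ss <- mean(sil[, "sil_width"])
    } else {
      message("single cluster: silhouette undefined, returning NA")
    }
  }
  c(HS = hs, SS = ss)
}

homogeneity_score <- function(labels, truth) {
  ct <- table(cluster = labels, class = truth)
  n <- sum(ct)
  p_class <- colSums(ct) / n
  h_class <- -sum(p_class[p_class > 0] * log(p_class[p_class > 0]))
  if (h_class == 0) {
    message("single reference class: homogeneity defined as 1")
    return(1)
  }
  h_cond <- 0
  for (i in seq_len(nrow(ct))) {
    row <- ct[i, ]; ni <- sum(row)
    if (ni == 0) next
    p <- row[row > 0] / ni
    h_cond <- h_cond - (ni / n) * sum(p * log(p))
  }
  1 - h_cond / h_class
}

#' Pearson correlation of two distance matrices
#'
#' Correlates the upper-triangle pairwise distances of the species shared
#' by both matrices. To keep the estimate unbiased by group sizes, at most
#' `max_per_group` species per group (e.g. taxonomic domain) are randomly
#' subsampled when `groups` is given.
#'
#' @param d1,d2 square distance matrices with species dimnames.
#' @param groups optional named vector of group labels over species.
#' @param max_per_group cap per group, default 80.
#' @param seed optional seed for the subsample.
#' @return Pearson correlation coefficient.
#' @export
correlate_distances <- function(d1, d2, groups = NULL, max_per_group = 80L,
                                seed = NULL) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  shared <- intersect(rownames(d1), rownames(d2))
  if (length(shared) < 3L) stop_("fewer than 3 shared species")
  if (!is.null(groups)) {
    shared <- with_seed(seed, {
      unlist(lapply(split(shared, groups[shared]), function(s)
        if (length(s) > max_per_group) sample(s, max_per_group) else s),
        use.names = FALSE)
    })
  }
  a <- d1[shared, shared]; b <- d2[shared, shared]
  stats::cor(a[upper.tri(a)], b[upper.tri(b)], method = "pearson")
}
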