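# Conserved / differential functional components: quasi-omnipresent term
# selection, generic-ancestor aggregation, association matrix and NMF.

# standardized term set of one species = union of its mapped targets
profile_std_terms <- function(profile) {
  if (!isTRUE(profile$updated))
    stop_("profile of species ", profile$species, " not updated")
  sort(unique(unlist(profile$mapping, use.names = FALSE)))
}

#' Quasi-omnipresent ("core") terms of a kingdom
#'
#' Terms present -- via the standardized mapping -- in strictly more than
#' `frac` of the kingdom's species, reduced for semantic redundancy by
#' removing any selected term that has a selected strict descendant (only
#' the most specific quasi-omnipresent terms remain).
#'
#' @param profiles list of updated `semantic_profile`s (one kingdom).
#' @param sg the `standardized_ontology` the profiles are mapped onto.
#' @param frac presence fraction, default 0.90 (strict `>`).
#' @return Character vector of term ids (possibly empty, with a warning).
#' @export
select_core_terms <- function(profiles, sg, frac = 0.90) {
  g <- sg$ontology
  sets <- lapply(profiles, profile_std_terms)
  cnt <- table(unlist(sets, use.names = FALSE))
  qual <- names(cnt)[cnt / length(profiles) > frac]
  if (!length(qual)) {
    warn_("no quasi-omnipresent terms at frac = ", frac)
    return(character())
  }
  anc <- anc_sets(g)
  qi <- term_index(g, qual)
  has_desc <- vapply(seq_along(qual), function(a) {
    any(vapply(seq_along(qual)[-a], function(b) qi[a] %in% anc[[qi[b]]],
               logical(1)))
  }, logical(1))
  sort(qual[!has_desc])
}

#' Generic-ancestor terms covering sub-threshold enrichment
#'
#' "Generic" terms sit at shortest-path distance exactly 2 from the root
#' of the original graph. A generic term qualifies when it is linked by
#' descendancy (ancestor-or-self) to sub-threshold enriched terms in
#' strictly more than `frac` of the kingdom's species; it aggregates
#' enrichment that accumulates in its branch without the term itself being
#' enriched.
#'
#' @param profiles list of updated `semantic_profile`s (one kingdom).
#' @param g the original `ontology`.
#' @param frac coverage fraction, default 0.50 (strict `>`).
#' @param core_frac presence fraction above which terms are handled by
#'   [select_core_terms()] and skipped here, default 0.90.
#' @return Character vector of generic term ids.
#' @export
select_generic_terms <- function(profiles, g, frac = 0.50, core_frac = 0.90) {
  dist <- root_distances(g)
  generic <- g$terms[!is.na(dist) & dist == 2L]
  if (!length(generic)) return(character())
  sets <- lapply(profiles, profile_std_terms)
  cnt <- table(unlist(sets, use.names = FALSE))
  over <- names(cnt)[cnt / length(profiles) > core_frac]
  sub_sets <- lapply(sets, function(s) setdiff(s, over))
  anc <- anc_sets(g)
  gi <- term_index(g, generic)
  covered <- vapply(seq_along(generic), function(a) {
    sum(vapply(sub_sets, function(s) {
      if (!length(s)) return(FALSE)
      si <- term_index(g, s)
      any(si == gi[a]) || any(vapply(si, function(x) gi[a] %in% anc[[x]],
                                     logical(1)))
    }, logical(1)))
  }, numeric(1))
  sort(generic[covered / length(profiles) > frac])
}

#' Assemble the component term set of a kingdom
#'
#' Union of the quasi-omnipresent terms (route `core`) and qualifying
#' generic ancestors (route `generic`).
#'
#' @inheritParams select_core_terms
#' @param g the original `ontology` (for the generic step).
#' @param kingdom label attached to the result.
#' @param core_frac,generic_frac the two thresholds (0.90 / 0.50).
#' @return A `component_terms` data frame: `term`, `route`, `kingdom`.
#' @export
select_component_terms <- function(profiles, sg, g = sg$ontology,
                                   kingdom = NA_character_,
                                   core_frac = 0.90, generic_frac = 0.50) {
  core <- select_core_terms(profiles, sg, frac = core_frac)
  gen <- setdiff(select_generic_terms(profiles, g, frac = generic_frac,
                                      core_frac = core_frac), core)
  structure(
    data.frame(term = c(core, gen),
               route = rep(c("core", "generic"),
                           c(length(core), length(gen))),
               kingdom = kingdom, stringsAsFactors = FALSE),
    class = c("component_terms", "data.frame"))
}

#' Association matrix of component terms with species
#'
#' `A[term, species]` is the negative log10 adjusted p-value of the term
#' in the species' enrichment results when the term itself is enriched;
#' otherwise that of the minimum adjusted p-value among its enriched
#' strict descendants; otherwise 0. Zero adjusted p-values are clamped to
#' the smallest representable double (logged).
#'
#' @param terms character vector of term ids (or a `component_terms`).
#' @param profiles named list of `semantic_profile`s carrying `p_adj`.
#' @param g the original `ontology` (descendant lookups).
#' @return A non-negative `association_matrix` (terms x species).
#' @export
build_association_matrix <- function(terms, profiles, g) {
  if (inherits(terms, "component_terms")) terms <- unique(terms$term)
  ids <- names(profiles) %||% vapply(profiles, `[[`, character(1), "species")
  anc <- anc_sets(g)
  ti <- term_index(g, terms)
  A <- matrix(0, length(terms), length(ids), dimnames = list(terms, ids))
  clamped <- FALSE
  for (s in seq_along(profiles)) {
    tab <- profiles[[s]]$terms
    p <- tab$p_adj
    if (any(p == 0)) { p[p == 0] <- .Machine$double.xmin; clamped <- TRUE }
    ei <- term_index(g, tab$term)
    # a term's own enrichment takes precedence; otherwise the minimum
    # adjusted p among its enriched strict descendants
    own <- rep(NA_real_, g$n_terms)
    desc_best <- rep(NA_real_, g$n_terms)
    for (e in seq_along(ei)) {
      own[ei[e]] <- min(own[ei[e]], p[e], na.rm = TRUE)
      up <- anc[[ei[e]]]
      better <- is.na(desc_best[up]) | desc_best[up] > p[e]
      desc_best[up[better]] <- p[e]
    }
    val <- ifelse(is.na(own[ti]), desc_best[ti], own[ti])
    hit <- !is.na(val)
    A[hit, s] <- -log10(val[hit])
  }
  if (clamped) message("zero adjusted p-value(s) clamped to double.xmin")
  structure(A, class = c("association_matrix", "matrix"))
}

#' Group component terms by consensus semantic similarity
#'
#' Optional reduction of the selected terms into `G` semantic groups:
#' average-linkage clustering of `1 - consensus similarity` (computed on
#' the original graph so that generic, possibly trimmed, terms are
#' comparable), cut into `min(G, #terms)` groups. Group scores are the
#' mean of the member rows of the association matrix; each group is
#' labelled by its medoid term.
#'
#' @param A an `association_matrix`.
#' @param g the original `ontology`.
#' @param G target number of groups, default 50.
#' @return An `association_matrix` over groups, with attribute `members`
#'   (named list of member terms per group).
#' @export
group_association_matrix <- function(A, g, G = 50L) {
  terms <- rownames(A)
  G <- min(G, length(terms))
  if (G == length(terms)) {
    attr(A, "members") <- as.list(stats::setNames(terms, terms))
    return(A)
  }
  S <- term_similarity_matrix(g, terms = terms, metric = "consensus")
  hc <- stats::hclust(stats::as.dist(1 - S), method = "average")
  grp <- stats::cutree(hc, k = G)
  members <- split(terms, grp)
  lab <- vapply(members, function(ts) {
    ts[which.max(colSums(S[ts, ts, drop = FALSE]))]  # medoid
  }, character(1))
  B <- do.call(rbind, lapply(members, function(ts)
    colMeans(A[ts, , drop = FALSE])))
  rownames(B) <- lab
  structure(B, members = stats::setNames(members, lab),
            class = c("association_matrix", "matrix"))
}

#' Non-negative matrix factorization of the association matrix
#'
#' Lee--Seung multiplicative updates minimizing the Frobenius
#' reconstruction error `||A - W H||`. Deterministic under `seed`; the
#' error is non-increasing across iterations. Species are assigned to the
#' component with the largest coefficient in their column of `H`.
#'
#' @param A non-negative matrix (terms x species); must not be all zero.
#' @param k rank (number of components), default 3.
#' @param seed seed for the random starts.
#' @param max_iter,tol iteration cap and relative-improvement tolerance.
#' @param init `"nndsvd"` (deterministic SVD-based initialization, the
#'   first fit) or `"random"`; with `n_starts > 1` additional random
#'   starts are run and the fit with the lowest error is kept.
#' @param n_starts total number of starts, default 5.
#' @return An `nmf_fit`: `W` (terms x k), `H` (k x species), `error`
#'   (final Frobenius norm), `error_trace`, `assignment` (named component
#'   index per species), `iterations`.
#' @export
nmf_decompose <- function(A, k = 3L, seed = NULL, max_iter = 500L,
                          tol = 1e-8, init = c("nndsvd", "random"),
                          n_starts = 5L) {
  init <- match.arg(init)
  A <- as.matrix(A) * 1.0
  if (any(A < 0)) stop_("association matrix has negative entries")
  if (all(A == 0)) stop_("all-zero association matrix")
  n <- nrow(A); m <- ncol(A)
  starts <- vector("list", n_starts)
  seeds <- derive_seeds(seed %||% 0L, n_starts)
  scale0 <- sqrt(mean(A) / k)
  for (s in seq_len(n_starts)) {
    starts[[s]] <- if (s == 1L && init == "nndsvd") nndsvd_init(A, k) else
      with_seed(seeds[[s]], list(
        W = matrix(stats::runif(n * k, 0.1, 1), n, k) * scale0,
        H = matrix(stats::runif(k * m, 0.1, 1), k, m) * scale0))
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    fit <- nmf_mu(A, starts[[s]]$W, starts[[s]]$H, max_iter, tol)
    if (is.null(best) || fit$error < best$error) best <- fit
  }
  assign <- apply(best$H, 2L, which.max)
  names(assign) <- colnames(A)
  structure(list(W = best$W, H = best$H, error = best$error,
                 error_trace = best$err, assignment = assign,
                 iterations = length(best$err), k = k),
            class = "nmf_fit")
}

# Lee-Seung multiplicative updates for the Frobenius objective; the error
# sequence is non-increasing.
nmf_mu <- function(A, W, H, max_iter, tol) {
  eps <- 1e-12
  err <- numeric(0)
  e_prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, A)) / (crossprod(W) %*% H + eps)
    W <- W * (A %*% t(H)) / (W %*% tcrossprod(H) + eps)
    e <- sqrt(sum((A - W %*% H)^2))
    err <- c(err, e)
    if (is.finite(e_prev) && (e_prev - e) < tol * max(e_prev, 1)) break
    e_prev <- e
  }
  list(W = W, H = H, error = err[length(err)], err = err)
}

# Non-negative double SVD initialization (Boutsidis & Gallopoulos):
# leading singular triplets split into their positive parts; zeros are
# filled with the matrix mean to avoid locked entries under
# multiplicative updates (the "nndsvda" variant).
nndsvd_init <- function(A, k) {
  sv <- svd(A, nu = k, nv = k)
  n <- nrow(A); m <- ncol(A)
  W <- matrix(0, n, k); H <- matrix(0, k, m)
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  for (j in seq_len(k)[-1]) {
    if (j > length(sv$d)) break
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    npu <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
    nnu <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
    if (npu >= nnu && npu > 0) {
      W[, j] <- sqrt(sv$d[j] * npu) * up / sqrt(sum(up^2))
      H[j, ] <- sqrt(sv$d[j] * npu) * vp / sqrt(sum(vp^2))
    } else if (nnu > 0) {
      W[, j] <- sqrt(sv$d[j] * nnu) * un / sqrt(sum(un^2))
      H[j, ] <- sqrt(sv$d[j] * nnu) * vn / sqrt(sum(vn^2))
    }
  }
  mu <- mean(A)
  W[W == 0] <- mu; H[H == 0] <- mu
  list(W = W, H = H)
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("NMF fit: k = %d, %d iterations, Frobenius error %.4g\n",
              x$k, x$iterations, x$error))
  invisible(x)
}

#' Write an NMF decomposition as TSV files
#'
#' @param fit an `nmf_fit`.
#' @param w_path,h_path,assign_path output TSVs for the basis, the
#'   coefficients and the species-to-component assignment.
#' @return Paths, invisibly.
#' @export
write_decomposition <- function(fit, w_path, h_path, assign_path) {
  utils::write.table(cbind(term = rownames(fit$W),
                           as.data.frame(fit$W)), w_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cbind(component = seq_len(nrow(fit$H)),
                           as.data.frame(fit$H)), h_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(species = names(fit$assignment),
                                component = fit$assignment), assign_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(w_path, h_path, assign_path))
}
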