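#' Construct an ontology DAG from parent links
#'
#' Builds the rooted directed acyclic graph of terms used throughout the
#' package. Edges point from a child term to its parents (`is_a` links in
#' ontology parlance); the unique term with no parents is the root.
#'
#' @param terms character vector of unique term identifiers.
#' @param parents list parallel to `terms`; each element is a character
#'   vector of parent term identifiers (empty for the root).
#' @param term_names optional character vector of human-readable labels.
#' @return An object of class `ontology` with fields `terms`, `parents`
#'   and `children` (integer adjacency lists), `root` (index), `n_terms`,
#'   and a topological order (ancestors before descendants).
#' @examples
#' g <- new_ontology(c("root", "A", "B"), list(character(), "root", "A"))
#' print(g)
#' @export
new_ontology <- function(terms, parents, term_names = NULL) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) stop_("duplicate term identifiers")
  n <- length(terms)
  if (n < 1L) stop_("empty ontology")
  idx <- seq_len(n)
  names(idx) <- terms
  par_idx <- lapply(parents, function(p) {
    p <- unique(as.character(p))
    i <- idx[p]
    if (anyNA(i)) stop_("parent term(s) not in term set: ",
                        paste(p[is.na(i)], collapse = ", "))
    unname(i)
  })
  child_idx <- vector("list", n)
  for (i in idx) child_idx[[i]] <- integer()
  for (i in idx) for (p in par_idx[[i]]) child_idx[[p]] <- c(child_idx[[p]], i)

  roots <- which(lengths(par_idx) == 0L)
  if (length(roots) == 0L) stop_("no root term (cycle among all terms?)")
  if (length(roots) > 1L)
    stop_("multiple roots / orphan terms: ",
          paste(terms[roots], collapse = ", "))

  topo <- topo_order(par_idx, n)
  if (is.null(topo)) stop_("cycle detected in ontology graph")

  # every non-root term must reach the root
  reach <- logical(n); reach[roots] <- TRUE
  for (i in topo) if (!reach[i] && any(reach[par_idx[[i]]])) reach[i] <- TRUE
  if (!all(reach))
    stop_("term(s) with no path to root: ",
          paste(terms[!reach], collapse = ", "))

  structure(list(
    terms = terms,
    names = if (is.null(term_names)) rep(NA_character_, n) else term_names,
    parents = par_idx,
    children = child_idx,
    root = roots,
    n_terms = n,
    topo = topo,
    cache = new.env(parent = emptyenv())
  ), class = "ontology")
}

# Kahn topological order over child->parent edges: parents emitted before
# children. Returns NULL on cycles.
topo_order <- function(par_idx, n) {
  npar <- lengths(par_idx)
  child <- vector("list", n)
  for (i in seq_len(n)) for (p in par_idx[[i]]) child[[p]] <- c(child[[p]], i)
  queue <- which(npar == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (ch in child[[v]]) {
      npar[ch] <- npar[ch] - 1L
      if (npar[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != n) NULL else out
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("ontology: %d terms, %d edges, root = %s\n",
              x$n_terms, sum(lengths(x$parents)), x$terms[x$root]))
  invisible(x)
}

term_index <- function(g, t) {
  i <- match(t, g$terms)
  if (anyNA(i)) stop_("unknown term(s): ", paste(t[is.na(i)], collapse = ", "))
  i
}

# Ancestor index sets (exclusive of self), memoised on the graph.
anc_sets <- function(g) {
  if (!is.null(g$cache$anc)) return(g$cache$anc)
  anc <- vector("list", g$n_terms)
  for (i in g$topo) {
    ps <- g$parents[[i]]
    anc[[i]] <- if (length(ps) == 0L) integer() else
      sort(unique(c(ps, unlist(anc[ps], use.names = FALSE))))
  }
  g$cache$anc <- anc
  anc
}

# Number of distinct descendants (exclusive of self) per term.
desc_counts <- function(g, universe_idx = NULL) {
  anc <- anc_sets(g)
  d <- integer(g$n_terms)
  use <- if (is.null(universe_idx)) seq_len(g$n_terms) else universe_idx
  for (i in use) for (a in anc[[i]]) d[a] <- d[a] + 1L
  d
}

#' Query ancestors or descendants of a term
#'
#' @param g an `ontology`.
#' @param t a term identifier.
#' @param inclusive include the term itself?
#' @return Character vector of term identifiers.
#' @export
ancestors <- function(g, t, inclusive = FALSE) {
  i <- term_index(g, t)
  a <- anc_sets(g)[[i]]
  if (inclusive) a <- sort(unique(c(a, i)))
  g$terms[a]
}

#' @rdname ancestors
#' @export
descendants <- function(g, t, inclusive = FALSE) {
  i <- term_index(g, t)
  anc <- anc_sets(g)
  d <- which(vapply(anc, function(a) i %in% a, logical(1)))
  if (inclusive) d <- sort(unique(c(d, i)))
  g$terms[d]
}

# Shortest-path distance (number of edges) from the root to every term,
# walking child links breadth-first.
root_distances <- function(g) {
  if (!is.null(g$cache$rootdist)) return(g$cache$rootdist)
  dist <- rep(NA_integer_, g$n_terms)
  dist[g$root] <- 0L
  queue <- g$root
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (ch in g$children[[v]]) {
      if (is.na(dist[ch])) {
        dist[ch] <- dist[v] + 1L
        queue <- c(queue, ch)
      }
    }
  }
  g$cache$rootdist <- dist
  dist
}
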