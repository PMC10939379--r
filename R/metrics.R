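#' Logistic ancestor-contribution weight
#'
#' The weight a term contributes to the semantic value of its descendants:
#' `sw(a) = 1 / (1 + exp(-1 / IC(a)))`, with the IC -> 0 limit equal to 1
#' (the root contributes exactly 1). Monotonically decreasing in IC and
#' bounded in (0.5, 1].
#'
#' @param ic non-negative information content value(s) in bits.
#' @return Numeric weight(s) in (0.5, 1].
#' @export
sv_weight <- function(ic) {
  w <- ifelse(ic <= 0, 1, 1 / (1 + exp(-1 / ic)))
  as.numeric(w)
}

#' Structural information content and semantic value of every term
#'
#' IC measures a term's specificity from its descendant count:
#' `IC(t) = -log2((D(t) + 1) / N)` where `D(t)` is the number of distinct
#' descendants of `t` (self excluded) and `N` the size of the term universe.
#' The root has IC 0, leaves have `log2(N)`. SV measures the information
#' accumulated along a term's ancestral plexus:
#' `SV(t) = sum over ancestors a of sv_weight(IC(a))` (self excluded), so
#' the root has SV 0 and SV grows strictly along any root-to-leaf path.
#'
#' @param g an `ontology`.
#' @param universe optional character vector of term ids restricting the
#'   universe (e.g. terms with at least one gene annotation). The set is
#'   closed under ancestors (and always contains the root) so that
#'   `IC(root) = 0` holds; `N` and descendant counts are taken within it.
#'   `NULL` uses all graph terms.
#' @return A `term_metrics` data frame with columns `term`, `ic`, `sv`,
#'   `sw`, attribute `n_universe`.
#' @examples
#' g <- new_ontology(c("r", "A", "B", "C"),
#'                   list(character(), "r", "r", c("A", "B")))
#' compute_metrics(g)
#' @export
compute_metrics <- function(g, universe = NULL) {
  stopifnot(inherits(g, "ontology"))
  anc <- anc_sets(g)
  if (is.null(universe)) {
    uni_idx <- seq_len(g$n_terms)
  } else {
    uni_idx <- term_index(g, unique(universe))
    # ancestor closure keeps the universe a rooted sub-DAG
    uni_idx <- sort(unique(c(uni_idx, unlist(anc[uni_idx], use.names = FALSE),
                             g$root)))
  }
  N <- length(uni_idx)
  d <- desc_counts(g, uni_idx)
  in_uni <- logical(g$n_terms); in_uni[uni_idx] <- TRUE
  # descendants of t within the universe; t itself contributes the "+1"
  ic <- -log2((d + 1) / N)
  ic[ic < 0] <- 0  # guard terms outside a restricted universe
  sw <- sv_weight(ic)
  sv <- vapply(seq_len(g$n_terms), function(i) sum(sw[anc[[i]]]), numeric(1))
  structure(
    data.frame(term = g$terms, ic = ic, sv = sv, sw = sw,
               stringsAsFactors = FALSE),
    n_universe = N, class = c("term_metrics", "data.frame")
  )
}

metric_lookup <- function(m, what) {
  v <- m[[what]]
  names(v) <- m$term
  v
}

#' Build the standardized (pruned) ontology graph
#'
#' A term is trimmed iff its IC exceeds the `pct`-th percentile of the IC
#' distribution AND its SV exceeds the `pct`-th percentile of the SV
#' distribution (both strictly); this removes very specific terms sitting
#' in expanded, densely annotated branches while keeping the rest of the
#' graph. Every term of the original graph is mapped onto its most
#' proximal retained ancestors (itself if retained).
#'
#' @param g an `ontology`.
#' @param m a `term_metrics` for `g`.
#' @param pct percentile (0-100) for both cutoffs; default 20.
#' @param ic_threshold,sv_threshold explicit cutoffs overriding the
#'   percentiles (used e.g. to re-apply a previous standardization).
#' @return A `standardized_ontology`: list with `ontology`, `metrics`,
#'   `retained` (character), `ic_threshold`, `sv_threshold`, and `mapping`
#'   (named list: every term -> non-empty character vector of retained
#'   ancestor-or-self targets).
#' @export
build_standardized_graph <- function(g, m, pct = 20,
                                     ic_threshold = NULL, sv_threshold = NULL) {
  stopifnot(inherits(g, "ontology"), inherits(m, "term_metrics"))
  m <- m[match(g$terms, m$term), ]
  if (anyNA(m$term)) stop_("metrics do not cover all graph terms")
  qic <- ic_threshold %||% unname(stats::quantile(m$ic, pct / 100, type = 7))
  qsv <- sv_threshold %||% unname(stats::quantile(m$sv, pct / 100, type = 7))
  trimmed <- m$ic > qic & m$sv > qsv
  retained_idx <- which(!trimmed)
  if (length(retained_idx) <= 1L)
    warn_("standardized graph degenerate: only the root survives trimming")

  anc <- anc_sets(g)
  keep <- !trimmed
  # most proximal retained ancestors, computed root-down so that parents'
  # mappings are available when a trimmed child is reached
  map_idx <- vector("list", g$n_terms)
  for (i in g$topo) {
    if (keep[i]) { map_idx[[i]] <- i; next }
    tgt <- sort(unique(unlist(map_idx[g$parents[[i]]], use.names = FALSE)))
    # drop strict ancestors of other targets (keep minimal elements)
    if (length(tgt) > 1L) {
      is_anc_of_other <- vapply(tgt, function(a)
        any(vapply(setdiff(tgt, a), function(b) a %in% anc[[b]], logical(1))),
        logical(1))
      tgt <- tgt[!is_anc_of_other]
    }
    map_idx[[i]] <- tgt
  }
  mapping <- lapply(map_idx, function(ix) g$terms[ix])
  names(mapping) <- g$terms

  structure(list(
    ontology = g,
    metrics = m,
    retained = g$terms[retained_idx],
    retained_idx = retained_idx,
    ic_threshold = qic,
    sv_threshold = qsv,
    mapping = mapping
  ), class = "standardized_ontology")
}

#' @export
print.standardized_ontology <- function(x, ...) {
  cat(sprintf(paste0("standardized ontology: %d of %d terms retained ",
                     "(IC > %.4g & SV > %.4g trimmed)\n"),
              length(x$retained), x$ontology$n_terms,
              x$ic_threshold, x$sv_threshold))
  invisible(x)
}

#' Map a term onto the standardized graph
#'
#' A retained term maps to itself; a trimmed term maps to the set of its
#' most proximal retained ancestors (ascending every parent path to the
#' first retained node, then dropping targets that are strict ancestors of
#' other targets).
#'
#' @param sg a `standardized_ontology`.
#' @param t term identifier(s) present in the original graph.
#' @return For one term, a character vector of retained targets; for
#'   several, a named list.
#' @export
map_to_standard <- function(sg, t) {
  stopifnot(inherits(sg, "standardized_ontology"))
  out <- sg$mapping[t]
  if (any(vapply(out, is.null, logical(1))))
    stop_("unknown term(s): ", paste(t[vapply(out, is.null, logical(1))],
                                     collapse = ", "))
  if (length(t) == 1L) out[[1L]] else out
}

#' Extract the retained sub-DAG as a standalone ontology
#'
#' Edges are the transitive reduction of the retained-ancestor relation:
#' each retained term's parents are its minimal retained strict ancestors.
#'
#' @param sg a `standardized_ontology`.
#' @return An `ontology` over the retained terms.
#' @export
as_ontology <- function(sg) {
  stopifnot(inherits(sg, "standardized_ontology"))
  g <- sg$ontology
  anc <- anc_sets(g)
  ridx <- sg$retained_idx
  in_r <- logical(g$n_terms); in_r[ridx] <- TRUE
  pars <- lapply(ridx, function(i) {
    ra <- anc[[i]][in_r[anc[[i]]]]
    if (!length(ra)) return(character())
    minimal <- ra[!vapply(ra, function(a)
      any(vapply(setdiff(ra, a), function(b) a %in% anc[[b]], logical(1))),
      logical(1))]
    g$terms[minimal]
  })
  new_ontology(g$terms[ridx], pars, g$names[ridx])
}

#' Recompute IC/SV/sw on the standardized sub-DAG
#'
#' Similarity between retained terms is computed with metrics of the
#' pruned graph itself (descendant counts and N restricted to retained
#' terms), not the original graph.
#'
#' @param sg a `standardized_ontology`.
#' @return A `term_metrics` over the retained terms.
#' @export
standardized_metrics <- function(sg) {
  compute_metrics(as_ontology(sg))
}

#' Write / read a standardized graph as TSV
#'
#' `write_standardized` emits two files: a term table
#' (term, ic, sv, retained) and a mapping table (term, targets as a
#' comma-separated list). `read_standardized_terms` and
#' `read_standardized_mapping` read them back.
#'
#' @param sg a `standardized_ontology`.
#' @param terms_path,mapping_path output TSV paths.
#' @return Paths, invisibly.
#' @export
write_standardized <- function(sg, terms_path, mapping_path) {
  m <- sg$metrics
  tab <- data.frame(term = m$term, ic = m$ic, sv = m$sv,
                    retained = m$term %in% sg$retained)
  utils::write.table(tab, terms_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  map <- data.frame(term = names(sg$mapping),
                    targets = vapply(sg$mapping, paste, character(1),
                                     collapse = ","))
  utils::write.table(map, mapping_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(terms_path, mapping_path))
}

#' @rdname write_standardized
#' @param path a TSV written by `write_standardized`.
#' @export
read_standardized_terms <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname write_standardized
#' @export
read_standardized_mapping <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- strsplit(tab$targets, ",", fixed = TRUE)
  names(out) <- tab$term
  out
}
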