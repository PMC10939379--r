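# Shared fixtures and independent oracles.

# diamond DAG: root -> {A, B}, A -> C, B -> C
diamond <- function() {
  new_ontology(c("root", "A", "B", "C"),
               list(character(), "root", "root", c("A", "B")))
}

# random rooted DAG over n terms (independent of the synth module's
# layered generator): term i attaches to 1-3 uniformly chosen earlier
# terms, so indices are already a topological order
random_dag <- function(n, seed) {
  withr::with_seed(seed, {
    ids <- sprintf("N%03d", seq_len(n))
    parents <- vector("list", n)
    parents[[1]] <- character()
    for (i in 2:n) {
      np <- sample.int(min(3L, i - 1L), 1L)
      parents[[i]] <- ids[sample.int(i - 1L, np)]
    }
    new_ontology(ids, parents)
  })
}

# Brute-force transitive closure by boolean matrix powers; wholly
# independent of the package's adjacency-list DP.
closure_oracle <- function(g) {
  n <- g$n_terms
  adj <- matrix(FALSE, n, n)  # child -> parent reachability
  for (i in seq_len(n)) adj[i, g$parents[[i]]] <- TRUE
  reach <- adj
  repeat {
    nxt <- reach | ((reach %*% adj) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  reach  # reach[i, j]: j is a strict ancestor of i
}

# IC/SV oracle from the closure matrix
metrics_oracle <- function(g) {
  reach <- closure_oracle(g)
  n <- g$n_terms
  D <- colSums(reach)                      # strict descendants
  ic <- -log2((D + 1) / n)
  sw <- ifelse(ic <= 0, 1, 1 / (1 + exp(-1 / ic)))
  sv <- vapply(seq_len(n), function(i) sum(sw[reach[i, ]]), numeric(1))
  list(ic = unname(ic), sv = unname(sv), sw = unname(sw), reach = reach)
}

# small in-memory corpus: one species, explicit gene -> terms map
toy_corpus <- function(gene2terms, species = "sp1") {
  annotation_corpus(stats::setNames(list(gene2terms), species))
}

write_tmp_lines <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Exhaustive-draw hypergeometric tail oracle: enumerate all C(U, n) draws.
hyper_tail_enum <- function(U, K, n, k) {
  draws <- utils::combn(U, n)
  marked <- seq_len(K)
  hits <- colSums(matrix(draws %in% marked, nrow = n))
  mean(hits >= k)
}

# Independent choose-sum tail (no phyper): P(X >= k)
hyper_tail_sum <- function(U, K, n, k) {
  kk <- max(k, max(0, n - (U - K))):min(K, n)
  sum(exp(lchoose(K, kk) + lchoose(U - K, n - kk) - lchoose(U, n)))
}
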