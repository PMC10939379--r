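# profiles with fixed mapped term sets (reusing the similarity fixture)
prof_with_map <- function(species, mapping, p_adj = NULL) {
  terms <- data.frame(term = names(mapping), k = 1L, K = 2L, n = 3L,
                      U = 10L, p_hyper = 0.01,
                      p_adj = p_adj %||% rep(0.01, length(mapping)))
  structure(list(species = species, terms = terms, mapping = mapping,
                 updated = TRUE), class = "semantic_profile")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("quasi-omnipresent selection is strict and redundancy-reduced", {
  g <- diamond()
  m <- compute_metrics(g)
  sg <- build_standardized_graph(g, m, ic_threshold = 10, sv_threshold = 10)
  # 10 species: A present in all, C present in all -> both qualify, but A
  # is an ancestor of C and must be removed
  profs <- lapply(1:10, function(i)
    prof_with_map(paste0("s", i), list(A = "A", C = "C")))
  expect_equal(select_core_terms(profs, sg), "C")
  # presence at exactly 90% is excluded
  profs2 <- lapply(1:10, function(i) {
    maps <- if (i <= 9) list(A = "A", B = "B") else list(A = "A")
    prof_with_map(paste0("s", i), maps)
  })
  expect_setequal(select_core_terms(profs2, sg), "A")
  # 95% presence qualifies
  profs3 <- lapply(1:20, function(i) {
    maps <- if (i <= 19) list(B = "B") else list(A = "A")
    prof_with_map(paste0("s", i), maps)
  })
  expect_equal(select_core_terms(profs3, sg), "B")
})

test_that("generic terms sit at shortest root distance 2 and use strict coverage", {
  # r -> a -> b -> c and r -> b (b has root distances {1, 2} -> distance 1;
  # c has distances {2, 3} -> generic at 2)
  g <- new_ontology(c("r", "a", "b", "c", "d"),
                    list(character(), "r", c("a", "r"), "b", "c"))
  dist2 <- g$terms[!is.na(semphylo:::root_distances(g)) &
                     semphylo:::root_distances(g) == 2L]
  expect_equal(dist2, "c")
  m <- compute_metrics(g)
  sg <- build_standardized_graph(g, m, ic_threshold = 10, sv_threshold = 10)
  # 10 species, 6 carrying the sub-threshold descendant d of c -> 60% > 50%
  profs <- lapply(1:10, function(i) {
    maps <- if (i <= 6) list(d = "d") else list(a = "a")
    prof_with_map(paste0("s", i), maps)
  })
  expect_equal(select_generic_terms(profs, g), "c")
  # exactly 50% coverage is excluded
  profs2 <- lapply(1:10, function(i) {
    maps <- if (i <= 5) list(d = "d") else list(a = "a")
    prof_with_map(paste0("s", i), maps)
  })
  expect_equal(select_generic_terms(profs2, g), character())
})

test_that("association scores use own p, then best descendant p, else 0", {
  g <- diamond()
  profs <- list(
    s1 = prof_with_map("s1", list(A = "A"), p_adj = 0.01),
    s2 = prof_with_map("s2", list(C = "C"), p_adj = 0.001),
    s3 = prof_with_map("s3", list(B = "B"), p_adj = 0.1)
  )
  A <- build_association_matrix(c("A", "C"), profs, g)
  expect_equal(A["A", "s1"], 2)          # enriched itself: -log10(0.01)
  expect_equal(A["A", "s2"], 3)          # via descendant C at 0.001
  expect_equal(A["C", "s3"], 0)          # absent everywhere
  expect_equal(A["C", "s1"], 0)          # A is an ancestor, not descendant
  expect_true(all(A >= 0))
})

test_that("own enrichment takes precedence over a lower descendant p", {
  g <- diamond()
  profs <- list(s1 = prof_with_map("s1", list(A = "A", C = "C"),
                                   p_adj = c(0.1, 0.0001)))
  A <- build_association_matrix(c("A"), profs, g)
  expect_equal(A["A", "s1"], 1)          # -log10(0.1), not the descendant's 4
})

test_that("zero adjusted p-values are clamped, not infinite", {
  g <- diamond()
  profs <- list(s1 = prof_with_map("s1", list(A = "A"), p_adj = 0))
  expect_message(A <- build_association_matrix("A", profs, g), "clamped")
  expect_true(is.finite(A["A", "s1"]) && A["A", "s1"] > 100)
})

test_that("rank-1 matrices factor exactly at k = 1", {
  w <- runif(8) + 0.1; h <- runif(5) + 0.1
  A <- outer(w, h)
  rownames(A) <- paste0("t", 1:8); colnames(A) <- paste0("s", 1:5)
  fit <- nmf_decompose(A, k = 1, seed = 1, max_iter = 2000, tol = 0)
  expect_lt(fit$error, 1e-8)
  expect_true(all(fit$W >= 0) && all(fit$H >= 0))
})

test_that("NMF recovers a planted block-diagonal structure", {
  withr::with_seed(10, {
    A <- matrix(0, 12, 9)
    for (b in 0:2)
      A[b * 4 + 1:4, b * 3 + 1:3] <- matrix(runif(12, 1, 3), 4, 3)
    rownames(A) <- paste0("t", 1:12); colnames(A) <- paste0("s", 1:9)
  })
  fit <- nmf_decompose(A, k = 3, seed = 2)
  truth <- rep(1:3, each = 3)
  ari <- mclust::adjustedRandIndex(fit$assignment, truth)
  expect_equal(ari, 1)
  # multiplicative updates never increase the error
  expect_true(all(diff(fit$error_trace) <= 1e-9))
})

test_that("degenerate NMF inputs are rejected", {
  A <- matrix(0, 3, 3)
  expect_error(nmf_decompose(A), "all-zero")
  B <- matrix(c(1, -1, 2, 3), 2, 2)
  expect_error(nmf_decompose(B), "negative")
})

test_that("semantic grouping reduces rows and preserves column count", {
  g <- random_dag(40, seed = 21)
  terms <- sample(g$terms, 12)
  A <- matrix(runif(12 * 6), 12, 6,
              dimnames = list(terms, paste0("s", 1:6)))
  class(A) <- c("association_matrix", "matrix")
  B <- group_association_matrix(A, g, G = 4)
  expect_equal(nrow(B), 4L)
  expect_equal(ncol(B), 6L)
  members <- attr(B, "members")
  expect_setequal(unlist(members), terms)
  # group scores are the means of member rows
  for (lab in rownames(B))
    expect_equal(unname(B[lab, ]), unname(colMeans(A[members[[lab]], ,
                                                     drop = FALSE])),
                 tolerance = 1e-12)
})
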