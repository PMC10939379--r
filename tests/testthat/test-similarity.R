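test_that("aggregate-IC self-similarity is 1 for every term", {
  g <- random_dag(40, seed = 2)
  for (t in sample(g$terms, 8)) {
    expect_equal(pairwise_term_similarity(g, t, t, metric = "aic"), 1,
                 tolerance = 1e-12)
  }
})

test_that("leaves sharing only the root have Resnik similarity 0", {
  g <- new_ontology(c("r", "a", "b"), list(character(), "r", "r"))
  expect_equal(pairwise_term_similarity(g, "a", "b", "resnik"), 0)
  expect_equal(pairwise_term_similarity(g, "a", "b", "xgrasm"), 0)
})

test_that("diamond consensus(A, C) equals the frozen closed-form value", {
  g <- diamond()
  # hand enumeration: CA(A,C) = {A, root}; resnik = IC(A)/IC_max = 1/2;
  # xgrasm = mean{IC(A)}/IC(C) = 1/2; aic = 2(1 + sw(A))/(SV+(A) + SV+(C))
  expect_equal(pairwise_term_similarity(g, "A", "C", "resnik"), 0.5)
  expect_equal(pairwise_term_similarity(g, "A", "C", "xgrasm"), 0.5)
  expect_equal(pairwise_term_similarity(g, "A", "C", "aic"),
               0.71893262446707, tolerance = 1e-12)
  expect_equal(pairwise_term_similarity(g, "A", "C", "consensus"),
               0.572977541489023, tolerance = 1e-12)
})

test_that("consensus similarity is symmetric and bounded on random DAGs", {
  for (seed in 1:5) {
    g <- random_dag(25, seed = 100 + seed)
    S <- term_similarity_matrix(g, metric = "consensus")
    expect_true(all(S >= 0 & S <= 1 + 1e-12))
    expect_equal(S, t(S), tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("cross-set similarity is the mean over the full cross product", {
  g <- diamond()
  S <- term_similarity_matrix(g)
  expect_equal(enriched_term_similarity("C", "C", S), S["C", "C"])
  expect_equal(enriched_term_similarity("A", c("B", "C"), S),
               (S["A", "B"] + S["A", "C"]) / 2)
  expect_equal(enriched_term_similarity(c("B", "C"), "A", S),
               enriched_term_similarity("A", c("B", "C"), S))
  expect_error(enriched_term_similarity(character(), "A", S), "empty")
})

# minimal updated profile with explicit mappings
fake_profile <- function(species, mapping) {
  terms <- data.frame(term = names(mapping), k = 1L, K = 2L, n = 3L,
                      U = 10L, p_hyper = 0.01, p_adj = 0.01)
  structure(list(species = species, terms = terms, mapping = mapping,
                 updated = TRUE), class = "semantic_profile")
}

test_that("best-match-average equals an exhaustive oracle on toy profiles", {
  g <- diamond()
  S <- term_similarity_matrix(g)
  p1 <- fake_profile("s1", list(t1 = "A", t2 = c("A", "B"), t3 = "C"))
  p2 <- fake_profile("s2", list(u1 = "B", u2 = c("root", "C")))
  got <- species_similarity(p1, p2, S)
  # oracle: explicit loops over every enriched pair
  sim <- function(ma, mb) mean(S[ma, mb])
  C <- outer(seq_along(p1$mapping), seq_along(p2$mapping),
             Vectorize(function(i, j) sim(p1$mapping[[i]], p2$mapping[[j]])))
  oracle <- (sum(apply(C, 1, max)) + sum(apply(C, 2, max))) / (3 + 2)
  expect_equal(got, oracle, tolerance = 1e-12)
  # singleton profiles reduce to the pair similarity
  q1 <- fake_profile("q1", list(t = "A"))
  q2 <- fake_profile("q2", list(u = "C"))
  expect_equal(species_similarity(q1, q2, S), S["A", "C"])
})

test_that("identical profiles are at distance 0 under a self-sim-1 metric", {
  g <- diamond()
  S <- term_similarity_matrix(g, metric = "aic")
  p <- fake_profile("s1", list(t1 = "A", t2 = "C"))
  q <- fake_profile("s2", list(t1 = "A", t2 = "C"))
  expect_equal(species_similarity(p, q, S), 1, tolerance = 1e-12)
  D <- build_distance_matrix(list(s1 = p, s2 = q), S)
  expect_equal(D["s1", "s2"], 0, tolerance = 1e-12)
})

test_that("distance matrices are symmetric, zero-diagonal and 1 - SSim", {
  g <- random_dag(30, seed = 77)
  S <- term_similarity_matrix(g)
  profs <- lapply(1:5, function(i) {
    terms <- sample(g$terms, 4)
    fake_profile(paste0("s", i),
                 stats::setNames(lapply(terms, identity), terms))
  })
  names(profs) <- paste0("s", 1:5)
  D <- build_distance_matrix(profs, S)
  expect_equal(diag(D), stats::setNames(rep(0, 5), names(profs)))
  expect_equal(D, t(D), ignore_attr = TRUE)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(D[i, j], 1 - species_similarity(profs[[i]], profs[[j]], S),
                 tolerance = 1e-12)
  }
})

test_that("self-similarity is near-maximal and the self-distance is zero", {
  # group-wise self-similarity is not exactly maximal: sim(t, t) is the
  # mean over the term's mapped target set, which dips below 1 when the
  # targets are mutually distant, so a cross-species term can exceed it
  # slightly; this is exactly why the species self-distance is defined as
  # 0 rather than 1 - SSim(s, s)
  cfg <- synth_config(n_species = 3, seed = 12)
  g <- generate_dag(cfg)
  sim <- generate_kingdom_corpus(cfg, g)
  fit <- semantic_phylogeny(sim$gene_sets, sim$corpus, g,
                            permutations = 99, seed = 12)
  expect_equal(unname(diag(fit$distance)),
               rep(0, length(fit$profiles)))
  for (sp in names(fit$profiles)) {
    self <- species_similarity(fit$profiles[[sp]], fit$profiles[[sp]], fit$S)
    for (other in setdiff(names(fit$profiles), sp)) {
      cross <- species_similarity(fit$profiles[[sp]], fit$profiles[[other]],
                                  fit$S)
      expect_gte(self, cross - 0.05)
    }
    # same-kingdom species are far closer than other-kingdom species
    kin <- startsWith(names(fit$profiles), substr(sp, 1, 2))
    expect_lt(mean(fit$distance[sp, kin & names(fit$profiles) != sp]),
              mean(fit$distance[sp, !kin]))
  }
})

test_that("matrix TSV round-trips and rejects non-square input", {
  m <- matrix(runif(9), 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  path <- tempfile(fileext = ".tsv")
  write_matrix_tsv(m, path)
  expect_equal(read_matrix_tsv(path), m, tolerance = 1e-12)
  bad <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(id = c("a", "b"), a = 1:2), bad,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_matrix_tsv(bad), "square")
})
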