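# universe of U genes, one term marked on the first K, query = first n
flat_corpus <- function(U, K, term = "tA", extra = list()) {
  genes <- sprintf("g%03d", seq_len(U))
  g2t <- lapply(seq_len(U), function(i) {
    ts <- if (i <= K) term else character()
    for (nm in names(extra)) if (i %in% extra[[nm]]) ts <- c(ts, nm)
    ts
  })
  names(g2t) <- genes
  g2t <- g2t[lengths(g2t) > 0]
  # pad unannotated genes with a background term so the universe stays U
  bg <- setdiff(genes, names(g2t))
  g2t <- c(g2t, stats::setNames(replicate(length(bg), "bg",
                                          simplify = FALSE), bg))
  toy_corpus(g2t)
}

test_that("full-overlap query reproduces the closed-form tail 1/C(20,5)", {
  corpus <- flat_corpus(20, 5)
  q <- gene_set("sp1", sprintf("g%03d", 1:5))
  rec <- hypergeometric_test(q, corpus)
  expect_equal(rec$p_hyper[rec$term == "tA"], 6.4499484004128e-05,
               tolerance = 1e-12)
  expect_equal(rec$k[rec$term == "tA"], 5L)
})

test_that("zero overlap gives p = 1", {
  corpus <- flat_corpus(30, 5)
  q <- gene_set("sp1", sprintf("g%03d", 11:15))
  rec <- hypergeometric_test(q, corpus)
  expect_equal(rec$p_hyper[rec$term == "tA"], 1)
})

test_that("tail probabilities match exhaustive draw enumeration", {
  cases <- list(c(U = 8, K = 3, n = 4), c(U = 10, K = 5, n = 3),
                c(U = 12, K = 4, n = 5), c(U = 14, K = 7, n = 4))
  for (cs in cases) {
    corpus <- flat_corpus(cs["U"], cs["K"])
    for (k_target in 0:min(cs["K"], cs["n"])) {
      # query with exactly k_target marked genes
      q_genes <- c(sprintf("g%03d", seq_len(k_target)),
                   sprintf("g%03d", cs["K"] + seq_len(cs["n"] - k_target)))
      if (length(q_genes) != cs["n"]) next
      q <- gene_set("sp1", q_genes)
      rec <- hypergeometric_test(q, corpus)
      expect_equal(rec$p_hyper[rec$term == "tA"],
                   hyper_tail_enum(cs["U"], cs["K"], cs["n"], k_target),
                   tolerance = 1e-12,
                   label = paste("U,K,n,k =", cs["U"], cs["K"], cs["n"],
                                 k_target))
    }
  }
})

test_that("query genes outside the universe are dropped, empty query fatal", {
  corpus <- flat_corpus(20, 5)
  q <- gene_set("sp1", c("g001", "alien"))
  expect_message(rec <- hypergeometric_test(q, corpus), "dropped")
  expect_equal(rec$n[1], 1L)
  expect_error(suppressMessages(
    hypergeometric_test(gene_set("sp1", "alien"), corpus)), "empty")
})

test_that("adding contained genes to the query never raises a term's p", {
  corpus <- flat_corpus(25, 6)
  p_prev <- 1
  for (n in 2:6) {
    q <- gene_set("sp1", sprintf("g%03d", 1:n))  # all inside the term
    rec <- hypergeometric_test(q, corpus)
    p <- rec$p_hyper[rec$term == "tA"]
    expect_lte(p, p_prev + 1e-15)
    p_prev <- p
  }
})

test_that("permutation p_adj hits its lower bound and is seed-stable", {
  corpus <- flat_corpus(40, 8)
  q <- gene_set("sp1", sprintf("g%03d", 1:8))
  rec <- hypergeometric_test(q, corpus)
  rec <- rec[rec$term == "tA", ]
  out1 <- permutation_prioritize(rec, corpus, R = 999, seed = 7,
                                 species = "sp1")
  # observed overlap 8/8 beats every permutation
  expect_equal(out1$p_adj, 1 / 1000)
  out2 <- permutation_prioritize(rec, corpus, R = 999, seed = 7,
                                 species = "sp1")
  expect_identical(out1$p_adj, out2$p_adj)
})

test_that("profile selection honours both cuts and the 100-term floor", {
  mk_records <- function(n_pass_both, n_pass_raw, n_total = n_pass_raw + 20) {
    data.frame(term = sprintf("t%04d", seq_len(n_total)),
               k = 5L, K = 10L, n = 50L, U = 500L,
               p_hyper = c(rep(0.01, n_pass_raw),
                           rep(0.5, n_total - n_pass_raw)),
               p_adj = c(rep(0.01, n_pass_both),
                         rep(0.2, n_total - n_pass_both)))
  }
  # 60 pass both, 200 pass raw -> exactly 100
  p <- build_profile(mk_records(60, 200), species = "s")
  expect_equal(nrow(p$terms), 100L)
  expect_true(all(p$terms$p_hyper < 0.05))
  # 150 pass both -> all 150 kept, no truncation
  p2 <- build_profile(mk_records(150, 200), species = "s")
  expect_equal(nrow(p2$terms), 150L)
  # only 40 raw-passing candidates -> floor capped at 40
  p3 <- build_profile(mk_records(10, 40), species = "s")
  expect_equal(nrow(p3$terms), 40L)
  # nothing passes the raw cut -> error
  bad <- mk_records(0, 0)
  expect_error(build_profile(bad, species = "s"), "raw")
})

test_that("profile extension follows the (p_adj, p_hyper, term) order", {
  rec <- data.frame(term = c("tC", "tA", "tB", "tD"),
                    k = 3L, K = 5L, n = 10L, U = 100L,
                    p_hyper = c(0.01, 0.02, 0.01, 0.04),
                    p_adj = c(0.10, 0.08, 0.10, 0.30))
  p <- build_profile(rec, floor = 3L, species = "s")
  expect_equal(p$terms$term, c("tA", "tB", "tC"))
})

test_that("update_profile applies mapping and the IC floor", {
  g <- diamond()
  m <- compute_metrics(g)
  sg <- build_standardized_graph(g, m, ic_threshold = 10, sv_threshold = 10)
  rec <- data.frame(term = c("A", "root"), k = 2L, K = 3L, n = 5L, U = 20L,
                    p_hyper = c(0.01, 0.01), p_adj = c(0.01, 0.01))
  prof <- build_profile(rec, species = "sp1")
  up <- update_profile(prof, sg, m, ic_min = 0.1)
  # A retained with IC 1 -> maps to itself; root has IC 0 -> removed
  expect_equal(up$terms$term, "A")
  expect_equal(up$mapping[["A"]], "A")
  # mixed mapping keeps only informative targets
  sg2 <- build_standardized_graph(g, m, ic_threshold = 1.5,
                                  sv_threshold = 0.5)
  # C trimmed, maps to {A, B}; force a mapping containing the root by
  # trimming A and B too
  sg3 <- suppressWarnings(
    build_standardized_graph(g, m, ic_threshold = 0, sv_threshold = 0))
  rec3 <- data.frame(term = "C", k = 2L, K = 3L, n = 5L, U = 20L,
                     p_hyper = 0.01, p_adj = 0.01)
  prof3 <- build_profile(rec3, species = "spx")
  expect_error(update_profile(prof3, sg3, m), "spx")
  up2 <- update_profile(build_profile(rec3, species = "spy"), sg2, m)
  expect_setequal(up2$mapping[["C"]], c("A", "B"))
})
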