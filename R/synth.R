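# Synthetic ontologies and annotation corpora with planted kingdom
# structure, so every pipeline stage is testable without external data.

#' Configuration for the synthetic corpus generator
#'
#' Defaults describe the study conditions used throughout the package's
#' tests: a three-kingdom corpus of 60 species with a shared core
#' functional module, one kingdom-specific module each, strong query
#' signal and a small annotation noise rate.
#'
#' @param n_terms number of ontology terms, default 150.
#' @param depth number of layers below the root, default 6.
#' @param max_parents maximum parents per term (1-3), default 3.
#' @param n_species species per kingdom (3 kingdoms), default 20.
#' @param n_genes annotated genes per species, default 600.
#' @param core_size terms in the shared core module, default 8.
#' @param kingdom_size terms per kingdom-specific module, default 6.
#' @param genes_per_term dedicated genes annotated to each module term,
#'   default 8.
#' @param query_size genes per species query list, default 80.
#' @param signal fraction of query genes drawn from the species' module
#'   genes, default 0.9.
#' @param noise annotation noise rate: probability a background gene gains
#'   an extra random term, default 0.05.
#' @param seed master seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_terms = 150L, depth = 6L, max_parents = 3L,
                         n_species = 20L, n_genes = 600L, core_size = 8L,
                         kingdom_size = 6L, genes_per_term = 8L,
                         query_size = 80L, signal = 0.9, noise = 0.05,
                         seed = 1L) {
  stopifnot(n_terms >= 2L, depth >= 1L, n_species >= 1L,
            signal >= 0, signal <= 1, noise >= 0, noise < 1)
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a random rooted DAG ontology
#'
#' Layer-wise construction: terms are spread over `depth` layers below a
#' single root; each term attaches to 1 to `max_parents` uniformly chosen
#' terms of shallower layers (layer-1 terms to the root). Acyclic by
#' construction and reproducible under the configured seed.
#'
#' @param cfg a `synth_config` (or arguments passed to [synth_config()]).
#' @return An `ontology` with terms `T0001 ... Tnnnn` (root `T0001`).
#' @export
generate_dag <- function(cfg = synth_config()) {
  if (!inherits(cfg, "synth_config")) stop_("cfg must be a synth_config")
  n <- cfg$n_terms
  ids <- sprintf("T%04d", seq_len(n))
  layer <- c(0L, sort(rep_len(seq_len(cfg$depth), n - 1L)))
  parents <- vector("list", n)
  parents[[1L]] <- character()
  # parent-count distribution skewed toward single inheritance, as in
  # real process ontologies
  pp <- c(0.7, 0.25, 0.05)[seq_len(cfg$max_parents)]
  with_seed(cfg$seed, {
    for (i in 2:n) {
      pool <- which(layer < layer[i])
      np <- min(sample.int(length(pp), 1L, prob = pp), length(pool))
      parents[[i]] <- ids[sample(pool, np)]
    }
  })
  new_ontology(ids, parents)
}

#' Generate a three-kingdom annotation corpus with planted structure
#'
#' Picks a shared core term module and one distinct module per kingdom.
#' Kingdom modules are planted in distinct branches of the ontology (terms
#' descending exclusively from one root-child each), mirroring how
#' taxon-specific biology occupies separate regions of a real process
#' ontology; the core module is drawn from the remaining terms.
#' Every species receives its own namespaced gene universe; each module
#' term is annotated to a dedicated block of genes, the remaining genes
#' carry 1-2 random background terms (plus an extra random term at the
#' configured noise rate). The species' query gene list mixes module genes
#' (core + own kingdom) at the configured signal fraction with uniform
#' background genes.
#'
#' @param cfg a `synth_config`.
#' @param g an `ontology` from [generate_dag()] (regenerated from `cfg`
#'   when omitted).
#' @return List with `corpus` (`annotation_corpus`), `gene_sets` (named
#'   list of `gene_set`s), `truth` (named kingdom labels), `modules`
#'   (list: `core`, `kingdoms`).
#' @export
generate_kingdom_corpus <- function(cfg = synth_config(), g = NULL) {
  if (is.null(g)) g <- generate_dag(cfg)
  kingdoms <- c("K1", "K2", "K3")
  need <- cfg$core_size + 3L * cfg$kingdom_size
  cand <- setdiff(g$terms, g$terms[g$root])
  if (length(cand) < need)
    stop_("module sizes exceed available non-root terms")
  # branch-exclusive term pools: terms whose only root-child ancestor is a
  # single branch anchor
  anc <- anc_sets(g)
  layer1 <- g$children[[g$root]]
  branch_anchors <- function() {
    excl <- lapply(layer1, function(b) {
      hit <- vapply(seq_len(g$n_terms), function(i)
        i != g$root && all(intersect(c(anc[[i]], i), layer1) == b),
        logical(1))
      g$terms[hit]
    })
    names(excl) <- g$terms[layer1]
    excl[order(-lengths(excl))]
  }
  excl <- branch_anchors()
  if (sum(lengths(excl) >= cfg$kingdom_size) < 3L)
    stop_("ontology lacks three branches with enough exclusive terms; ",
          "increase n_terms or reduce kingdom_size")
  with_seed(cfg$seed + 1L, {
    pools <- excl[lengths(excl) >= cfg$kingdom_size]
    chosen <- sample(names(pools), 3L)
    kmod <- lapply(chosen, function(b) sample(pools[[b]], cfg$kingdom_size))
    names(kmod) <- kingdoms
    # core terms must share no branch ancestry with the kingdom modules,
    # or their standardized mappings could collide with a kingdom signature
    chosen_idx <- term_index(g, chosen)
    untouched <- vapply(seq_len(g$n_terms), function(i)
      i != g$root && !any(chosen_idx %in% c(anc[[i]], i)), logical(1))
    core_pool <- g$terms[untouched]
    if (length(core_pool) < cfg$core_size)
      stop_("not enough terms outside the kingdom branches for the core")
    core <- sample(core_pool, cfg$core_size)
    species <- list(); queries <- list(); truth <- character()
    for (kg in kingdoms) {
      mod_terms <- c(core, kmod[[kg]])
      for (s in seq_len(cfg$n_species)) {
        sp <- sprintf("%s_sp%02d", kg, s)
        genes <- sprintf("%s_g%03d", sp, seq_len(cfg$n_genes))
        n_mod <- length(mod_terms) * cfg$genes_per_term
        if (n_mod >= cfg$n_genes)
          stop_("module gene blocks exceed the gene universe")
        g2t <- vector("list", cfg$n_genes)
        names(g2t) <- genes
        # dedicated module blocks
        for (m in seq_along(mod_terms)) {
          block <- ((m - 1L) * cfg$genes_per_term + 1L):(m * cfg$genes_per_term)
          for (b in block) g2t[[b]] <- mod_terms[m]
        }
        # background genes: 1-2 random terms (+ noise)
        for (b in (n_mod + 1L):cfg$n_genes) {
          g2t[[b]] <- sample(cand, sample(1:2, 1L))
        }
        noisy <- which(stats::runif(cfg$n_genes) < cfg$noise)
        for (b in noisy) g2t[[b]] <- unique(c(g2t[[b]], sample(cand, 1L)))
        species[[sp]] <- g2t
        # query: module genes at the signal fraction (allocated evenly
        # across module terms, as a species expresses each of its active
        # processes), background genes otherwise
        n_sig <- min(round(cfg$signal * cfg$query_size), n_mod)
        base <- n_sig %/% length(mod_terms)
        extra <- n_sig - base * length(mod_terms)
        takes <- rep(base, length(mod_terms))
        if (extra > 0L)
          takes[sample.int(length(mod_terms), extra)] <- base + 1L
        takes <- pmin(takes, cfg$genes_per_term)
        sig_genes <- unlist(lapply(seq_along(mod_terms), function(m) {
          block <- genes[((m - 1L) * cfg$genes_per_term + 1L):
                           (m * cfg$genes_per_term)]
          sample(block, takes[m])
        }), use.names = FALSE)
        q <- c(sig_genes,
               sample(genes[(n_mod + 1L):cfg$n_genes],
                      cfg$query_size - length(sig_genes)))
        queries[[sp]] <- gene_set(sp, q, label = "planted query")
        truth[sp] <- kg
      }
    }
  })
  list(corpus = annotation_corpus(species), gene_sets = queries,
       truth = truth, modules = list(core = core, kingdoms = kmod))
}

#' Write a synthetic corpus in the pipeline's input formats
#'
#' Emits the ontology as OBO, per-species 2-column annotation TSVs and
#' per-species gene-list files, readable by [load_obo()],
#' [load_annotations()] and [read_gene_list()].
#'
#' @param sim output of [generate_kingdom_corpus()].
#' @param g the `ontology` used.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(sim, g, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_obo(g, file.path(dir, "ontology.obo"))
  for (sp in names(sim$corpus$species)) {
    entry <- sim$corpus$species[[sp]]
    gene <- rep(names(entry$gene2terms), lengths(entry$gene2terms))
    term <- unlist(entry$gene2terms, use.names = FALSE)
    utils::write.table(data.frame(gene, term),
                       file.path(dir, paste0(sp, ".annotations.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    writeLines(sim$gene_sets[[sp]]$genes,
               file.path(dir, paste0(sp, ".genes.txt")))
  }
  utils::write.table(data.frame(species = names(sim$truth),
                                kingdom = sim$truth),
                     file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
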