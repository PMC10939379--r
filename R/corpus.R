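#' Load per-species gene-to-term annotations
#'
#' Accepts GAF 2.x files (17 tab-separated columns, comment lines starting
#' with `!`; rows with a `NOT` qualifier are skipped; gene = column 2, term
#' = column 5) or plain 2-column TSV files (gene, term). Duplicate pairs
#' are collapsed. Annotations to terms absent from the ontology are
#' dropped with a message when `g` is supplied.
#'
#' @param paths character vector of file paths, named by species id
#'   (unnamed entries use the file base name).
#' @param g optional `ontology` used to validate term ids.
#' @return An `annotation_corpus`: named list (per species) of
#'   `gene2terms` (named list: gene -> character terms) and `universe`
#'   (annotated genes).
#' @export
load_annotations <- function(paths, g = NULL) {
  nm <- names(paths) %||% rep("", length(paths))
  nm[nm == ""] <- sub("\\.[^.]*$", "", basename(paths[nm == ""]))
  species <- lapply(seq_along(paths), function(i)
    load_annotation_file(paths[[i]], g))
  names(species) <- nm
  structure(list(species = species), class = "annotation_corpus")
}

load_annotation_file <- function(path, g = NULL) {
  if (!file.exists(path)) stop_("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (!length(lines)) stop_("no usable annotation rows in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol1 <- length(fields[[1L]])
  is_gaf <- ncol1 >= 15L
  pairs <- lapply(fields, function(f) {
    if (is_gaf) {
      if (length(f) < 15L) return(NULL)              # malformed row
      if (grepl("(^|\\|)NOT($|\\|)", f[4L])) return(NULL)  # NOT qualifier
      c(f[2L], f[5L])
    } else {
      if (length(f) < 2L || !nzchar(f[1L]) || !nzchar(f[2L])) return(NULL)
      c(f[1L], f[2L])
    }
  })
  bad <- vapply(pairs, is.null, logical(1))
  if (any(bad)) message(sum(bad), " row(s) skipped in ", basename(path))
  pairs <- pairs[!bad]
  if (!length(pairs)) stop_("zero usable annotation rows in ", path)
  gene <- vapply(pairs, `[`, character(1), 1L)
  term <- vapply(pairs, `[`, character(1), 2L)
  keep <- !duplicated(paste0(gene, "\r", term))
  gene <- gene[keep]; term <- term[keep]
  if (!is.null(g)) {
    ok <- term %in% g$terms
    if (!all(ok)) {
      message(sum(!ok), " annotation(s) to unknown terms dropped in ",
              basename(path))
      gene <- gene[ok]; term <- term[ok]
    }
    if (!length(gene)) stop_("zero usable annotation rows in ", path)
  }
  annotation_species(split(term, gene))
}

annotation_species <- function(gene2terms) {
  gene2terms <- lapply(gene2terms, function(x) sort(unique(as.character(x))))
  list(gene2terms = gene2terms, universe = names(gene2terms))
}

#' Build a corpus directly from in-memory annotations
#'
#' @param species named list; each element a named list mapping gene id to
#'   a character vector of term ids.
#' @return An `annotation_corpus`.
#' @export
annotation_corpus <- function(species) {
  structure(list(species = lapply(species, annotation_species)),
            class = "annotation_corpus")
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat(sprintf("annotation corpus: %d species, %s genes (median)\n",
              length(x$species),
              stats::median(vapply(x$species, function(s)
                length(s$universe), numeric(1)))))
  invisible(x)
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' Closes every gene's term set under ancestors, excluding the root (a
#' gene annotated to a child of the root is unchanged). Idempotent.
#'
#' @param corpus an `annotation_corpus`.
#' @param g the `ontology` the terms live in.
#' @return The propagated `annotation_corpus`.
#' @export
propagate <- function(corpus, g) {
  stopifnot(inherits(corpus, "annotation_corpus"), inherits(g, "ontology"))
  anc <- anc_sets(g)
  root_id <- g$terms[g$root]
  corpus$species <- lapply(corpus$species, function(sp) {
    sp$gene2terms <- lapply(sp$gene2terms, function(terms) {
      i <- term_index(g, terms)
      up <- unlist(anc[i], use.names = FALSE)
      sort(unique(c(terms, setdiff(g$terms[up], root_id))))
    })
    sp
  })
  corpus
}

#' Read a plain-text gene list (one identifier per line)
#'
#' @param path file path; blank lines and `#` comments are skipped.
#' @param species species identifier to attach.
#' @param label provenance label (free text).
#' @return A `gene_set`: list with `species`, `genes`, `label`.
#' @export
read_gene_list <- function(path, species = sub("\\.[^.]*$", "", basename(path)),
                           label = "gene list") {
  lines <- trimws(readLines(path, warn = FALSE))
  genes <- lines[nzchar(lines) & !startsWith(lines, "#")]
  gene_set(species, genes, label)
}

#' @rdname read_gene_list
#' @param genes character vector of gene identifiers.
#' @export
gene_set <- function(species, genes, label = "gene list") {
  genes <- unique(as.character(genes))
  if (!length(genes)) stop_("empty gene set for species ", species)
  structure(list(species = species, genes = genes, label = label),
            class = "gene_set")
}

#' Species inclusion by annotation coverage
#'
#' Retains species whose gene set reaches at least `frac` of the reference
#' gene-set size (ties inclusive: `|genes| >= frac * |reference|`).
#'
#' @param sets list of `gene_set` objects.
#' @param reference a `gene_set` (typically the model-species seed list).
#' @param frac coverage fraction, default 0.75.
#' @return The retained subset of `sets`.
#' @export
coverage_filter <- function(sets, reference, frac = 0.75) {
  stopifnot(inherits(reference, "gene_set"), length(reference$genes) > 0)
  keep <- vapply(sets, function(s) length(s$genes) >=
                   frac * length(reference$genes), logical(1))
  sets[keep]
}
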