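#' Read an ontology from an OBO file
#'
#' Parses OBO 1.2/1.4 `[Term]` stanzas into an [new_ontology()] DAG.
#' Obsolete terms are dropped. Only the requested relation types become
#' edges; by default only `is_a`. Terms can be restricted to one namespace
#' (e.g. `biological_process`). Edges pointing at terms that are absent
#' after filtering are dropped with a warning.
#'
#' @param path OBO file path.
#' @param relations character vector of relation names to use as
#'   child-to-parent edges. `is_a` is always understood; other names
#'   (e.g. `part_of`) are matched against `relationship:` lines.
#' @param namespace optional namespace filter; terms whose `namespace:`
#'   differs are ignored.
#' @return An `ontology`.
#' @export
load_obo <- function(path, relations = "is_a", namespace = NULL) {
  if (!file.exists(path)) stop_("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  # strip trailing comments (unescaped '!')
  lines <- sub("\\s*!.*$", "", lines)
  lines <- trimws(lines)

  stanza_starts <- which(lines == "[Term]")
  if (length(stanza_starts) == 0L) stop_("no [Term] stanzas in ", path)
  bounds <- c(grep("^\\[.*\\]$", lines), length(lines) + 1L)

  ids <- character(); nms <- character(); pars <- list()
  keep_rel <- setdiff(relations, "is_a")
  use_isa <- "is_a" %in% relations

  for (s in stanza_starts) {
    e <- min(bounds[bounds > s]) - 1L
    block <- lines[s:e]
    gv <- function(key) sub(paste0("^", key, ":\\s*"), "",
                            grep(paste0("^", key, ":"), block, value = TRUE))
    id <- gv("id")[1]
    if (is.na(id) || !nzchar(id)) next
    if (length(gv("is_obsolete")) && any(gv("is_obsolete") == "true")) next
    ns <- gv("namespace")
    if (!is.null(namespace) && length(ns) && !any(ns == namespace)) next
    p <- character()
    if (use_isa) p <- c(p, vapply(gv("is_a"), function(x)
      strsplit(x, "\\s+")[[1]][1], character(1), USE.NAMES = FALSE))
    if (length(keep_rel)) {
      rel <- gv("relationship")
      for (r in rel) {
        f <- strsplit(r, "\\s+")[[1]]
        if (length(f) >= 2 && f[1] %in% keep_rel) p <- c(p, f[2])
      }
    }
    ids <- c(ids, id); nms <- c(nms, if (length(gv("name"))) gv("name")[1] else NA)
    pars <- c(pars, list(unique(p)))
  }
  if (!length(ids)) stop_("no usable terms parsed from ", path)
  if (anyDuplicated(ids)) {
    keep <- !duplicated(ids)
    ids <- ids[keep]; nms <- nms[keep]; pars <- pars[keep]
  }
  # drop edges to terms filtered out (other namespaces, obsolete)
  known <- ids
  dropped <- setdiff(unique(unlist(pars)), known)
  if (length(dropped)) {
    warn_("dropping ", length(dropped), " edge target(s) absent from the ",
          "loaded term set")
    pars <- lapply(pars, function(p) p[p %in% known])
  }
  new_ontology(ids, pars, nms)
}

#' Write an ontology as a minimal OBO file
#'
#' Emits one `[Term]` stanza per term with `is_a` links, readable back by
#' [load_obo()].
#'
#' @param g an `ontology`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_obo <- function(g, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(g$n_terms)) {
    writeLines("[Term]", con)
    writeLines(paste0("id: ", g$terms[i]), con)
    if (!is.na(g$names[i])) writeLines(paste0("name: ", g$names[i]), con)
    for (p in g$parents[[i]])
      writeLines(paste0("is_a: ", g$terms[p]), con)
    writeLines("", con)
  }
  invisible(path)
}
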