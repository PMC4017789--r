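#' Gene Ontology DAG container
#'
#' A `go_dag` holds one or more GO namespaces as a directed acyclic graph of
#' child-to-parent edges. Obsolete terms are excluded at load time and
#' `alt_id`s are resolved to primary identifiers. Each namespace is analyzed
#' independently: cross-namespace edges are dropped and every namespace has
#' its own root (the unique term without parents; for standard GO these are
#' GO:0003674, GO:0008150 and GO:0005575).
#'
#' @param ids character vector of term identifiers.
#' @param names character vector of term names (same length as `ids`).
#' @param namespaces character vector of namespaces, one per term.
#' @param parents named list: term id -> character vector of parent ids
#'   (within the same namespace). Missing entries mean "no parents".
#' @param alt named character vector mapping alternative ids to primary ids.
#'
#' @return An object of class `go_dag` with elements `id`, `name`,
#'   `namespace`, `parents`, `children`, `roots` (named list namespace ->
#'   root ids), `alt`, and a private cache of ancestor/descendant sets.
#' @export
go_dag <- function(ids, names = ids, namespaces = "molecular_function",
                   parents = list(), alt = character(0)) {
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop_domfun("duplicate term ids: ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  namespaces <- rep_len(as.character(namespaces), length(ids))
  names <- rep_len(as.character(names), length(ids))
  ns <- stats::setNames(namespaces, ids)

  par <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(ids)) par[[i]] <- character(0)
  for (tid in names(parents)) {
    if (!tid %in% ids) stop_domfun("parents listed for unknown term ", tid)
    p <- unique(as.character(parents[[tid]]))
    bad <- setdiff(p, ids)
    if (length(bad))
      stop_domfun("term ", tid, " references unknown parent(s): ",
                  paste(bad, collapse = ", "))
    # D3: cross-namespace edges are dropped
    p <- p[ns[p] == ns[tid]]
    par[[tid]] <- p
  }

  chl <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(ids)) chl[[i]] <- character(0)
  for (tid in ids) for (p in par[[tid]]) chl[[p]] <- c(chl[[p]], tid)

  topo <- topo_sort(ids, par)   # errors on cycles

  roots <- split(ids[lengths(par) == 0L], ns[ids[lengths(par) == 0L]])
  dag <- structure(
    list(id = ids, name = stats::setNames(names, ids), namespace = ns,
         parents = par, children = chl, roots = roots,
         alt = alt, cache = new.env(parent = emptyenv())),
    class = "go_dag")
  dag
}

# Kahn topological sort; parents before children. Errors on any cycle.
topo_sort <- function(ids, parents) {
  indeg <- lengths(parents)[ids]
  queue <- ids[indeg == 0L]
  out <- character(0)
  children <- stats::setNames(vector("list", length(ids)), ids)
  for (tid in ids) for (p in parents[[tid]])
    children[[p]] <- c(children[[p]], tid)
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]
    out <- c(out, t)
    for (ch in children[[t]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != length(ids))
    stop_domfun("ontology graph contains a cycle involving: ",
                paste(utils::head(setdiff(ids, out), 5L), collapse = ", "))
  out
}

#' @export
print.go_dag <- function(x, ...) {
  cat("GO DAG:", length(x$id), "terms,",
      sum(lengths(x$parents)), "edges\n")
  for (ns in names(x$roots))
    cat("  ", ns, ": root ", paste(x$roots[[ns]], collapse = ", "),
        " (", sum(x$namespace == ns), " terms)\n", sep = "")
  invisible(x)
}

#' Read a GO ontology from an OBO file
#'
#' Parses OBO 1.2/1.4 `[Term]` stanzas. Obsolete terms are dropped (their
#' count is reported when `getOption("domfun.verbose")` is TRUE), `alt_id`s
#' are recorded and resolved on lookup, and only edges with the requested
#' relation labels are kept. `is_a` is the conservative default; `part_of`
#' traversal is opt-in.
#'
#' @param path path to an OBO text file.
#' @param relations character vector of relation labels to keep as edges.
#' @return a [go_dag].
#' @export
read_obo <- function(path, relations = "is_a") {
  lines <- readLines(path, warn = FALSE)
  in_term <- FALSE
  cur <- NULL
  terms <- list()
  flush <- function(cur) { if (!is.null(cur) && !is.null(cur$id)) terms[[length(terms) + 1L]] <<- cur }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "") next
    if (startsWith(ln, "[")) {
      flush(cur); cur <- NULL
      in_term <- identical(ln, "[Term]")
      next
    }
    if (!in_term) next
    sep <- regexpr(":", ln, fixed = TRUE)
    if (sep < 0L)
      stop_domfun("malformed OBO stanza at line ", i, ": ", ln)
    key <- substr(ln, 1L, sep - 1L)
    val <- trimws(substr(ln, sep + 1L, nchar(ln)))
    val <- sub("\\s*!.*$", "", val)          # strip trailing comments
    if (is.null(cur)) cur <- list(parents = character(0), alt = character(0))
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_obsolete") cur$obsolete <- identical(val, "true")
    else if (key == "alt_id") cur$alt <- c(cur$alt, val)
    else if (key == "replaced_by") cur$replaced_by <- val
    else if (key == "is_a" && "is_a" %in% relations)
      cur$parents <- c(cur$parents, val)
    else if (key == "relationship") {
      parts <- strsplit(val, "\\s+")[[1L]]
      if (length(parts) >= 2L && parts[[1L]] %in% relations)
        cur$parents <- c(cur$parents, parts[[2L]])
    }
  }
  flush(cur)
  if (!length(terms)) stop_domfun("no [Term] stanzas found in ", path)

  obs <- vapply(terms, function(t) isTRUE(t$obsolete), logical(1))
  msg(sum(obs), " obsolete terms dropped")
  alt <- character(0)
  for (t in terms[!obs])
    if (length(t$alt)) alt[t$alt] <- t$id
  # replaced_by of obsolete terms also resolves to the replacement
  for (t in terms[obs])
    if (!is.null(t$replaced_by)) alt[t$id] <- t$replaced_by
  terms <- terms[!obs]

  ids <- vapply(terms, function(t) t$id, character(1))
  nms <- vapply(terms, function(t) t$name %||% t$id, character(1))
  nss <- vapply(terms, function(t) t$namespace %||% "molecular_function",
                character(1))
  parents <- stats::setNames(lapply(terms, function(t) {
    p <- unique(t$parents)
    # tolerate edges into obsolete terms only if the obsolete parent was
    # replaced; otherwise it is a dangling reference
    p <- unique(vapply(p, function(q) {
      if (q %in% ids) q
      else if (q %in% names(alt)) unname(alt[[q]])
      else q
    }, character(1), USE.NAMES = FALSE))
    bad <- setdiff(p, ids)
    if (length(bad))
      stop_domfun("term ", t$id, " references unknown parent(s): ",
                  paste(bad, collapse = ", "))
    p
  }), ids)
  go_dag(ids, nms, nss, parents, alt = alt)
}

# map an id through alt_id resolution and verify membership
resolve_term <- function(dag, term) {
  if (term %in% dag$id) return(term)
  hit <- dag$alt[term]
  if (length(hit) == 1L && !is.na(hit) && hit %in% dag$id) return(unname(hit))
  stop_domfun("unknown term id: ", term)
}

#' Ancestors of a GO term
#'
#' All terms reachable by following child-to-parent edges, excluding the term
#' itself. Under the true path rule every annotation to a term implies all of
#' its ancestors up to the namespace root.
#'
#' @param dag a [go_dag].
#' @param term a term id.
#' @return character vector of ancestor term ids (empty for a root).
#' @export
ancestors <- function(dag, term) {
  term <- resolve_term(dag, term)
  anc_table(dag)[[term]]
}

# memoized all-ancestor table, computed in one topological pass
anc_table <- function(dag) {
  cache <- dag$cache
  if (!is.null(cache$anc)) return(cache$anc)
  topo <- topo_sort(dag$id, dag$parents)
  anc <- stats::setNames(vector("list", length(dag$id)), dag$id)
  for (t in topo) {
    p <- dag$parents[[t]]
    anc[[t]] <- if (!length(p)) character(0)
                else unique(c(p, unlist(anc[p], use.names = FALSE)))
  }
  cache$anc <- anc
  anc
}

# memoized descendant sets (self-inclusive), reverse topological pass
desc_table <- function(dag) {
  cache <- dag$cache
  if (!is.null(cache$desc)) return(cache$desc)
  topo <- rev(topo_sort(dag$id, dag$parents))
  desc <- stats::setNames(vector("list", length(dag$id)), dag$id)
  for (t in topo) {
    ch <- dag$children[[t]]
    desc[[t]] <- if (!length(ch)) t
                 else unique(c(t, unlist(desc[ch], use.names = FALSE)))
  }
  cache$desc <- desc
  desc
}

#' Descendant count of a GO term (semantic coverage)
#'
#' Size of the set of terms reachable downward from `term`, including the
#' term itself, so a leaf counts 1 and counts never decrease toward the root.
#' The self-inclusive convention keeps the semantic-coverage ratio used by
#' [extend_mapping()] well defined for leaf terms.
#'
#' @inheritParams ancestors
#' @return a positive integer.
#' @export
descendant_count <- function(dag, term) {
  term <- resolve_term(dag, term)
  length(desc_table(dag)[[term]])
}

#' True-path extension of a term set
#'
#' Unites a set of terms with all ancestors of every member. Idempotent and
#' monotone in the input set.
#'
#' @param dag a [go_dag].
#' @param terms character vector of term ids.
#' @return character vector: `terms` plus all their ancestors.
#' @export
true_path_extend <- function(dag, terms) {
  if (!length(terms)) return(character(0))
  terms <- vapply(terms, resolve_term, character(1), dag = dag,
                  USE.NAMES = FALSE)
  anc <- anc_table(dag)
  unique(c(terms, unlist(anc[terms], use.names = FALSE)))
}

#' Namespace root of a GO DAG
#'
#' @param dag a [go_dag].
#' @param namespace one of the namespaces present in `dag`.
#' @return the root term id (the unique parentless term of the namespace).
#' @export
go_root <- function(dag, namespace) {
  r <- dag$roots[[namespace]]
  if (is.null(r)) stop_domfun("namespace not in ontology: ", namespace)
  if (length(r) != 1L)
    stop_domfun("namespace ", namespace, " has ", length(r),
                " parentless terms; a unique root is required")
  r
}

#' Write a GO DAG as an OBO 1.2 file
#'
#' Serializes the terms of a [go_dag] with `is_a` edges only, producing a
#' file that [read_obo()] loads back to an isomorphic DAG.
#'
#' @param dag a [go_dag].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in dag$id) {
    writeLines(c("[Term]",
                 paste0("id: ", t),
                 paste0("name: ", dag$name[[t]]),
                 paste0("namespace: ", dag$namespace[[t]]),
                 if (length(dag$parents[[t]]))
                   paste0("is_a: ", dag$parents[[t]]),
                 ""), con)
  }
  invisible(path)
}
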