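# synthetic ground-truthed corpora: ontology + planted domain-term
# associations + proteins, so every stage is testable without downloads

ns_offset <- c(molecular_function = 1000000L,
               biological_process = 2000000L,
               cellular_component = 3000000L)

#' Simulate a single-rooted GO-like DAG
#'
#' Terms are added in order; the first is the namespace root and every later
#' term picks 1 to `max_parents` parents uniformly among the earlier terms,
#' so the graph is acyclic by construction and serializes to valid OBO.
#'
#' @param n_terms number of terms (>= 1).
#' @param max_parents maximum parents per non-root term.
#' @param namespace GO namespace label for all terms.
#' @param seed optional integer seed (caller's RNG state preserved).
#' @return a [go_dag].
#' @export
simulate_dag <- function(n_terms, max_parents = 2L,
                         namespace = "molecular_function", seed = NULL) {
  if (!is.numeric(n_terms) || n_terms < 1L)
    stop_domfun("n_terms must be >= 1")
  if (!is.numeric(max_parents) || max_parents < 1L)
    stop_domfun("max_parents must be >= 1")
  off <- ns_offset[namespace]
  if (is.na(off)) off <- 4000000L
  ids <- sprintf("GO:%07d", off + seq_len(n_terms))
  parents <- with_seed(seed, {
    p <- stats::setNames(vector("list", n_terms), ids)
    for (i in seq_len(n_terms)) {
      p[[i]] <- if (i == 1L) character(0) else {
        k <- sample.int(min(max_parents, i - 1L), 1L)
        ids[sample.int(i - 1L, k)]
      }
    }
    p
  })
  go_dag(ids, names = paste0("synthetic term ", seq_len(n_terms)),
         namespaces = namespace, parents = parents)
}

#' Simulate a ground-truthed annotation corpus
#'
#' Generates an ontology, plants `assoc_per_domain` "true" GO terms on each
#' domain (drawn uniformly without replacement), gives every protein a random
#' domain set, and derives its clean annotations as the union of the planted
#' terms of its domains — the generative assumption that resident domains
#' carry the host protein's functions. Observed annotations are the clean
#' ones corrupted by the two failure modes of real annotation corpora:
#' independent per-term dropout (a true term omitted with probability
#' `dropout`) and spurious addition (with probability `spurious` a protein
#' gains one uniformly random term). Everything is reproducible under `seed`.
#'
#' Defaults mirror the reference recovery experiment: 200 terms, 30 domains,
#' 3 associations per domain, 300 proteins, 1-3 domains per protein,
#' zero noise.
#'
#' @param n_terms terms in the namespace.
#' @param max_parents maximum parents per term in the simulated DAG.
#' @param n_domains number of domains.
#' @param assoc_per_domain planted terms per domain.
#' @param n_proteins number of proteins.
#' @param domains_per_protein length-2 integer range (min, max) of resident
#'   domains per protein, drawn uniformly.
#' @param dropout per-term probability that a true annotation is omitted.
#' @param spurious per-protein probability of gaining one random term.
#' @param namespace GO namespace label.
#' @param seed optional integer seed (caller's RNG state preserved).
#' @return an object of class `synthetic_corpus`: list with `ontology`
#'   ([go_dag]), `planted` (data.frame domain, term), `domains`,
#'   `annotations` (observed, noisy), `truth` (clean) and `config`.
#' @export
simulate_corpus <- function(n_terms = 200L, max_parents = 2L,
                            n_domains = 30L, assoc_per_domain = 3L,
                            n_proteins = 300L,
                            domains_per_protein = c(1L, 3L),
                            dropout = 0, spurious = 0,
                            namespace = "molecular_function", seed = NULL) {
  if (assoc_per_domain > n_terms)
    stop_domfun("assoc_per_domain (", assoc_per_domain,
                ") exceeds n_terms (", n_terms, ")")
  if (dropout < 0 || dropout > 1 || spurious < 0 || spurious > 1)
    stop_domfun("dropout and spurious must be rates in [0, 1]")
  if (length(domains_per_protein) != 2L ||
      domains_per_protein[1L] < 1L ||
      domains_per_protein[2L] < domains_per_protein[1L] ||
      domains_per_protein[2L] > n_domains)
    stop_domfun("domains_per_protein must be a valid (min, max) range")

  with_seed(seed, {
    dag <- simulate_dag(n_terms, max_parents, namespace, seed = NULL)
    dom_ids <- sprintf("PF%05d", seq_len(n_domains))
    planted <- stats::setNames(lapply(dom_ids, function(d)
      sample(dag$id, assoc_per_domain)), dom_ids)

    prot_ids <- sprintf("P%04d", seq_len(n_proteins))
    sizes <- sample(seq(domains_per_protein[1L], domains_per_protein[2L]),
                    n_proteins, replace = TRUE)
    domains <- stats::setNames(lapply(sizes, function(k)
      sample(dom_ids, k)), prot_ids)

    truth <- lapply(domains, function(d)
      unique(unlist(planted[d], use.names = FALSE)))

    observed <- lapply(prot_ids, function(p) {
      g <- truth[[p]]
      g <- g[stats::runif(length(g)) >= dropout]
      if (spurious > 0 && stats::runif(1L) < spurious)
        g <- unique(c(g, sample(dag$id, 1L)))
      g
    })
    names(observed) <- prot_ids
    observed <- observed[lengths(observed) > 0L]

    structure(list(
      ontology = dag,
      planted = data.frame(
        domain = rep(dom_ids, each = assoc_per_domain),
        term = unlist(planted, use.names = FALSE),
        stringsAsFactors = FALSE),
      domains = domains,
      annotations = observed,
      truth = truth,
      config = list(n_terms = n_terms, max_parents = max_parents,
                    n_domains = n_domains,
                    assoc_per_domain = assoc_per_domain,
                    n_proteins = n_proteins,
                    domains_per_protein = domains_per_protein,
                    dropout = dropout, spurious = spurious,
                    namespace = namespace, seed = seed)),
      class = "synthetic_corpus")
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cfg <- x$config
  cat("synthetic corpus (", cfg$namespace, "): ", cfg$n_terms, " terms, ",
      cfg$n_domains, " domains (", cfg$assoc_per_domain,
      " planted terms each), ", cfg$n_proteins, " proteins\n", sep = "")
  cat("  noise: dropout = ", cfg$dropout, ", spurious = ", cfg$spurious,
      "; ", length(x$annotations), " proteins observed annotated\n", sep = "")
  invisible(x)
}

#' Write a synthetic corpus as plain-text fixture files
#'
#' Emits `go.obo`, `truth.gaf`, `observed.gaf`, `domains.tsv` and
#' `planted_map.tsv` into a directory; reloading through [read_obo()],
#' [read_gaf()] and [read_domains()] reproduces the in-memory corpus.
#'
#' @param corpus a `synthetic_corpus`.
#' @param dir output directory (created if missing).
#' @return named character vector of the file paths, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(obo = file.path(dir, "go.obo"),
             truth = file.path(dir, "truth.gaf"),
             observed = file.path(dir, "observed.gaf"),
             domains = file.path(dir, "domains.tsv"),
             planted = file.path(dir, "planted_map.tsv"))
  write_obo(corpus$ontology, paths[["obo"]])
  truth <- corpus$truth[lengths(corpus$truth) > 0L]
  write_gaf(truth, paths[["truth"]], dag = corpus$ontology)
  write_gaf(corpus$annotations, paths[["observed"]], dag = corpus$ontology)
  write_domains(corpus$domains, paths[["domains"]])
  utils::write.table(corpus$planted, paths[["planted"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
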