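# weighted domain <-> GO-term mapping: sparse (domain, term, score) triples

new_domain_go_map <- function(domain, term, score, method, extension = "none") {
  stopifnot(length(domain) == length(term), length(term) == length(score))
  structure(
    data.frame(domain = as.character(domain), term = as.character(term),
               score = as.numeric(score), stringsAsFactors = FALSE),
    method = method, extension = extension,
    class = c("domain_go_map", "data.frame"))
}

#' @export
print.domain_go_map <- function(x, ...) {
  cat("domain-GO mapping: ", nrow(x), " pairs, ",
      length(unique(x$domain)), " domains, ",
      length(unique(x$term)), " terms\n",
      "  weighting: ", attr(x, "method"),
      ", extension: ", attr(x, "extension"), "\n", sep = "")
  if (nrow(x)) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

#' Count protein-level co-occurrences of domains and GO terms
#'
#' The counting universe is the set of proteins present in *both* the
#' annotation set and the domain composition with at least one (directly
#' assigned) annotation in the requested namespace: conditional
#' probabilities are meaningless for proteins that cannot co-occur.
#' Annotations are counted as directly assigned, without true-path
#' propagation — the hierarchy is applied afterwards, by [extend_mapping()];
#' extending before counting would apply it twice.
#'
#' @param annotations named list: protein -> GO term ids (direct assignments).
#' @param domains named list: protein -> domain accessions.
#' @param dag a [go_dag].
#' @param namespace GO namespace to count in.
#' @return an object of class `cooc_counts`: list with `pairs` (data.frame
#'   domain, term, n_both), `n_dom` (named integer), `n_term` (named
#'   integer), `n_proteins` (universe size N) and `namespace`.
#' @export
count_cooccurrence <- function(annotations, domains, dag,
                               namespace = "molecular_function") {
  check_named_sets(annotations, "annotations")
  check_named_sets(domains, "domains")
  ns_terms <- dag$id[dag$namespace == namespace]
  ann <- lapply(annotations, function(g) {
    g <- vapply(g, resolve_term, character(1), dag = dag, USE.NAMES = FALSE)
    intersect(g, ns_terms)
  })
  ann <- ann[lengths(ann) > 0L]
  universe <- intersect(names(ann), names(domains))
  if (!length(universe))
    stop_domfun("no co-annotated proteins: the annotation set and domain ",
                "composition share no protein with annotations in ", namespace)
  ann <- ann[universe]
  dom <- domains[universe]

  # long table of (protein, domain) x (protein, term) joined on protein
  nd <- lengths(dom); nt <- lengths(ann)
  d_long <- unlist(dom, use.names = FALSE)
  t_long <- unlist(ann, use.names = FALSE)
  pair_d <- rep(d_long, times = rep(nt, times = nd))
  pair_t <- unlist(lapply(seq_along(universe), function(i)
    rep(ann[[i]], times = nd[[i]])), use.names = FALSE)
  key <- paste(pair_d, pair_t, sep = "\r")
  tab <- table(key)
  dt <- strsplit(names(tab), "\r", fixed = TRUE)
  pairs <- data.frame(domain = vapply(dt, `[[`, character(1), 1L),
                      term = vapply(dt, `[[`, character(1), 2L),
                      n_both = as.integer(tab), stringsAsFactors = FALSE,
                      row.names = NULL)
  structure(list(pairs = pairs,
                 n_dom = table_int(d_long),
                 n_term = table_int(t_long),
                 n_proteins = length(universe),
                 namespace = namespace),
            class = "cooc_counts")
}

table_int <- function(x) {
  tab <- table(x)
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.cooc_counts <- function(x, ...) {
  cat("co-occurrence counts (", x$namespace, "): N = ", x$n_proteins,
      " proteins, ", length(x$n_dom), " domains, ", length(x$n_term),
      " terms, ", nrow(x$pairs), " co-occurring pairs\n", sep = "")
  invisible(x)
}

check_counts <- function(counts) {
  stopifnot(inherits(counts, "cooc_counts"))
  p <- counts$pairs
  nd <- counts$n_dom[p$domain]; nt <- counts$n_term[p$term]
  if (any(is.na(nd)) || any(is.na(nt)) || any(nd == 0L) || any(nt == 0L))
    stop_domfun("inconsistent counts: a co-occurring pair has a zero margin")
  if (any(p$n_both > pmin(nd, nt)) || any(p$n_both < 0L))
    stop_domfun("inconsistent counts: n_both outside [0, min(n_dom, n_term)]")
  invisible(counts)
}

#' Relevance of domain-term pairs by symmetrical conditional probability
#'
#' The relevance of GO term g and domain d is the product of the two
#' conditional probabilities Pr(g | d) and Pr(d | g), estimated from protein
#' counts as `n_both^2 / (n_dom * n_term)`. Scores lie in (0, 1]; pairs that
#' never co-occur are not materialized.
#'
#' @param counts a `cooc_counts` from [count_cooccurrence()].
#' @return a `domain_go_map` with method `"scp"`.
#' @export
relevance_scp <- function(counts) {
  check_counts(counts)
  p <- counts$pairs[counts$pairs$n_both > 0L, , drop = FALSE]
  score <- p$n_both^2 /
    (as.numeric(counts$n_dom[p$domain]) * as.numeric(counts$n_term[p$term]))
  new_domain_go_map(p$domain, p$term, score, method = "scp")
}

#' Relevance by plain (one-directional) conditional probability
#'
#' The comparison weighting: `n_both / n_dom` for the default
#' `term_given_domain` direction (probability that a protein containing the
#' domain carries the term), or `n_both / n_term` for `domain_given_term`.
#' The product of the two directions equals the symmetrical conditional
#' probability.
#'
#' @inheritParams relevance_scp
#' @param direction `"term_given_domain"` (default) or `"domain_given_term"`.
#' @return a `domain_go_map` with method `"cp"`.
#' @export
relevance_cp <- function(counts,
                         direction = c("term_given_domain",
                                       "domain_given_term")) {
  direction <- match.arg(direction)
  check_counts(counts)
  p <- counts$pairs[counts$pairs$n_both > 0L, , drop = FALSE]
  denom <- if (direction == "term_given_domain")
    as.numeric(counts$n_dom[p$domain]) else as.numeric(counts$n_term[p$term])
  new_domain_go_map(p$domain, p$term, p$n_both / denom, method = "cp")
}

#' Relevance by hypergeometric over-representation P-value
#'
#' Scores each co-occurring pair by `-log10` of the one-sided hypergeometric
#' upper-tail probability of observing at least `n_both` proteins carrying
#' both the domain and the term, when `n_dom` proteins are drawn from a
#' universe of N containing `n_term` annotated ones. Larger means a stronger
#' association. This mirrors the P-value weighting used by enrichment-style
#' domain annotators and is provided for comparison only; its scores are not
#' probabilities and exceed 1 freely.
#'
#' @inheritParams relevance_scp
#' @return a `domain_go_map` with method `"pv"`.
#' @export
relevance_pvalue <- function(counts) {
  check_counts(counts)
  p <- counts$pairs[counts$pairs$n_both > 0L, , drop = FALSE]
  nd <- as.numeric(counts$n_dom[p$domain])
  nt <- as.numeric(counts$n_term[p$term])
  # P(X >= n_both), X ~ Hypergeometric(N, n_term successes, n_dom draws)
  pv <- stats::phyper(p$n_both - 1L, nt, counts$n_proteins - nt, nd,
                      lower.tail = FALSE)
  new_domain_go_map(p$domain, p$term, -log10(pmax(pv, .Machine$double.xmin)),
                    method = "pv")
}
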