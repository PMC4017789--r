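#' Extend a weighted mapping along GO true paths
#'
#' Every (domain, term) pair with relevance s contributes a candidate score
#' to each ancestor of the term. Under the semantic-coverage strategy
#' (`"rsc"`) the candidate at ancestor a of seed term g is
#' `s * |D(a)| / |D(g)|`, where |D()| is the self-inclusive descendant count:
#' an ancestor has broader semantic coverage, so along any true path the
#' relevance grows toward the root. Under the equal-relevance strategy
#' (`"rpe"`) the candidate is simply s. When an ancestor receives candidates
#' from several seed terms of the same domain (or is itself a seed), the
#' maximum wins — consistent with the max-over-domains transfer rule at the
#' protein level. Propagated coverage-scaled scores may exceed 1; the
#' root normalization applied at prediction time restores the \[0, 1\] scale.
#'
#' @param mapping an unextended `domain_go_map`.
#' @param dag a [go_dag] containing every mapped term.
#' @param strategy `"rsc"` (coverage-scaled, default) or `"rpe"` (equal).
#' @return a `domain_go_map` whose `extension` attribute records the
#'   strategy; contains every seed pair plus all (domain, ancestor) pairs.
#' @export
extend_mapping <- function(mapping, dag, strategy = c("rsc", "rpe")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(mapping, "domain_go_map"))
  if (!identical(attr(mapping, "extension"), "none"))
    stop_domfun("mapping is already extended (", attr(mapping, "extension"), ")")
  bad <- setdiff(unique(mapping$term), dag$id)
  if (length(bad))
    stop_domfun("mapped term(s) absent from ontology: ",
                paste(utils::head(bad, 5L), collapse = ", "))
  if (!nrow(mapping))
    return(new_domain_go_map(character(0), character(0), numeric(0),
                             method = attr(mapping, "method"),
                             extension = strategy))

  anc <- anc_table(dag)
  n_anc <- lengths(anc)[mapping$term]
  dcount <- lengths(desc_table(dag))

  # one candidate row per (seed pair, ancestor), plus the seeds themselves
  cand_dom <- c(mapping$domain, rep(mapping$domain, times = n_anc))
  cand_term <- c(mapping$term,
                 unlist(anc[mapping$term], use.names = FALSE))
  seed_score <- rep(mapping$score, times = n_anc)
  cand_score <- c(mapping$score,
                  if (strategy == "rsc") {
                    seed_term <- rep(mapping$term, times = n_anc)
                    seed_score * dcount[cand_term[-seq_len(nrow(mapping))]] /
                      dcount[seed_term]
                  } else seed_score)

  key <- paste(cand_dom, cand_term, sep = "\r")
  best <- tapply(cand_score, key, max)
  dt <- strsplit(names(best), "\r", fixed = TRUE)
  new_domain_go_map(vapply(dt, `[[`, character(1), 1L),
                    vapply(dt, `[[`, character(1), 2L),
                    as.numeric(best),
                    method = attr(mapping, "method"),
                    extension = strategy)
}
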