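#' Prediction set container
#'
#' Holds root-normalized relevance scores per protein: a named list mapping
#' protein id to a named numeric vector of term scores in \[0, 1\], with the
#' namespace root always scoring 1 for every scored protein.
#'
#' @param scores named list: protein -> named numeric vector (term -> score).
#' @param namespace GO namespace tag.
#' @return an object of class `prediction_set`.
#' @export
prediction_set <- function(scores, namespace = "molecular_function") {
  stopifnot(is.list(scores))
  structure(list(scores = scores, namespace = namespace),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  n_terms <- sum(lengths(x$scores))
  cat("prediction set (", x$namespace, "): ", length(x$scores),
      " proteins, ", n_terms, " scored (protein, term) pairs\n", sep = "")
  invisible(x)
}

#' Protein-level relevance: maximum over resident domains
#'
#' A protein inherits every term associated with any of its resident domains;
#' the relevance of protein P and term g is the maximum of the domain-term
#' relevances over the domains P contains. Terms reached by no resident
#' domain are absent (an empty result is legal when no domain is mapped).
#'
#' @param mapping a `domain_go_map` (normally extended).
#' @param domains character vector of the protein's domain accessions.
#' @return named numeric vector: term -> raw relevance PR.
#' @export
protein_relevance <- function(mapping, domains) {
  stopifnot(inherits(mapping, "domain_go_map"), length(domains) > 0L)
  rows <- mapping$domain %in% domains
  if (!any(rows)) return(stats::setNames(numeric(0), character(0)))
  sc <- tapply(mapping$score[rows], mapping$term[rows], max)
  stats::setNames(as.numeric(sc), names(sc))
}

#' Normalize protein relevance against the subontology root
#'
#' Real annotations descend from the namespace root, so the relevance of the
#' root term is the natural baseline: NPR(g) = PR(g) / PR(root). After
#' extension the root carries the largest relevance of every domain's chains,
#' so all normalized scores lie in (0, 1] with NPR(root) = 1. A protein
#' whose raw scores lack the root (or score it 0) cannot be normalized and
#' yields NULL with a warning.
#'
#' @param pr named numeric vector of raw relevances (from
#'   [protein_relevance()]).
#' @param dag a [go_dag].
#' @param namespace the namespace whose root is the baseline.
#' @return named numeric vector of normalized scores, or NULL if degenerate.
#' @export
normalize_relevance <- function(pr, dag, namespace = "molecular_function") {
  root <- go_root(dag, namespace)
  base <- pr[root]
  if (length(base) != 1L || is.na(base) || base <= 0) {
    warning("protein skipped: no positive relevance on root ", root,
            call. = FALSE)
    return(NULL)
  }
  pr / as.numeric(base)
}

#' Threshold a prediction set into annotation sets
#'
#' P_t(x) is the set of terms whose normalized relevance with protein x is at
#' least t. The comparison is inclusive, so t = 0 returns every scored term
#' and t = 1 keeps the root and any other score of exactly 1; predicted sets
#' shrink monotonically as t grows.
#'
#' @param preds a [prediction_set].
#' @param t threshold in \[0, 1\].
#' @return named list: protein -> character vector of predicted term ids
#'   (possibly empty).
#' @export
threshold_predictions <- function(preds, t) {
  stopifnot(inherits(preds, "prediction_set"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0 || t > 1)
    stop_domfun("threshold t must be a single number in [0, 1]")
  lapply(preds$scores, function(sc) names(sc)[sc >= t])
}

#' Fit a weighted domain-to-GO-term annotation model
#'
#' Mines a domain-to-term mapping from the proteins present in both the
#' annotation set and the domain composition: co-occurrences are counted on
#' directly assigned annotations, weighted by the chosen relevance measure,
#' and extended along GO true paths. The fitted object predicts GO
#' annotations for any protein from its domain composition alone via
#' [predict.domfun()].
#'
#' The full method is `method = "scp"` with `extension = "rsc"`: symmetrical
#' conditional probability weighting combined with semantic-coverage
#' propagation. `extension = "rpe"` gives the classical equal-relevance
#' true-path transfer, and `extension = "none"` leaves the raw mapping
#' (predictions then cannot be root-normalized).
#'
#' @param annotations named list: protein -> directly assigned GO term ids.
#' @param domains named list: protein -> domain accessions.
#' @param ontology a [go_dag].
#' @param namespace GO namespace to model.
#' @param method relevance weighting: `"scp"` (symmetrical conditional
#'   probability, default), `"cp"` (plain conditional probability) or `"pv"`
#'   (hypergeometric P-value, comparison only).
#' @param extension true-path extension strategy: `"rsc"` (semantic
#'   coverage, default), `"rpe"` (equal relevance) or `"none"`.
#' @param direction conditional-probability direction when `method = "cp"`.
#' @return an object of class `domfun`: list with the raw `mapping`, the
#'   `extended` mapping, the co-occurrence `counts`, the `ontology`,
#'   `namespace`, `root`, `method`, `extension` and the `call`.
#' @seealso [predict.domfun()], [evaluate_predictions()], [simulate_corpus()]
#' @examples
#' corpus <- simulate_corpus(n_terms = 40, n_domains = 8, n_proteins = 60,
#'                           seed = 1)
#' fit <- domfun(corpus$annotations, corpus$domains, corpus$ontology)
#' fit
#' pred <- predict(fit, corpus$domains)
#' head(threshold_predictions(pred, 0.65)[[1]])
#' @export
domfun <- function(annotations, domains, ontology,
                   namespace = "molecular_function",
                   method = c("scp", "cp", "pv"),
                   extension = c("rsc", "rpe", "none"),
                   direction = "term_given_domain") {
  method <- match.arg(method)
  extension <- match.arg(extension)
  counts <- count_cooccurrence(annotations, domains, ontology, namespace)
  mapping <- switch(method,
                    scp = relevance_scp(counts),
                    cp = relevance_cp(counts, direction),
                    pv = relevance_pvalue(counts))
  extended <- if (extension == "none") mapping
              else extend_mapping(mapping, ontology, extension)
  structure(list(call = match.call(), mapping = mapping, extended = extended,
                 counts = counts, ontology = ontology, namespace = namespace,
                 root = go_root(ontology, namespace),
                 method = method, extension = extension),
            class = "domfun")
}

#' Build a prediction model from an unweighted pfam2go-style mapping
#'
#' The baseline predictor: every term curated for a domain gets relevance 1,
#' and the mapping is true-path-extended at relevance 1, so every term of a
#' resident domain (and all its ancestors) is predicted with full confidence.
#'
#' @param pairs data.frame with columns `domain` and `term` (see
#'   [read_pfam2go()]).
#' @param ontology a [go_dag].
#' @param namespace GO namespace to keep.
#' @return a `domfun` object with method `"pfam2go"`.
#' @export
domfun_pfam2go <- function(pairs, ontology,
                           namespace = "molecular_function") {
  stopifnot(is.data.frame(pairs), all(c("domain", "term") %in% names(pairs)))
  terms <- vapply(as.character(pairs$term), resolve_term, character(1),
                  dag = ontology, USE.NAMES = FALSE)
  keep <- ontology$namespace[terms] == namespace
  mapping <- new_domain_go_map(as.character(pairs$domain)[keep], terms[keep],
                               rep(1, sum(keep)), method = "pfam2go")
  extended <- extend_mapping(mapping, ontology, "rpe")
  attr(extended, "method") <- "pfam2go"
  structure(list(call = match.call(), mapping = mapping, extended = extended,
                 counts = NULL, ontology = ontology, namespace = namespace,
                 root = go_root(ontology, namespace),
                 method = "pfam2go", extension = "rpe"),
            class = "domfun")
}

#' Predict GO annotations from domain compositions
#'
#' Transfers the fitted (extended) domain-term relevances to each protein by
#' a maximum over its resident domains, then normalizes against the namespace
#' root so scores land in (0, 1]. Proteins with no mapped domain, or whose
#' relevance chain misses the root (only possible with
#' `extension = "none"`), are skipped with a warning.
#'
#' @param object a fitted [domfun] model.
#' @param newdata named list: protein -> domain accessions.
#' @param threshold optional; when given, returns the thresholded annotation
#'   sets instead of scores.
#' @param ... unused.
#' @return a [prediction_set], or (with `threshold`) a named list of
#'   predicted term-id vectors.
#' @export
predict.domfun <- function(object, newdata, threshold = NULL, ...) {
  check_named_sets(newdata, "newdata")
  ext <- object$extended
  # index the mapping by domain once; per-protein max is then a small merge
  by_dom <- split(seq_len(nrow(ext)), ext$domain)
  scores <- vector("list", length(newdata))
  names(scores) <- names(newdata)
  skipped <- 0L
  for (p in names(newdata)) {
    rows <- unlist(by_dom[intersect(newdata[[p]], names(by_dom))],
                   use.names = FALSE)
    if (!length(rows)) { skipped <- skipped + 1L; next }
    pr <- tapply(ext$score[rows], ext$term[rows], max)
    pr <- stats::setNames(as.numeric(pr), names(pr))
    npr <- normalize_relevance(pr, object$ontology, object$namespace)
    if (is.null(npr)) { skipped <- skipped + 1L; next }
    scores[[p]] <- npr
  }
  scores <- scores[!vapply(scores, is.null, logical(1))]
  msg(skipped, " proteins without usable domain mapping skipped")
  preds <- prediction_set(scores, object$namespace)
  if (is.null(threshold)) preds else threshold_predictions(preds, threshold)
}

#' One-call ablation predictor
#'
#' Runs one of the three prediction modes end to end on a corpus:
#' `"combine"` (symmetrical conditional probability weighting with
#' semantic-coverage extension — the full method), `"weighted"` (the same
#' weighting with equal-relevance extension) and `"pfam2go"` (the unweighted
#' curated mapping transferred at relevance 1).
#'
#' @param mode one of `"pfam2go"`, `"weighted"`, `"combine"`.
#' @param domains named list: protein -> domain accessions (targets).
#' @param ontology a [go_dag].
#' @param annotations training annotations; required for `"weighted"` and
#'   `"combine"`.
#' @param pfam2go data.frame of curated (domain, term) pairs; required for
#'   `"pfam2go"`.
#' @param namespace GO namespace.
#' @param threshold optional threshold passed to [predict.domfun()].
#' @return as [predict.domfun()].
#' @export
domfun_predict <- function(mode = c("combine", "weighted", "pfam2go"),
                           domains, ontology, annotations = NULL,
                           pfam2go = NULL,
                           namespace = "molecular_function",
                           threshold = NULL) {
  mode <- match.arg(mode)
  fit <- switch(mode,
    pfam2go = {
      if (is.null(pfam2go))
        stop_domfun("mode 'pfam2go' requires the 'pfam2go' mapping argument")
      domfun_pfam2go(pfam2go, ontology, namespace)
    },
    weighted = {
      if (is.null(annotations))
        stop_domfun("mode 'weighted' requires the 'annotations' argument")
      domfun(annotations, domains, ontology, namespace,
             method = "scp", extension = "rpe")
    },
    combine = {
      if (is.null(annotations))
        stop_domfun("mode 'combine' requires the 'annotations' argument")
      domfun(annotations, domains, ontology, namespace,
             method = "scp", extension = "rsc")
    })
  predict(fit, domains, threshold = threshold)
}

#' @export
print.domfun <- function(x, ...) {
  cat("Domain-based GO annotation model (", x$namespace, ")\n", sep = "")
  cat("  weighting: ", x$method, ", extension: ", x$extension, "\n", sep = "")
  if (!is.null(x$counts))
    cat("  trained on ", x$counts$n_proteins, " proteins (",
        length(x$counts$n_dom), " domains, ", length(x$counts$n_term),
        " terms)\n", sep = "")
  cat("  mapping: ", nrow(x$mapping), " weighted pairs, ",
      nrow(x$extended), " after true-path extension\n", sep = "")
  invisible(x)
}

#' @export
summary.domfun <- function(object, ...) {
  s <- list(call = object$call, method = object$method,
            extension = object$extension, namespace = object$namespace,
            n_pairs = nrow(object$mapping),
            n_extended = nrow(object$extended),
            n_domains = length(unique(object$mapping$domain)),
            n_terms = length(unique(object$mapping$term)),
            n_proteins = if (is.null(object$counts)) NA_integer_
                         else object$counts$n_proteins,
            score_quantiles = stats::quantile(object$mapping$score,
                                              c(0, .25, .5, .75, 1)))
  class(s) <- "summary.domfun"
  s
}

#' @export
print.summary.domfun <- function(x, ...) {
  cat("Domain-based GO annotation model\n\nCall: ")
  print(x$call)
  cat("\nNamespace: ", x$namespace, "   weighting: ", x$method,
      "   extension: ", x$extension, "\n", sep = "")
  if (!is.na(x$n_proteins))
    cat("Training universe: ", x$n_proteins, " proteins\n", sep = "")
  cat("Mapping: ", x$n_pairs, " pairs over ", x$n_domains, " domains and ",
      x$n_terms, " terms (", x$n_extended, " after extension)\n", sep = "")
  cat("Relevance score quantiles (unextended):\n")
  print(round(x$score_quantiles, 4))
  invisible(x)
}

#' @export
coef.domfun <- function(object, extended = FALSE, ...) {
  m <- if (extended) object$extended else object$mapping
  as.data.frame(m)[order(-m$score), , drop = FALSE]
}

#' Plot the relevance distribution of a fitted mapping
#'
#' Draws the sorted relevance curve (rank versus score, descending), the
#' standard way to compare the resolution and robustness of different
#' weighting strategies.
#'
#' @param x a [domfun] model.
#' @param extended plot the extended mapping instead of the raw one.
#' @param ... passed to [graphics::plot()].
#' @export
plot.domfun <- function(x, extended = FALSE, ...) {
  curve <- relevance_distribution(if (extended) x$extended else x$mapping)
  graphics::plot(seq_along(curve), curve, type = "l",
                 xlab = "rank", ylab = "relevance",
                 main = paste0("Relevance distribution (", x$method, ")"),
                 ...)
  invisible(x)
}
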