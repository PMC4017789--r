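# CAFA-style protein-centric evaluation with true-path extension

# run expr with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# True-path extension of a per-protein score vector: a term inherits the
# maximum score of any scored descendant, so thresholding the extended vector
# equals extending each thresholded set. Restricted to terms known to `dag`.
extend_scores <- function(sc, dag) {
  if (!length(sc)) return(sc)
  anc <- anc_table(dag)
  terms <- names(sc)
  n_anc <- lengths(anc)[terms]
  all_terms <- c(terms, unlist(anc[terms], use.names = FALSE))
  all_sc <- c(as.numeric(sc), rep(as.numeric(sc), times = n_anc))
  out <- tapply(all_sc, all_terms, max)
  stats::setNames(as.numeric(out), names(out))
}

# Shared preprocessing: true-path-extend the truth, extend prediction scores,
# drop proteins with empty truth in the namespace (the recall denominator
# divides by |K(x)|). Returns the target set S with per-protein pieces.
prepare_eval <- function(preds, truth, dag) {
  stopifnot(inherits(preds, "prediction_set"))
  check_named_sets(truth, "truth")
  ns <- preds$namespace
  ns_terms <- dag$id[dag$namespace == ns]
  k_ext <- lapply(truth, function(g) {
    g <- intersect(vapply(g, resolve_term, character(1), dag = dag,
                          USE.NAMES = FALSE), ns_terms)
    if (!length(g)) return(character(0))
    true_path_extend(dag, g)
  })
  empty <- lengths(k_ext) == 0L
  if (any(empty))
    warning(sum(empty), " protein(s) with no truth annotations in ", ns,
            " dropped from the target set", call. = FALSE)
  k_ext <- k_ext[!empty]
  s_ext <- lapply(names(k_ext), function(p)
    extend_scores(preds$scores[[p]] %||% stats::setNames(numeric(0),
                                                         character(0)), dag))
  names(s_ext) <- names(k_ext)
  list(K = k_ext, scores = s_ext, S = names(k_ext))
}

#' Protein-centric precision at a threshold
#'
#' Over the m(t) target proteins with at least one predicted term at
#' threshold t, the mean of |K(x) ∩ P_t(x)| / |P_t(x)|, after true-path
#' extension of both the known annotation set K(x) and the prediction set
#' P_t(x). Undefined when no protein has a prediction (m(t) = 0): `NA` is
#' returned and such thresholds are excluded from the Fmax sweep.
#'
#' @param preds a [prediction_set].
#' @param truth named list: protein -> directly assigned true term ids.
#' @param dag a [go_dag].
#' @param t threshold in \[0, 1\].
#' @return list with elements `precision` and `m`.
#' @export
precision_at <- function(preds, truth, dag, t) {
  ev <- prepare_eval(preds, truth, dag)
  eval_at(ev, t)[c("precision", "m")]
}

#' Protein-centric recall at a threshold
#'
#' The mean over *all* target proteins (including those with empty P_t(x)) of
#' |K(x) ∩ P_t(x)| / |K(x)|, both sets true-path-extended.
#'
#' @inheritParams precision_at
#' @return a single number in \[0, 1\].
#' @export
recall_at <- function(preds, truth, dag, t) {
  ev <- prepare_eval(preds, truth, dag)
  eval_at(ev, t)$recall
}

# core metric computation on prepared pieces
eval_at <- function(ev, t) {
  per_prec <- numeric(0)
  rc_sum <- 0
  for (p in ev$S) {
    sc <- ev$scores[[p]]
    pt <- names(sc)[sc >= t]
    k <- ev$K[[p]]
    if (length(pt))
      per_prec <- c(per_prec, length(intersect(k, pt)) / length(pt))
    rc_sum <- rc_sum + length(intersect(k, pt)) / length(k)
  }
  m <- length(per_prec)
  list(precision = if (m > 0L) mean(per_prec) else NA_real_,
       recall = rc_sum / length(ev$S),
       m = m)
}

#' Threshold sweep and Fmax
#'
#' Evaluates precision and recall over a grid of thresholds and reports Fmax,
#' the maximum harmonic mean 2 pr rc / (pr + rc), the standard protein-centric
#' CAFA summary. Thresholds where no protein has a prediction (m(t) = 0) or
#' where pr + rc = 0 are skipped.
#'
#' @inheritParams precision_at
#' @param thresholds numeric grid; default 101 evenly spaced points on
#'   \[0, 1\].
#' @return an object of class `domfun_eval`: list with `table` (data.frame
#'   t, precision, recall, f, m), `fmax`, `t_max` (argmax threshold),
#'   `n_targets` and `namespace`.
#' @export
evaluate_predictions <- function(preds, truth, dag,
                                 thresholds = seq(0, 1, by = 0.01)) {
  if (!length(thresholds))
    stop_domfun("empty threshold grid")
  ev <- prepare_eval(preds, truth, dag)
  rows <- lapply(sort(thresholds), function(t) {
    r <- eval_at(ev, t)
    f <- if (r$m > 0L && !is.na(r$precision) && (r$precision + r$recall) > 0)
      2 * r$precision * r$recall / (r$precision + r$recall) else NA_real_
    data.frame(t = t, precision = r$precision, recall = r$recall,
               f = f, m = r$m)
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$f)
  fmax <- if (any(ok)) max(tab$f[ok]) else NA_real_
  t_max <- if (any(ok)) tab$t[ok][which.max(tab$f[ok])] else NA_real_
  structure(list(table = tab, fmax = fmax, t_max = t_max,
                 n_targets = length(ev$S), namespace = preds$namespace),
            class = "domfun_eval")
}

#' @export
print.domfun_eval <- function(x, ...) {
  cat("protein-centric evaluation (", x$namespace, "): ",
      x$n_targets, " target proteins\n", sep = "")
  cat(sprintf("  Fmax = %.4f at t = %.2f\n", x$fmax, x$t_max))
  i <- which(x$table$t == x$t_max)
  if (length(i) == 1L)
    cat(sprintf("  precision = %.4f, recall = %.4f, m = %d at t_max\n",
                x$table$precision[i], x$table$recall[i], x$table$m[i]))
  invisible(x)
}

#' @export
plot.domfun_eval <- function(x, ...) {
  ok <- !is.na(x$table$precision)
  graphics::plot(x$table$recall[ok], x$table$precision[ok], type = "b",
                 xlab = "recall", ylab = "precision", xlim = c(0, 1),
                 ylim = c(0, 1), main = "precision-recall over thresholds",
                 ...)
  invisible(x)
}

#' Jackknife subsets: leave one of ten partitions out
#'
#' Shuffles the protein ids into ten near-equal partitions and returns the
#' ten subsets formed by dropping one partition at a time, each holding about
#' 90% of the proteins. Used to probe the robustness of relevance weightings
#' on slightly perturbed corpora.
#'
#' @param protein_ids character vector of at least 10 ids.
#' @param seed optional integer seed (the caller's RNG state is preserved).
#' @return list of 10 character vectors.
#' @export
jackknife_subsets <- function(protein_ids, seed = NULL) {
  n <- length(protein_ids)
  if (n < 10L) stop_domfun("need at least 10 proteins, got ", n)
  shuffled <- with_seed(seed, sample(protein_ids))
  part <- sort(rep_len(1:10, n))  # partition sizes differ by at most 1
  lapply(1:10, function(i) shuffled[part != i])
}

#' Sorted relevance distribution curve
#'
#' The scores of a mapping sorted in descending order: the flatter and more
#' stable this curve across perturbed corpora, the more robust the weighting;
#' the steeper, the higher its resolution.
#'
#' @param mapping a `domain_go_map`.
#' @return numeric vector of scores, descending.
#' @export
relevance_distribution <- function(mapping) {
  stopifnot(inherits(mapping, "domain_go_map"))
  if (!nrow(mapping)) stop_domfun("empty mapping has no distribution")
  sort(mapping$score, decreasing = TRUE)
}

#' Maximum vertical distance between two sorted score curves
#'
#' Curves of different lengths are compared at equal relative rank: each is
#' interpolated linearly onto a common grid of relative ranks in \[0, 1\] and
#' the maximum absolute difference is returned.
#'
#' @param a,b numeric vectors (sorted descending, as from
#'   [relevance_distribution()]).
#' @param grid_n number of interpolation points.
#' @return a single nonnegative number.
#' @export
curve_max_distance <- function(a, b, grid_n = 512L) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  q <- seq(0, 1, length.out = grid_n)
  interp <- function(v) {
    if (length(v) == 1L) return(rep(v, grid_n))
    stats::approx(seq(0, 1, length.out = length(v)), v, xout = q)$y
  }
  max(abs(interp(a) - interp(b)))
}

#' Jackknife spread of a relevance weighting
#'
#' Builds the ten leave-one-partition-out subsets of the training proteins,
#' recomputes the weighted mapping on each, and returns the maximum pairwise
#' [curve_max_distance()] between the ten sorted score curves. A smaller
#' spread means the weighting is more robust to small perturbations of the
#' corpus.
#'
#' @param annotations named list: protein -> term ids.
#' @param domains named list: protein -> domain accessions.
#' @param ontology a [go_dag].
#' @param namespace GO namespace.
#' @param method `"scp"`, `"cp"` or `"pv"` (see [domfun()]).
#' @param seed optional integer seed for the partition shuffle.
#' @return list with `spread` (max pairwise curve distance) and `curves`
#'   (list of 10 sorted score vectors).
#' @export
jackknife_relevance_spread <- function(annotations, domains, ontology,
                                       namespace = "molecular_function",
                                       method = "scp", seed = NULL) {
  universe <- intersect(names(annotations), names(domains))
  subsets <- jackknife_subsets(universe, seed = seed)
  curves <- lapply(subsets, function(ids) {
    counts <- count_cooccurrence(annotations[ids], domains[ids],
                                 ontology, namespace)
    map <- switch(method, scp = relevance_scp(counts),
                  cp = relevance_cp(counts),
                  pv = relevance_pvalue(counts))
    relevance_distribution(map)
  })
  d <- 0
  for (i in 1:9) for (j in (i + 1):10)
    d <- max(d, curve_max_distance(curves[[i]], curves[[j]]))
  list(spread = d, curves = curves)
}
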