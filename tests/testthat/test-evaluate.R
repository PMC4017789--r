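# hand-worked 3-protein toy on the 3-chain root <- mid <- leaf:
#   P1: true {leaf},  predicted {mid: 0.8}   -> extended P_t = {mid, root}
#   P2: true {root},  predicted {mid: 0.9}   -> extended P_t = {mid, root}
#   P3: true {mid},   no predictions
# at t = 0.5: per-protein precisions 1 and 1/2 -> pr = 0.75, m = 2;
#             recalls 2/3, 1, 0               -> rc = 5/9; F = 30/47
# at t = 0.85: only P2 predicts -> pr = 1/2, m = 1, rc = 1/3, F = 2/5
toy <- function() {
  dag <- chain_dag()
  truth <- list(P1 = "GO:0000003", P2 = "GO:0000001", P3 = "GO:0000002")
  preds <- prediction_set(list(P1 = c("GO:0000002" = 0.8),
                               P2 = c("GO:0000002" = 0.9)))
  list(dag = dag, truth = truth, preds = preds)
}

test_that("precision and recall match the hand-worked toy exactly", {
  with(toy(), {
    p <- precision_at(preds, truth, dag, 0.5)
    expect_equal(p$precision, 0.75)
    expect_equal(p$m, 2L)
    expect_equal(recall_at(preds, truth, dag, 0.5), 5 / 9)

    p2 <- precision_at(preds, truth, dag, 0.85)
    expect_equal(p2$precision, 0.5)
    expect_equal(p2$m, 1L)
    expect_equal(recall_at(preds, truth, dag, 0.85), 1 / 3)

    # m(t) = 0: precision undefined, reported as missing
    p3 <- precision_at(preds, truth, dag, 0.95)
    expect_true(is.na(p3$precision))
    expect_equal(p3$m, 0L)
  })
})

test_that("the threshold sweep reproduces the toy Fmax and skips empty thresholds", {
  with(toy(), {
    res <- evaluate_predictions(preds, truth, dag)
    expect_equal(res$fmax, 30 / 47)
    expect_lte(res$t_max, 0.8)
    tab <- res$table
    expect_true(all(is.na(tab$f[tab$m == 0])))
    expect_true(all(diff(tab$m) <= 0))             # m(t) non-increasing
    expect_true(all(tab$precision >= 0 & tab$precision <= 1, na.rm = TRUE))
    expect_true(all(tab$recall >= 0 & tab$recall <= 1))
  })
})

test_that("grid Fmax equals the exhaustive distinct-score sweep on grid-aligned scores", {
  dag <- chain_dag()
  truth <- list(P1 = "GO:0000003", P2 = "GO:0000002", P3 = "GO:0000003")
  preds <- prediction_set(list(P1 = c("GO:0000003" = 1.0),
                               P2 = c("GO:0000003" = 0.6),
                               P3 = c("GO:0000002" = 0.2)))
  grid <- evaluate_predictions(preds, truth, dag)
  exhaustive <- evaluate_predictions(preds, truth, dag,
                                     thresholds = c(0, 0.2, 0.6, 1.0))
  expect_equal(grid$fmax, exhaustive$fmax)
  # the default grid dominates any coarser subgrid
  coarse <- evaluate_predictions(preds, truth, dag,
                                 thresholds = seq(0, 1, 0.25))
  expect_gte(grid$fmax, coarse$fmax)
  expect_error(evaluate_predictions(preds, truth, dag, thresholds = numeric(0)),
               "empty")
})

test_that("a subset predictor has precision 1 wherever it predicts", {
  set.seed(1313)
  corpus <- simulate_corpus(n_terms = 40, n_domains = 8, n_proteins = 50)
  truth <- corpus$truth
  # predict a true-path-closed subset of the truth with arbitrary scores
  scores <- lapply(truth, function(g) {
    pick <- true_path_extend(corpus$ontology, g[1])
    stats::setNames(stats::runif(length(pick), 0.2, 1), pick)
  })
  preds <- prediction_set(scores)
  for (t in c(0, 0.1, 0.5)) {
    p <- precision_at(preds, truth, corpus$ontology, t)
    if (p$m > 0) expect_equal(p$precision, 1.0)
  }
})

test_that("jackknife subsets leave one tenth out", {
  ids <- sprintf("P%03d", 1:100)
  subs <- jackknife_subsets(ids, seed = 5)
  expect_length(subs, 10L)
  expect_true(all(lengths(subs) == 90L))
  counts <- table(unlist(subs))
  expect_true(all(counts == 9L))                    # each id in exactly 9
  expect_setequal(union(subs[[1]], subs[[2]]), ids) # any pair covers all
  subs10 <- jackknife_subsets(sprintf("P%d", 1:10), seed = 5)
  expect_true(all(lengths(subs10) == 9L))
  expect_error(jackknife_subsets(sprintf("P%d", 1:9)), "at least 10")
  # seeded and reproducible without clobbering the caller's RNG
  set.seed(99); before <- stats::runif(1)
  set.seed(99); jackknife_subsets(ids, seed = 7); after <- stats::runif(1)
  expect_equal(before, after)
  expect_identical(jackknife_subsets(ids, seed = 7),
                   jackknife_subsets(ids, seed = 7))
})

test_that("relevance distribution sorts descending; curve distance is exact", {
  m <- domfun:::new_domain_go_map(c("a", "b", "c"), c("x", "y", "z"),
                                  c(0.5, 1.0, 0.1), method = "scp")
  expect_equal(relevance_distribution(m), c(1.0, 0.5, 0.1))
  expect_equal(curve_max_distance(c(1, .5, .1), c(1, .5, .1)), 0)
  # equal-length curves: distance is the plain elementwise maximum gap
  a <- sort(stats::runif(513), decreasing = TRUE)
  b <- sort(stats::runif(513), decreasing = TRUE)
  expect_equal(curve_max_distance(a, b, grid_n = 513L), max(abs(a - b)),
               tolerance = 1e-9)
})
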