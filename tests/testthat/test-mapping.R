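# small corpus helper: counts from explicit protein tables on a flat DAG
counts_from <- function(ann, dom, n_terms = 10) {
  ids <- sprintf("GO:%07d", 1:n_terms)
  dag <- go_dag(ids, parents = stats::setNames(
    lapply(ids[-1], function(x) ids[1]), ids[-1]))
  count_cooccurrence(ann, dom, dag)
}

test_that("count_cooccurrence counts pairs and restricts the universe", {
  c1 <- counts_from(list(P1 = "GO:0000002", P2 = "GO:0000002"),
                    list(P1 = "PF1", P2 = "PF1"))
  p <- c1$pairs
  expect_equal(p$n_both[p$domain == "PF1" & p$term == "GO:0000002"], 2L)
  expect_equal(unname(c1$n_dom["PF1"]), 2L)
  expect_equal(unname(c1$n_term["GO:0000002"]), 2L)
  expect_equal(c1$n_proteins, 2L)

  c2 <- counts_from(list(P1 = "GO:0000002", P2 = "GO:0000003"),
                    list(P1 = "PF1", P2 = "PF2"))
  expect_false(any(c2$pairs$domain == "PF1" & c2$pairs$term == "GO:0000003"))

  # protein with domains but no annotation in the namespace: not in N
  c3 <- counts_from(list(P1 = "GO:0000002"),
                    list(P1 = "PF1", P2 = "PF9"))
  expect_equal(c3$n_proteins, 1L)
  expect_error(
    count_cooccurrence(list(P1 = "GO:0000002"), list(P9 = "PF1"),
                       chain_dag()),
    "no co-annotated proteins")
})

test_that("relevance_scp reproduces the closed form on fixed count triples", {
  counts <- structure(list(
    pairs = data.frame(domain = c("d1", "d2", "d3"),
                       term = c("g1", "g2", "g3"),
                       n_both = c(2L, 5L, 1L)),
    n_dom = c(d1 = 4L, d2 = 5L, d3 = 10L),
    n_term = c(g1 = 2L, g2 = 5L, g3 = 10L),
    n_proteins = 20L, namespace = "molecular_function"),
    class = "cooc_counts")
  m <- relevance_scp(counts)
  sc <- stats::setNames(m$score, paste(m$domain, m$term))
  expect_equal(unname(sc["d1 g1"]), 0.5)    # 4 / (4*2)
  expect_equal(unname(sc["d2 g2"]), 1.0)    # perfect co-occurrence
  expect_equal(unname(sc["d3 g3"]), 0.01)   # = pr(u|v) * pr(v|u) = 0.1 * 0.1
})

test_that("scp equals the product of the two conditional probabilities", {
  set.seed(303)
  corpus <- simulate_corpus(n_terms = 60, n_domains = 12, n_proteins = 120,
                            dropout = 0.1, spurious = 0.1)
  counts <- count_cooccurrence(corpus$annotations, corpus$domains,
                               corpus$ontology)
  scp <- relevance_scp(counts)
  fwd <- relevance_cp(counts, "term_given_domain")
  rev <- relevance_cp(counts, "domain_given_term")
  key <- function(m) paste(m$domain, m$term)
  expect_equal(key(scp), key(fwd))
  prod <- stats::setNames(fwd$score, key(fwd))[key(scp)] *
    stats::setNames(rev$score, key(rev))[key(scp)]
  expect_equal(scp$score, unname(prod))
  expect_true(all(scp$score > 0 & scp$score <= 1))
  expect_true(all(fwd$score > 0 & fwd$score <= 1))
})

test_that("scp is symmetric in the margins and monotone in n_both", {
  base <- function(n_both, n_dom, n_term, N = 100L) {
    counts <- structure(list(
      pairs = data.frame(domain = "d", term = "g", n_both = n_both),
      n_dom = c(d = n_dom), n_term = c(g = n_term),
      n_proteins = N, namespace = "x"), class = "cooc_counts")
    relevance_scp(counts)$score
  }
  expect_equal(base(3L, 7L, 11L), base(3L, 11L, 7L))   # swap margins
  sweeps <- vapply(1:7, base, numeric(1), n_dom = 7L, n_term = 9L)
  expect_true(all(diff(sweeps) > 0))
})

test_that("relevance_cp uses the requested direction", {
  counts <- structure(list(
    pairs = data.frame(domain = "d", term = "g", n_both = 2L),
    n_dom = c(d = 4L), n_term = c(g = 2L),
    n_proteins = 10L, namespace = "x"), class = "cooc_counts")
  expect_equal(relevance_cp(counts)$score, 0.5)
  expect_equal(relevance_cp(counts, "domain_given_term")$score, 1.0)
})

test_that("relevance_pvalue matches exact hypergeometric enumeration", {
  mk <- function(n_both, n_dom, n_term, N) structure(list(
    pairs = data.frame(domain = "d", term = "g", n_both = n_both),
    n_dom = c(d = n_dom), n_term = c(g = n_term),
    n_proteins = N, namespace = "x"), class = "cooc_counts")

  # saturated table: tail probability 1, score 0
  expect_equal(relevance_pvalue(mk(5L, 5L, 5L, 5L))$score, 0)
  # fully coincident triple out of N = 10: P = 1 / choose(10, 3) = 1/120
  expect_equal(relevance_pvalue(mk(3L, 3L, 3L, 10L))$score, -log10(1 / 120))

  set.seed(404)
  for (i in 1:20) {
    N <- sample(5:40, 1)
    nd <- sample(1:N, 1); nt <- sample(1:N, 1)
    nb <- sample(max(1L, nd + nt - N):min(nd, nt), 1)
    expect_equal(relevance_pvalue(mk(nb, nd, nt, N))$score,
                 -log10(brute_hyper_tail(nb, nd, nt, N)),
                 tolerance = 1e-10)
  }
})

test_that("invalid counts are rejected", {
  bad <- structure(list(
    pairs = data.frame(domain = "d", term = "g", n_both = 5L),
    n_dom = c(d = 3L), n_term = c(g = 4L),
    n_proteins = 10L, namespace = "x"), class = "cooc_counts")
  expect_error(relevance_scp(bad), "n_both")
})
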