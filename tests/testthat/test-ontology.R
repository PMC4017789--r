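test_that("read_obo loads chains, drops obsolete terms, keeps multi-parent edges", {
  dag <- read_obo(write_tmp(obo_text_chain, ".obo"))
  expect_s3_class(dag, "go_dag")
  expect_length(dag$id, 3L)
  expect_equal(sum(lengths(dag$parents)), 2L)
  expect_equal(go_root(dag, "molecular_function"), "GO:0000001")

  obs <- c(obo_text_chain,
           "[Term]", "id: GO:0000009", "name: gone",
           "namespace: molecular_function", "is_obsolete: true", "")
  dag2 <- read_obo(write_tmp(obs, ".obo"))
  expect_false("GO:0000009" %in% dag2$id)

  two_par <- c(obo_text_chain,
               "[Term]", "id: GO:0000004", "name: multi",
               "namespace: molecular_function",
               "is_a: GO:0000002", "is_a: GO:0000001", "")
  dag3 <- read_obo(write_tmp(two_par, ".obo"))
  expect_setequal(dag3$parents[["GO:0000004"]],
                  c("GO:0000002", "GO:0000001"))
})

test_that("read_obo resolves alt_ids and errors on dangling or malformed input", {
  alt <- c(obo_text_chain[1:2],
           "[Term]", "id: GO:0000001", "name: root",
           "namespace: molecular_function", "alt_id: GO:0000099", "")
  dag <- read_obo(write_tmp(alt, ".obo"))
  expect_equal(ancestors(dag, "GO:0000099"), ancestors(dag, "GO:0000001"))

  dangling <- c(obo_text_chain,
                "[Term]", "id: GO:0000005", "namespace: molecular_function",
                "is_a: GO:0099999", "")
  expect_error(read_obo(write_tmp(dangling, ".obo")), "GO:0099999")

  malformed <- c("format-version: 1.2", "", "[Term]", "id: GO:0000001",
                 "not a key value line")
  expect_error(read_obo(write_tmp(malformed, ".obo")), "line 5")
})

test_that("relations filter keeps part_of edges only when asked", {
  rel <- c(obo_text_chain,
           "[Term]", "id: GO:0000006", "name: part",
           "namespace: molecular_function",
           "relationship: part_of GO:0000002", "")
  is_a_only <- read_obo(write_tmp(rel, ".obo"))
  expect_length(is_a_only$parents[["GO:0000006"]], 0L)
  both <- read_obo(write_tmp(rel, ".obo"), relations = c("is_a", "part_of"))
  expect_equal(both$parents[["GO:0000006"]], "GO:0000002")
})

test_that("ancestors: root, chain and diamond cases", {
  dag <- chain_dag()
  expect_equal(ancestors(dag, "GO:0000001"), character(0))
  expect_setequal(ancestors(dag, "GO:0000003"), c("GO:0000002", "GO:0000001"))
  dia <- diamond_dag()
  expect_setequal(ancestors(dia, "GO:0000004"),
                  c("GO:0000002", "GO:0000003", "GO:0000001"))
  expect_error(ancestors(dag, "GO:7777777"), "unknown term")
})

test_that("descendant_count is self-inclusive and counts diamonds once", {
  dag <- chain_dag()
  expect_equal(descendant_count(dag, "GO:0000003"), 1L)
  expect_equal(descendant_count(dag, "GO:0000001"), 3L)
  expect_equal(descendant_count(diamond_dag(), "GO:0000001"), 4L)
})

test_that("true_path_extend: closure, identity on root, idempotence, monotonicity", {
  dag <- chain_dag()
  expect_setequal(true_path_extend(dag, "GO:0000003"),
                  c("GO:0000003", "GO:0000002", "GO:0000001"))
  expect_equal(true_path_extend(dag, "GO:0000001"), "GO:0000001")
  ext <- true_path_extend(dag, "GO:0000003")
  expect_setequal(true_path_extend(dag, ext), ext)

  set.seed(101)
  for (i in 1:10) {
    dag <- simulate_dag(sample(5:40, 1), max_parents = 3)
    a <- sample(dag$id, 3)
    b <- unique(c(a, sample(dag$id, 2)))
    ea <- true_path_extend(dag, a)
    eb <- true_path_extend(dag, b)
    expect_true(all(ea %in% eb))        # monotone
    expect_true(all(a %in% ea))         # output contains input
    expect_setequal(true_path_extend(dag, ea), ea)  # idempotent
  }
})

test_that("traversal matches brute-force DFS and igraph on random DAGs", {
  set.seed(202)
  library(igraph)
  for (i in 1:30) {
    dag <- simulate_dag(sample(3:50, 1), max_parents = sample(1:3, 1))
    edges <- do.call(rbind, lapply(dag$id, function(t) {
      p <- dag$parents[[t]]
      if (length(p)) cbind(t, p) else NULL
    }))
    g <- graph_from_data_frame(
      if (is.null(edges)) data.frame(from = character(0), to = character(0))
      else data.frame(from = edges[, 1], to = edges[, 2]),
      directed = TRUE, vertices = dag$id)
    for (t in sample(dag$id, min(5, length(dag$id)))) {
      expect_equal(sort(ancestors(dag, t)), brute_ancestors(dag$parents, t))
      expect_setequal(
        ancestors(dag, t),
        setdiff(names(subcomponent(g, t, mode = "out")), t))
      expect_equal(descendant_count(dag, t),
                   length(brute_descendants(dag$parents, dag$id, t)))
      expect_equal(descendant_count(dag, t),
                   length(subcomponent(g, t, mode = "in")))
    }
    # edge invariants
    for (t in dag$id) for (p in dag$parents[[t]]) {
      expect_gte(descendant_count(dag, p), descendant_count(dag, t))
      expect_true(all(c(p, ancestors(dag, p)) %in% ancestors(dag, t)))
    }
  }
})

test_that("cycles and duplicate ids are rejected", {
  expect_error(
    go_dag(c("GO:0000001", "GO:0000002"),
           parents = list("GO:0000001" = "GO:0000002",
                          "GO:0000002" = "GO:0000001")),
    "cycle")
  expect_error(go_dag(c("GO:0000001", "GO:0000001")), "duplicate")
})
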