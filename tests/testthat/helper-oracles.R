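# independent brute-force oracles and small fixture builders
# (deliberately naive: plain DFS / full enumeration, no shared code paths
# with the package's topological-order implementations)

brute_ancestors <- function(parents, term) {
  out <- character(0)
  stack <- parents[[term]]
  while (length(stack)) {
    t <- stack[[1L]]; stack <- stack[-1L]
    if (!(t %in% out)) {
      out <- c(out, t)
      stack <- c(stack, parents[[t]])
    }
  }
  sort(out)
}

# self-inclusive downward reachable set, via the upward oracle
brute_descendants <- function(parents, ids, term) {
  sort(unique(c(term, ids[vapply(ids, function(x)
    term %in% brute_ancestors(parents, x), logical(1))])))
}

# enumerate every (seed, ancestor) candidate explicitly, combine by max
brute_extend <- function(map_df, parents, ids, strategy = "rsc") {
  dcount <- vapply(ids, function(t)
    length(brute_descendants(parents, ids, t)), numeric(1))
  rows <- list()
  for (i in seq_len(nrow(map_df))) {
    d <- map_df$domain[i]; g <- map_df$term[i]; s <- map_df$score[i]
    rows[[length(rows) + 1L]] <- data.frame(domain = d, term = g, score = s)
    for (a in brute_ancestors(parents, g)) {
      sc <- if (strategy == "rsc") s * dcount[[a]] / dcount[[g]] else s
      rows[[length(rows) + 1L]] <- data.frame(domain = d, term = a,
                                              score = sc)
    }
  }
  all <- do.call(rbind, rows)
  agg <- stats::aggregate(score ~ domain + term, data = all, FUN = max)
  agg[order(agg$domain, agg$term), ]
}

# exact hypergeometric upper tail by enumeration over the count table
brute_hyper_tail <- function(n_both, n_dom, n_term, N) {
  ks <- n_both:min(n_dom, n_term)
  sum(choose(n_term, ks) * choose(N - n_term, n_dom - ks)) / choose(N, n_dom)
}

# small fixed DAGs used across tests
chain_dag <- function() {
  go_dag(c("GO:0000001", "GO:0000002", "GO:0000003"),
         parents = list("GO:0000002" = "GO:0000001",
                        "GO:0000003" = "GO:0000002"))
}

diamond_dag <- function() {
  # leaf with two parents sharing one grandparent root
  go_dag(c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004"),
         parents = list("GO:0000002" = "GO:0000001",
                        "GO:0000003" = "GO:0000001",
                        "GO:0000004" = c("GO:0000002", "GO:0000003")))
}

obo_text_chain <- c(
  "format-version: 1.2",
  "",
  "[Term]", "id: GO:0000001", "name: root", "namespace: molecular_function",
  "",
  "[Term]", "id: GO:0000002", "name: mid", "namespace: molecular_function",
  "is_a: GO:0000001 ! root",
  "",
  "[Term]", "id: GO:0000003", "name: leaf", "namespace: molecular_function",
  "is_a: GO:0000002 ! mid",
  "")

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# sorted deep comparison of protein -> set structures
expect_same_sets <- function(a, b) {
  expect_equal(sort(names(a)), sort(names(b)))
  for (p in names(a)) expect_setequal(a[[p]], b[[p]])
}
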