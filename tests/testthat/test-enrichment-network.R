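test_that("hypergeometric p matches combinatorial enumeration", {
  coll <- list(sets = list(T1 = paste0("g", 1:5)),
               descriptions = c(T1 = "term"),
               universe = paste0("g", 1:20))
  res <- hypergeometric_enrichment(paste0("g", 1:5), coll)
  expect_equal(res$table$p, 1 / choose(20, 5))
  expect_equal(res$table$fold, (5 / 5) / (5 / 20))

  # zero overlap: upper tail includes X >= 0, so p = 1
  res0 <- hypergeometric_enrichment(paste0("g", 10:14), coll)
  expect_equal(res0$table$p, 1)

  # term covering the whole universe: p = 1 always
  coll2 <- list(sets = list(ALL = paste0("g", 1:20)),
                descriptions = c(ALL = "all"),
                universe = paste0("g", 1:20))
  expect_equal(hypergeometric_enrichment(paste0("g", 1:3), coll2)$table$p, 1)
})

test_that("hypergeometric p matches brute-force mass enumeration (N <= 30)", {
  set.seed(55)
  for (trial in 1:50) {
    N <- sample(10:30, 1)
    universe <- paste0("g", seq_len(N))
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    term <- sample(universe, K)
    query <- sample(universe, n)
    coll <- list(sets = list(T = term), descriptions = c(T = "t"),
                 universe = universe)
    res <- hypergeometric_enrichment(query, coll)
    k <- length(intersect(term, query))
    expect_equal(res$table$p, oracle_hyper_upper(k, K, N, n),
                 tolerance = 1e-12)
  }
})

test_that("query genes outside the universe are dropped, empty query errors", {
  coll <- read_gmt(write_test_gmt())
  res <- hypergeometric_enrichment(c("G1", "G2", "NOT_A_GENE"), coll)
  expect_equal(res$n_dropped, 1L)
  expect_error(hypergeometric_enrichment("NOT_A_GENE", coll), "no query")
})

test_that("BH adjustment follows the step-up rule and is idempotent", {
  p <- c(0.001, 0.01, 0.02, 0.05)
  adj <- bh_adjust(p)
  expect_equal(adj$adjusted, c(0.004, 0.02, 0.8 / 30, 0.05),
               tolerance = 1e-12)
  expect_true(all(adj$significant))

  expect_equal(bh_adjust(0.04)$adjusted, 0.04)
  expect_false(any(bh_adjust(rep(1, 5))$significant))

  # monotone in input p order, and a second application only grows values
  set.seed(2)
  p2 <- runif(30)
  a1 <- bh_adjust(p2)$adjusted
  ord <- order(p2)
  expect_true(all(diff(a1[ord]) >= -1e-12))
  expect_true(all(bh_adjust(a1)$adjusted >= a1 - 1e-12))
})

test_that("GMT reading keeps term structure and harmonizes to the universe", {
  coll <- read_gmt(write_test_gmt())
  expect_length(coll$sets, 3)
  expect_equal(coll$descriptions[["GO:0002"]], "reproduction")
  expect_equal(sort(coll$universe), sort(paste0("G", 1:20)))
  small <- read_gmt(write_test_gmt(), universe = paste0("G", 1:6))
  expect_true(all(unlist(small$sets) %in% paste0("G", 1:6)))
})

test_that("network assembly enforces the strict confidence cutoff", {
  edges <- data.frame(geneA = c("A", "B"), geneB = c("B", "C"),
                      confidence = c(0.9, 0.69))
  net <- build_network(edges, seed_genes = "A")
  expect_setequal(net$interactors, c("A", "B"))
  expect_equal(igraph::ecount(net$graph), 1)

  tri <- data.frame(geneA = c("A", "B", "C"), geneB = c("B", "C", "A"),
                    confidence = 0.8)
  net2 <- build_network(tri, seed_genes = "A")
  expect_setequal(net2$interactors, c("A", "B", "C"))

  # an edge at exactly 0.7 is kept
  at <- build_network(data.frame(geneA = "A", geneB = "B",
                                 confidence = 0.7), seed_genes = "A")
  expect_equal(igraph::ecount(at$graph), 1)

  # absent seed kept as isolated node
  iso <- build_network(edges, seed_genes = c("A", "Z"))
  expect_equal(iso$n_isolated_seeds, 1L)
  expect_true("Z" %in% iso$interactors)
})

test_that("components match a union-find oracle on random graphs", {
  set.seed(404)
  for (trial in 1:40) {
    n_nodes <- sample(5:25, 1)
    nodes <- paste0("n", seq_len(n_nodes))
    n_edges <- sample(3:40, 1)
    edges <- data.frame(geneA = sample(nodes, n_edges, replace = TRUE),
                        geneB = sample(nodes, n_edges, replace = TRUE),
                        confidence = runif(n_edges))
    net <- build_network(edges, seed_genes = nodes, min_confidence = 0.5)
    kept <- edges[edges$confidence >= 0.5 & edges$geneA != edges$geneB, ]
    oracle <- oracle_components(nodes, kept$geneA, kept$geneB)
    got <- net$components[nodes]
    # same partition: equal membership up to relabelling
    expect_equal(length(unique(oracle)), length(unique(got)))
    expect_true(all(tapply(oracle, got, function(v) length(unique(v))) == 1))
  }
})

test_that("raising the confidence cutoff never adds edges or grows parts", {
  set.seed(11)
  nodes <- paste0("n", 1:15)
  edges <- data.frame(geneA = sample(nodes, 30, replace = TRUE),
                      geneB = sample(nodes, 30, replace = TRUE),
                      confidence = runif(30))
  prev_edges <- Inf
  prev_max <- Inf
  for (cut in c(0.3, 0.5, 0.7, 0.9)) {
    net <- build_network(edges, seed_genes = nodes[1], min_confidence = cut)
    expect_lte(igraph::ecount(net$graph), prev_edges)
    expect_lte(max(net$component_sizes), prev_max)
    prev_edges <- igraph::ecount(net$graph)
    prev_max <- max(net$component_sizes)
  }
})

test_that("term overlap intersects significant sets across analyses", {
  expect_equal(term_overlap(list(a = c("t1", "t2"), b = c("t1", "t2")))$shared,
               c("t1", "t2"))
  expect_length(term_overlap(list(a = "t1", b = "t2"))$shared, 0)
  sets <- list(a = c("t1", "t2", "t3"), b = c("t2", "t3", "t4"),
               c = c("t3", "t5"))
  ov <- term_overlap(sets)
  expect_equal(ov$shared, Reduce(intersect, sets))
  expect_equal(sum(ov$venn$regions), length(unique(unlist(sets))))
})

test_that("edge lists validate confidence bounds", {
  f <- tempfile()
  writeLines(c("geneA\tgeneB\tconfidence", "A\tB\t1.2"), f)
  expect_error(read_edges(f), "\\[0, 1\\]")
  edges <- read_edges(write_test_edges())
  expect_equal(ncol(edges), 3L)
  expect_equal(nrow(edges), 5L)
})
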