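test_that("graph construction restricts, keeps isolated nodes and counts round-trip", {
  el <- edge_list(data.frame(gene_a = c("g1", "g2", "g3"),
                             gene_b = c("g2", "g3", "g4"),
                             confidence = c(900, 800, 700)))
  g <- build_graph(el, c("g1", "g2", "g3", "iso1", "iso2"))
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 2)      # g3-g4 dropped (g4 outside)
  expect_identical(unname(igraph::degree(g)[c("iso1", "iso2")]), c(0, 0))

  gfull <- build_graph(el)
  expect_equal(igraph::vcount(gfull), 4)
  expect_equal(igraph::ecount(gfull), 3)

  expect_error(build_graph(el, c("x", "y")), "no requested gene")

  # synthetic truth graph round-trips node and edge counts
  truth <- list(true_up_genes = sprintf("U%02d", 1:8),
                true_down_genes = sprintf("D%02d", 1:8),
                true_module_labels = stats::setNames(
                  integer(16), c(sprintf("U%02d", 1:8), sprintf("D%02d", 1:8))))
  sel <- generate_edge_list(truth, n_hubs = 2, hub_degree = 5,
                            noise_prob = 0.1, n_background = 0, seed = 3)
  gg <- build_graph(sel, unique(c(sel$gene_a, sel$gene_b)))
  expect_equal(igraph::ecount(gg), nrow(sel))
})

test_that("centralities match closed forms on star, path and complete graphs", {
  star <- build_graph(edge_list(data.frame(gene_a = "c",
                                           gene_b = c("l1", "l2", "l3"),
                                           confidence = 900)))
  b <- betweenness_centrality(star)
  expect_equal(unname(b["c"]), 3)              # C(3,2) pairs routed via center
  expect_equal(unname(b[c("l1", "l2", "l3")]), c(0, 0, 0))

  path <- build_graph(edge_list(data.frame(gene_a = c("a", "b"),
                                           gene_b = c("b", "c"),
                                           confidence = 900)))
  expect_equal(unname(betweenness_centrality(path)["b"]), 1)
  r <- radiality_centrality(path)
  expect_equal(unname(r["b"]), 2)              # (2+2)/2 with diameter 2
  expect_equal(unname(r["a"]), 1.5)            # (2+1-1 + 2+1-2)/2

  k4 <- expand.grid(a = letters[1:4], b = letters[1:4], stringsAsFactors = FALSE)
  k4 <- k4[k4$a < k4$b, ]
  g4 <- build_graph(edge_list(data.frame(gene_a = k4$a, gene_b = k4$b,
                                         confidence = 900)))
  r4 <- radiality_centrality(g4)
  expect_true(all(abs(r4 - r4[1]) < 1e-12))    # symmetry forces equality
})

test_that("centralities match brute-force oracles on random graphs", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(4:7, 1)
    adj <- random_adjacency(n, runif(1, 0.3, 0.8))
    if (sum(adj) == 0) next
    genes <- sprintf("g%02d", 1:n)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    igraph::V(g)$name <- genes
    expect_equal(unname(betweenness_centrality(g)), oracle_betweenness(adj),
                 tolerance = 1e-10)
    expect_equal(unname(radiality_centrality(g)), oracle_radiality(adj),
                 tolerance = 1e-10)
  }
})

test_that("centralities are invariant under node relabeling", {
  set.seed(4)
  adj <- random_adjacency(7, 0.4)
  genes <- sprintf("g%02d", 1:7)
  g1 <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g1)$name <- genes
  perm <- sample(7)
  g2 <- igraph::graph_from_adjacency_matrix(adj[perm, perm], mode = "undirected")
  igraph::V(g2)$name <- genes[perm]
  for (f in list(betweenness_centrality, radiality_centrality)) {
    expect_equal(f(g1)[genes], f(g2)[genes])
  }
})

test_that("hub selection unions top-k deterministically and recovers planted hubs", {
  ct <- data.frame(gene = sprintf("g%02d", 1:12),
                   betweenness = 12:1, radiality = 12:1)
  expect_identical(nrow(select_hubs(ct, k = 5)), 5L)     # identical rankings

  ct2 <- data.frame(gene = sprintf("g%02d", 1:12),
                    betweenness = 12:1, radiality = 1:12)
  h2 <- select_hubs(ct2, k = 5)
  expect_identical(nrow(h2), 10L)                        # fully disjoint
  expect_true(all(nrow(h2) >= 5 & nrow(h2) <= 10))

  # ties at the k-th rank: broken by other centrality then gene ID
  ct3 <- data.frame(gene = c("gB", "gA", "gC", "gD"),
                    betweenness = c(5, 5, 5, 1),
                    radiality = c(1, 1, 2, 9))
  h3 <- select_hubs(ct3, k = 2)
  expect_true("gC" %in% h3$gene[h3$from_betweenness])    # tie won on radiality
  expect_error(select_hubs(ct3, k = 9), "exceeds")

  truth <- list(true_up_genes = sprintf("U%02d", 1:15),
                true_down_genes = sprintf("D%02d", 1:15),
                true_module_labels = stats::setNames(
                  integer(40), c(sprintf("U%02d", 1:15), sprintf("D%02d", 1:15),
                                 sprintf("B%02d", 1:10))))
  el <- generate_edge_list(truth, n_hubs = 5, hub_degree = 12,
                           noise_prob = 0.04, n_background = 10, seed = 2)
  g <- build_graph(el, unique(c(el$gene_a, el$gene_b)))
  hubs <- select_hubs(centrality_table(g), k = 5)
  expect_true(all(attr(el, "designated_hubs") %in% hubs$gene))
})
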