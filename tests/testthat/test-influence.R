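test_that("two-node diffusion matches the closed form", {
  net <- igraph::make_graph(~ A - B)
  Fm <- compute_influence(net, beta = 0.4)
  # F = 0.4 (I - 0.6 [[0,1],[1,0]])^-1 = (0.4/0.64) [[1, .6], [.6, 1]]
  expect_equal(Fm["A", "A"], 0.625)
  expect_equal(Fm["A", "B"], 0.375)
  expect_equal(Fm["B", "A"], 0.375)
})

test_that("diffusion columns sum to one with a dominant diagonal", {
  set.seed(11)
  net <- igraph::simplify(igraph::sample_pa(40, m = 2, directed = FALSE))
  igraph::V(net)$name <- sprintf("G%02d", 1:40)
  for (beta in c(0.25, 0.4, 0.7)) {
    Fm <- compute_influence(net, beta)
    expect_equal(unname(colSums(Fm)), rep(1, 40), tolerance = 1e-12)
    expect_true(all(diag(unclass(Fm)) >= beta - 1e-12))
    expect_true(all(Fm >= 0 & Fm <= 1))
  }
  # beta near 1: almost no diffusion
  Fm <- compute_influence(net, 1 - 1e-9)
  expect_equal(unclass(Fm), diag(40), ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("diffusion rejects bad restart probabilities and isolated nodes", {
  net <- igraph::make_graph(~ A - B)
  expect_error(compute_influence(net, 0), "in \\(0, 1\\)")
  expect_error(compute_influence(net, 1), "in \\(0, 1\\)")
  iso <- igraph::make_graph(~ A - B, C)
  expect_error(compute_influence(iso, 0.4), "C")
})

test_that("influence graph uses the min rule and drops zero pairs", {
  Fm <- matrix(c(0.6, 0.1, 0.0,
                 0.3, 0.6, 0.2,
                 0.0, 0.4, 0.6), 3, 3, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  G <- build_influence_graph(covex:::new_influence_matrix(Fm),
                             c("A", "B", "C"))
  w_ab <- igraph::E(G)$weight[igraph::get_edge_ids(G, c("A", "B"))]
  w_bc <- igraph::E(G)$weight[igraph::get_edge_ids(G, c("B", "C"))]
  expect_equal(w_ab, 0.1)   # min(F(A,B)=0.3 row? min of 0.3 and 0.1)
  expect_equal(w_bc, 0.2)
  expect_equal(igraph::get_edge_ids(G, c("A", "C")), 0)  # min = 0
  expect_error(build_influence_graph(covex:::new_influence_matrix(Fm), "Z"),
               "absent")
})

test_that("symmetric influence leaves weights unchanged", {
  Fm <- matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  G <- build_influence_graph(covex:::new_influence_matrix(Fm), c("A", "B"))
  expect_equal(igraph::E(G)$weight, 0.3)
})

test_that("graph reduction keeps the heaviest edge-count cut exactly", {
  g <- igraph::make_full_graph(4)
  igraph::V(g)$name <- c("A", "B", "C", "D")
  igraph::E(g)$weight <- c(0.9, 0.8, 0.3, 0.7, 0.2, 0.5)
  Gr <- reduce_graph(g, target_avg_degree = 2)   # keep ceiling(2*4/2) = 4
  expect_equal(igraph::ecount(Gr), 4)
  expect_equal(sort(igraph::E(Gr)$weight), c(0.5, 0.7, 0.8, 0.9))
  expect_equal(igraph::graph_attr(Gr, "delta"), 0.5)
  # average degree in [target, target + 2/n)
  avg <- mean(igraph::degree(Gr))
  expect_gte(avg, 2); expect_lt(avg, 2 + 2 / 4)
})

test_that("reduction tie-break is lexicographic and scale-invariant", {
  g <- igraph::make_full_graph(4)
  igraph::V(g)$name <- c("A", "B", "C", "D")
  igraph::E(g)$weight <- rep(1, 6)
  Gr <- reduce_graph(g, target_avg_degree = 1)   # keep 2 of 6 equal edges
  kept <- apply(igraph::as_edgelist(Gr), 1, paste, collapse = "-")
  expect_identical(sort(kept), c("A-B", "A-C"))
  # monotone reweighting does not change the kept edge set
  g2 <- g; igraph::E(g2)$weight <- c(0.9, 0.8, 0.3, 0.7, 0.2, 0.5)
  g3 <- g; igraph::E(g3)$weight <- sqrt(c(0.9, 0.8, 0.3, 0.7, 0.2, 0.5))
  e2 <- apply(igraph::as_edgelist(reduce_graph(g2, 2)), 1, paste, collapse = "-")
  e3 <- apply(igraph::as_edgelist(reduce_graph(g3, 2)), 1, paste, collapse = "-")
  expect_identical(sort(e2), sort(e3))
})

test_that("reduction warns and keeps everything when edges are scarce", {
  g <- igraph::make_graph(~ A - B, B - C)
  igraph::E(g)$weight <- c(0.5, 0.4)
  expect_warning(Gr <- reduce_graph(g, 15), "fewer")
  expect_equal(igraph::ecount(Gr), 2)
  expect_error(reduce_graph(igraph::make_empty_graph(0, directed = FALSE)),
               "empty")
})

test_that("local networks follow BFS with weight-ranked overflow", {
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("C", "N1", "N2", "N3", "N4", "N5")
  igraph::E(star)$weight <- c(0.5, 0.4, 0.3, 0.2, 0.1)
  all_in <- extract_local_network(star, "C", cap = 10)
  expect_setequal(all_in, igraph::V(star)$name)
  # overflow: root plus the three heaviest neighbors
  top <- extract_local_network(star, "C", cap = 4)
  expect_identical(as.character(top), c("C", "N1", "N2", "N3"))
  # path graph: BFS order forced
  pth <- igraph::make_graph(~ A - B, B - C, C - D, D - E)
  igraph::E(pth)$weight <- 1
  expect_identical(as.character(extract_local_network(pth, "A", cap = 3)),
                   c("A", "B", "C"))
  # radius bound
  expect_identical(as.character(extract_local_network(pth, "A", cap = 10,
                                                      radius = 1)),
                   c("A", "B"))
  expect_error(extract_local_network(pth, "Z"), "unknown root")
})
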