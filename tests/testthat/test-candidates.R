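test_that("k = 1 always returns the root singleton", {
  set.seed(2)
  A <- random_mutation_matrix(10, 5)
  out <- brute_force_best_module(A, genes(A), genes(A)[3], k = 1, lam = 1)
  expect_identical(out$genes[[1]], genes(A)[3])
  out2 <- solve_root_blp(A, genes(A), genes(A)[3], k = 1, lam = 1)
  expect_identical(out2$genes[[1]], genes(A)[3])
})

test_that("solver equals the exhaustive oracle on random instances", {
  set.seed(123)
  for (t in 1:30) {
    A <- random_mutation_matrix(sample(6:30, 1), sample(4:12, 1),
                                p = runif(1, 0.05, 0.4))
    root <- sample(genes(A), 1)
    k <- sample(2:4, 1)
    lam <- sample(c(0, 1), 1)
    got <- solve_root_blp(A, genes(A), root, k, lam)
    want <- brute_force_best_module(A, genes(A), root, k, lam)
    expect_equal(got$W, want$W)
    expect_identical(got$genes[[1]], want$genes[[1]])
  }
})

test_that("lam = 0 optimum attains maximal local coverage", {
  set.seed(9)
  A <- random_mutation_matrix(20, 6, p = 0.3)
  out <- solve_root_blp(A, genes(A), genes(A)[1], k = 6, lam = 0)
  expect_equal(out$W, sum(rowSums(unclass(A)) > 0))
})

test_that("a fully mutated root stays alone at lam = 1 when everything overlaps", {
  m <- matrix(1L, 6, 1, dimnames = list(paste0("P", 1:6), "ROOT"))
  extra <- matrix(rbinom(12, 1, 0.5), 6, 2,
                  dimnames = list(paste0("P", 1:6), c("GA", "GB")))
  extra[1, extra[1, ] == 0] <- 1L  # ensure mutated
  A <- mutation_matrix(cbind(m, extra))
  out <- solve_root_blp(A, genes(A), "ROOT", k = 3, lam = 1)
  expect_identical(out$genes[[1]], "ROOT")
  expect_equal(out$W, 6)
})

test_that("duplicate-column ties resolve to the lexicographically smallest set", {
  m <- matrix(0L, 4, 3, dimnames = list(paste0("P", 1:4),
                                        c("GA", "GB", "GC")))
  m[1:2, "GA"] <- 1L; m[3:4, "GB"] <- 1L; m[3:4, "GC"] <- 1L
  A <- mutation_matrix(m)
  out <- solve_root_blp(A, genes(A), "GA", k = 2, lam = 0)
  expect_identical(out$genes[[1]], c("GA", "GB"))
  want <- brute_force_best_module(A, genes(A), "GA", k = 2, lam = 0)
  expect_identical(want$genes[[1]], c("GA", "GB"))
})

test_that("optimal weight is monotone in k", {
  set.seed(31)
  A <- random_mutation_matrix(25, 10, p = 0.15)
  for (lam in c(0, 1)) {
    w <- vapply(1:5, function(k)
      solve_root_blp(A, genes(A), genes(A)[1], k, lam)$W, 1)
    expect_true(all(diff(w) >= -1e-9))
  }
})

test_that("connected mode only returns modules connected in the graph", {
  set.seed(17)
  for (t in 1:10) {
    A <- random_mutation_matrix(15, 8, p = 0.25)
    g <- igraph::sample_gnp(8, 0.3)
    igraph::V(g)$name <- genes(A)
    root <- sample(genes(A), 1)
    out <- solve_root_blp(A, genes(A), root, k = 3, lam = 1,
                          graph = g, require_connected = TRUE)
    sg <- igraph::induced_subgraph(g, out$genes[[1]])
    expect_true(igraph::is_connected(sg))
    # never better than the unconstrained optimum
    expect_lte(out$W, solve_root_blp(A, genes(A), root, 3, 1)$W + 1e-9)
  }
})

test_that("per-root enumeration deduplicates by gene set", {
  m <- matrix(0L, 8, 4, dimnames = list(paste0("P", 1:8),
                                        c("GA", "GB", "GC", "GD")))
  m[1:4, "GA"] <- 1L; m[5:8, "GB"] <- 1L; m[1, "GC"] <- 1L; m[5, "GD"] <- 1L
  A <- mutation_matrix(m)
  g <- igraph::make_graph(~ GA - GB, GC - GA, GD - GB)
  igraph::E(g)$weight <- 1
  cands <- enumerate_candidates(g, A, k = 2, lam = 1)
  keys <- vapply(cands$genes, paste, "", collapse = ";")
  expect_false(any(duplicated(keys)))
  expect_lte(nrow(cands), igraph::vcount(g))
  # both GA and GB root the same exclusive pair
  expect_true("GA;GB" %in% keys)
  expect_identical(sum(keys == "GA;GB"), 1L)
})

test_that("an isolated node yields its own singleton candidate", {
  m <- matrix(c(1L, 0L, 0L, 1L), 2, 2,
              dimnames = list(c("P1", "P2"), c("GA", "GB")))
  A <- mutation_matrix(m)
  g <- igraph::add_vertices(igraph::make_empty_graph(directed = FALSE),
                            2, name = c("GA", "GB"))
  cands <- enumerate_candidates(g, A, k = 3, lam = 1)
  expect_setequal(vapply(cands$genes, paste, "", collapse = ";"),
                  c("GA", "GB"))
})

test_that("the oracle refuses oversized universes", {
  set.seed(4)
  A <- random_mutation_matrix(5, 21, p = 0.5)
  expect_error(brute_force_best_module(A, genes(A), genes(A)[1], 2, 0),
               "too large")
})
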