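test_that("the worked example yields 8 exclusive patients and CovEx 0.5", {
  A <- demo_module_matrix()
  M <- paste0("G", 1:4)
  expect_length(module_exclusive_patients(A, M), 8L)
  expect_equal(covex:::module_stats(A, M)$ratios, c(0.25, 0.75, 0.75, 0.25))
  expect_equal(exclusivity_ex(A, M), 0.5)
  expect_equal(coverage_cov(A, M), 1)
  expect_equal(covex_score(A, M), 0.5)
})

test_that("exclusivity hits its extremes on disjoint and identical supports", {
  m <- matrix(0L, 4, 2, dimnames = list(paste0("P", 1:4), c("G1", "G2")))
  m[1:2, 1] <- 1L; m[3:4, 2] <- 1L
  A <- mutation_matrix(m)
  expect_equal(exclusivity_ex(A, c("G1", "G2")), 1)
  expect_equal(covex_score(A, c("G1", "G2")), coverage_cov(A, c("G1", "G2")))
  m2 <- cbind(G1 = c(1L, 1L, 0L), G2 = c(1L, 1L, 0L))
  rownames(m2) <- paste0("P", 1:3)
  A2 <- mutation_matrix(m2)
  expect_length(module_exclusive_patients(A2, c("G1", "G2")), 0L)
  expect_equal(exclusivity_ex(A2, c("G1", "G2")), 0)
  # singleton module: every covered patient is exclusive
  expect_setequal(module_exclusive_patients(A2, "G1"),
                  gamma_patients(A2, "G1"))
})

test_that("scores stay in [0,1] with CovEx = Cov * Ex exactly", {
  set.seed(21)
  for (t in 1:20) {
    A <- random_mutation_matrix(12, 6, p = runif(1, 0.1, 0.5))
    M <- sample(genes(A), sample(2:4, 1))
    cov <- coverage_cov(A, M); ex <- exclusivity_ex(A, M)
    expect_gte(min(cov, ex), 0); expect_lte(max(cov, ex), 1)
    expect_equal(covex_score(A, M), cov * ex)
    expect_lte(covex_score(A, M), min(cov, ex) + 1e-12)
  }
})

test_that("the null sampler is seeded, reproducible and respects the graph", {
  ct <- longtail_cohort(m = 60, n = 30, seed = 8)
  n1 <- sample_null(ct$graph, ct$A, k = 3, n_samples = 500, seed = 42)
  n2 <- sample_null(ct$graph, ct$A, k = 3, n_samples = 500, seed = 42)
  n3 <- sample_null(ct$graph, ct$A, k = 3, n_samples = 500, seed = 43)
  expect_identical(n1$scores, n2$scores)
  expect_false(identical(n1$scores, n3$scores))
  expect_length(n1$scores, 500L)
  expect_true(all(n1$scores >= 0 & n1$scores <= 1))
})

test_that("a single clique gives a constant null; k=1 reduces to Cov", {
  m <- matrix(0L, 6, 3, dimnames = list(paste0("P", 1:6),
                                        c("GA", "GB", "GC")))
  m[1:2, 1] <- 1L; m[3:4, 2] <- 1L; m[5:6, 3] <- 1L
  A <- mutation_matrix(m)
  cl <- igraph::make_full_graph(3)
  igraph::V(cl)$name <- c("GA", "GB", "GC")
  null <- sample_null(cl, A, k = 3, n_samples = 50, seed = 1)
  expect_equal(unique(null$scores), 1)  # disjoint supports, full coverage
  null1 <- sample_null(cl, A, k = 1, n_samples = 200, seed = 1)
  expect_setequal(unique(null1$scores), c(2 / 6))
  expect_error(sample_null(cl, A, k = 4, n_samples = 10, seed = 1),
               "largest component")
})

test_that("the add-one p-value estimator behaves at the boundaries", {
  null <- structure(list(k = 2L, scores = as.numeric(1:99) / 100,
                         n_samples = 99L, seed = NULL),
                    class = "covex_null")
  expect_equal(empirical_p(2, null), 0.01)     # above the whole null
  expect_equal(empirical_p(0.001, null), 1)    # below the whole null
  null9 <- structure(list(k = 2L, scores = as.numeric(1:9) / 10,
                          n_samples = 9L, seed = NULL),
                     class = "covex_null")
  # ties count against the candidate: 5 null values >= the median
  expect_equal(empirical_p(0.5, null9), 0.6)
  # vectorized and monotone decreasing in the score
  p <- empirical_p(c(0, 0.35, 0.95, 2), null9)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p > 0 & p <= 1))
})

test_that("filtration enforces both thresholds and is monotone", {
  ct <- longtail_cohort(m = 80, n = 40, seed = 13)
  # hand-made candidates: a perfectly exclusive pair and a poor one
  m <- matrix(0L, 20, 4, dimnames = list(sprintf("Q%02d", 1:20),
                                         c("GA", "GB", "GC", "GD")))
  m[1:9, "GA"] <- 1L; m[10:18, "GB"] <- 1L
  m[1:9, "GC"] <- 1L; m[1:10, "GD"] <- 1L
  A <- mutation_matrix(m)
  cl <- igraph::make_full_graph(4)
  igraph::V(cl)$name <- genes(A)
  null <- sample_null(cl, A, k = 2, n_samples = 2000, seed = 3)
  cands <- tibble::tibble(root = c("GA", "GC"), k = 2L, lambda = 1,
                          genes = list(c("GA", "GB"), c("GC", "GD")),
                          W = c(18, 9))
  kept <- filter_candidates(cands, null, A, ex_min = 0.8, p_max = 0.5)
  keys <- vapply(kept$genes, paste, "", collapse = ";")
  expect_true("GA;GB" %in% keys)       # Ex = 1, top of the null
  expect_false("GC;GD" %in% keys)      # heavily overlapping, Ex < 0.8
  # raising ex_min or lowering p_max never adds modules
  kept2 <- filter_candidates(cands, null, A, ex_min = 0.9, p_max = 0.5)
  kept3 <- filter_candidates(cands, null, A, ex_min = 0.8, p_max = 0.01)
  expect_true(all(vapply(kept2$genes, paste, "", collapse = ";") %in% keys))
  expect_true(all(vapply(kept3$genes, paste, "", collapse = ";") %in% keys))
  # missing null size errors
  cands3 <- tibble::tibble(genes = list(c("GA", "GB", "GC")))
  expect_error(filter_candidates(cands3, null, A), "size")
})

test_that("exclusivity requires every module gene to be mutated", {
  m <- matrix(c(1L, 0L), 1, 2, dimnames = list("P1", c("G1", "G2")))
  A <- covex:::new_mutation_matrix(m)
  expect_error(exclusivity_ex(A, c("G1", "G2")), "no mutations")
})
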