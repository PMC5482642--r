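# Shared fixtures, built in code.

# The 11-patient x 4-gene worked-example matrix: 8 patients carry exactly
# one module gene; per-gene supports are G1:4, G2:4, G3:4, G4:4 with
# exclusive counts 1, 3, 3, 1; all 11 patients are covered.
demo_module_matrix <- function() {
  g <- c("G1", "G2", "G3", "G4")
  p <- sprintf("P%02d", 1:11)
  m <- matrix(0L, 11, 4, dimnames = list(p, g))
  m["P01", "G1"] <- 1L
  m[c("P02", "P03", "P04"), "G2"] <- 1L
  m[c("P05", "P06", "P07"), "G3"] <- 1L
  m["P08", "G4"] <- 1L
  m["P09", c("G1", "G2", "G4")] <- 1L
  m["P10", c("G1", "G3", "G4")] <- 1L
  m["P11", c("G1", "G4")] <- 1L
  mutation_matrix(m)
}

# Random binary matrix with every gene mutated at least once.
random_mutation_matrix <- function(m, n, p = 0.2) {
  mat <- matrix(rbinom(m * n, 1, p), m, n,
                dimnames = list(sprintf("p%02d", seq_len(m)),
                                sprintf("g%02d", seq_len(n))))
  mat[cbind(sample(m, n, replace = TRUE), seq_len(n))] <- 1L
  mutation_matrix(mat)
}

# Three-network toy whose consensus has pair weights ab:3, bc:2, cd:1, ef:2.
toy_consensus_solutions <- function() {
  tibble::tibble(
    network = c("net1", "net1", "net1", "net1", "net2", "net2", "net2",
                "net3"),
    genes = list(c("a", "b"), c("b", "c"), c("c", "d"), c("e", "f"),
                 c("a", "b"), c("b", "c"), c("e", "f"),
                 c("a", "b"))
  )
}

# Cohort with a long-tailed per-gene mutation-rate spectrum plus a
# scale-free graph; used where a fine-grained CovEx distribution matters.
longtail_cohort <- function(m = 500, n = 400, seed = 5) {
  set.seed(seed)
  rates <- exp(runif(n, log(0.01), log(0.15)))
  mat <- matrix(rbinom(m * n, 1, rep(rates, each = m)), m, n,
                dimnames = list(sprintf("P%03d", seq_len(m)),
                                sprintf("G%03d", seq_len(n))))
  mat[cbind(sample(m, n, replace = TRUE), seq_len(n))] <- 1L
  g <- igraph::simplify(igraph::sample_pa(n, m = 3, directed = FALSE))
  igraph::V(g)$name <- colnames(mat)
  list(A = mutation_matrix(mat), graph = g)
}
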