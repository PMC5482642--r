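#' Synthetic cohort with planted mutually exclusive driver modules
#'
#' Generates a scale-free interaction network (preferential attachment), a
#' binary patient-by-gene mutation matrix, and ground truth.  Each planted
#' module is a connected subgraph grown by random edge expansion from a
#' random seed node; planted modules use disjoint gene sets.  Every planted
#' module independently covers each patient with probability
#' `coverage`; a covered patient receives exactly one uniformly chosen
#' module gene with probability `1 - comutation` and two distinct module
#' genes otherwise.  On top of that, every matrix entry is flipped to 1
#' with probability `passenger_rate` (sporadic passenger mutations).
#'
#' With `comutation = 0` and `passenger_rate = 0` every planted module has
#' exclusivity `Ex = 1` exactly by construction.
#'
#' @param n_patients Cohort size (default 200).
#' @param n_genes Number of genes / network nodes (default 500).
#' @param n_modules Number of planted driver modules (default 5).
#' @param module_size Genes per planted module (default 3).
#' @param coverage Per-module probability that a patient carries a driver
#'   mutation from it (default 0.5).
#' @param comutation Probability that a covered patient gets two module
#'   genes instead of one (default 0.05).
#' @param passenger_rate Background per-entry mutation probability
#'   (default 0.008).
#' @param pa_edges Edges added per node in the preferential-attachment
#'   model (default 3, mean degree about 6).
#' @param seed Optional integer seed.
#' @return A list of class `covex_sim`: `network` (igraph), `A`
#'   ([mutation_matrix()], restricted to mutated genes), `truth` (list with
#'   `modules` — list of planted gene sets — and `patient_modules` — per
#'   patient, the indices of the modules that cover it), and `config`.
#' @export
generate_synthetic <- function(n_patients = 200L, n_genes = 500L,
                               n_modules = 5L, module_size = 3L,
                               coverage = 0.5, comutation = 0.05,
                               passenger_rate = 0.008, pa_edges = 3L,
                               seed = NULL) {
  if (coverage <= 0 || coverage > 1) abort("`coverage` must be in (0, 1]")
  if (comutation < 0 || comutation >= 1) abort("`comutation` must be in [0, 1)")
  if (passenger_rate < 0 || passenger_rate >= 1) {
    abort("`passenger_rate` must be in [0, 1)")
  }
  if (n_modules * module_size > n_genes) {
    abort("planted modules need more genes than the network has")
  }
  if (module_size < 2 && n_modules > 0) {
    abort("planted modules need at least 2 genes")
  }
  if (!is.null(seed)) set.seed(seed)
  gene_names <- sprintf("G%04d", seq_len(n_genes))
  net <- igraph::sample_pa(n_genes, m = pa_edges, directed = FALSE)
  net <- igraph::simplify(net)
  igraph::V(net)$name <- gene_names
  adj <- lapply(igraph::as_adj_list(net, mode = "all"), as.integer)

  # plant connected, gene-disjoint modules by random edge expansion
  taken <- integer()
  modules <- vector("list", n_modules)
  for (j in seq_len(n_modules)) {
    grown <- NULL
    for (attempt in seq_len(1000L)) {
      seed_node <- sample.int(n_genes, 1L)
      if (seed_node %in% taken) next
      S <- seed_node
      while (length(S) < module_size) {
        nb <- unlist(adj[S], use.names = FALSE)
        nb <- nb[!(nb %in% S) & !(nb %in% taken)]
        if (length(nb) == 0L) break
        S <- c(S, nb[sample.int(length(nb), 1L)])
      }
      if (length(S) == module_size) { grown <- S; break }
    }
    if (is.null(grown)) abort("could not plant a connected module; network too fragmented")
    modules[[j]] <- sort(grown)
    taken <- c(taken, grown)
  }

  mat <- matrix(0L, n_patients, n_genes,
                dimnames = list(sprintf("P%04d", seq_len(n_patients)),
                                gene_names))
  patient_modules <- rep(list(integer()), n_patients)
  for (j in seq_len(n_modules)) {
    covered <- which(runif(n_patients) < coverage)
    for (i in covered) {
      two <- runif(1) < comutation
      pick <- sample(modules[[j]], if (two) 2L else 1L)
      mat[i, pick] <- 1L
      patient_modules[[i]] <- c(patient_modules[[i]], j)
    }
  }
  flips <- which(matrix(runif(n_patients * n_genes) < passenger_rate,
                        n_patients, n_genes), arr.ind = TRUE)
  mat[flips] <- 1L

  mutated <- colSums(mat) > 0L
  A <- new_mutation_matrix(mat[, mutated, drop = FALSE])
  truth <- list(modules = lapply(modules, function(S) gene_names[S]),
                patient_modules = setNames(patient_modules, rownames(mat)))
  structure(list(network = net, A = A, truth = truth,
                 config = list(n_patients = n_patients, n_genes = n_genes,
                               n_modules = n_modules,
                               module_size = module_size,
                               coverage = coverage, comutation = comutation,
                               passenger_rate = passenger_rate,
                               pa_edges = pa_edges, seed = seed)),
            class = "covex_sim")
}

#' @export
print.covex_sim <- function(x, ...) {
  cat(sprintf(
    "<covex_sim> %d patients x %d mutated genes, %d planted modules of size %d\n",
    nrow(x$A), ncol(x$A), x$config$n_modules, x$config$module_size))
  invisible(x)
}

#' Sensitivity and accuracy of a gene-level prediction
#'
#' Follows the convention of counting benchmark hits: sensitivity is the
#' number of predicted genes found in the benchmark list; accuracy is that
#' count divided by the number of predicted genes.
#'
#' @param predicted Character vector of predicted gene symbols (nonempty).
#' @param benchmark Character vector of benchmark cancer genes, or a gene
#'   set list from [read_gene_set()].
#' @return A one-row tibble with `n_predicted`, `sensitivity`, `accuracy`.
#' @export
score_prediction <- function(predicted, benchmark) {
  if (is.list(benchmark)) benchmark <- benchmark$genes
  predicted <- unique(normalize_symbols(predicted))
  predicted <- predicted[nzchar(predicted)]
  if (length(predicted) == 0L) {
    abort("empty prediction: accuracy undefined")
  }
  benchmark <- unique(normalize_symbols(benchmark))
  sens <- length(intersect(predicted, benchmark))
  tibble::tibble(n_predicted = length(predicted),
                 sensitivity = sens,
                 accuracy = sens / length(predicted))
}

#' Fraction of planted modules recovered exactly
#'
#' @param predicted_modules List of predicted gene sets (character
#'   vectors), or a tibble with a `genes` list-column.
#' @param truth Ground truth from [generate_synthetic()] (or its `truth`
#'   element).
#' @return Fraction in `[0, 1]` of planted modules matched exactly (set
#'   equality) by some predicted module.
#' @export
recovery_rate <- function(predicted_modules, truth) {
  if (inherits(truth, "covex_sim")) truth <- truth$truth
  if (is.data.frame(predicted_modules)) {
    predicted_modules <- predicted_modules$genes
  }
  planted <- truth$modules
  if (length(planted) == 0L) return(NaN)
  pred_keys <- unique(vapply(predicted_modules,
                             function(M) paste(sort(M), collapse = ";"), ""))
  hit <- vapply(planted, function(M) {
    paste(sort(M), collapse = ";") %in% pred_keys
  }, TRUE)
  mean(hit)
}
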