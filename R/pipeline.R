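#' Run the three-phase driver-module pipeline for one parameter setting
#'
#' Phases, in order: restrict the mutation matrix to the network's mutated
#' genes; build (or accept) the influence matrix and the weighted influence
#' graph over mutated genes; reduce it to the target average degree;
#' enumerate one exact candidate module per root ([enumerate_candidates()]);
#' filter on exclusivity and empirical CovEx significance
#' ([filter_candidates()]); select crucial patient-specific modules by
#' greedy set cover ([greedy_cover()]); optionally drop s-modules.
#'
#' @param A A [mutation_matrix()].
#' @param network An `igraph` interaction network, or a precomputed
#'   `influence_matrix` (see [read_influence_matrix()]).
#' @param lambda Trade-off \eqn{\lambda} (default 1).
#' @param k Module size bound (default 3).
#' @param beta Restart probability for the diffusion (default 0.4; ignored
#'   when `network` is already an influence matrix).
#' @param avg_degree Target average degree of the reduced influence graph
#'   (default 15).
#' @param cap Local network size cap (default 300).
#' @param ex_min,p_max Filtration thresholds (defaults 0.8 and 0.05).
#' @param null_samples Null subnetworks per module size (default 100000).
#' @param drop_s Optional s-module threshold; when given, s-modules are
#'   removed from the final solution.
#' @param require_connected Constrain candidate modules to be connected in
#'   the reduced graph (default `FALSE`).
#' @param label Network label recorded on the solution (default
#'   `"network"`).
#' @param seed Optional seed applied before the null sampling.
#' @param null Optional precomputed `covex_null` (or list of them) to reuse
#'   across settings that share the graph and `k`.
#' @return An object of class `covex_solution`: list with `modules` (the
#'   final tibble, selection-ordered, with scores and marginals), `cover`
#'   (the `covex_cover`), `graph` (the reduced influence graph), `null`,
#'   `counts` (per-stage module counts) and `params`.
#' @export
run_covex <- function(A, network, lambda = 1, k = 3L, beta = 0.4,
                      avg_degree = 15, cap = 300L, ex_min = 0.8,
                      p_max = 0.05, null_samples = 100000L, drop_s = NULL,
                      require_connected = FALSE, label = "network",
                      seed = NULL, null = NULL) {
  prep <- prepare_graph(A, network, beta = beta, avg_degree = avg_degree)
  run_covex_prepared(prep$A, prep$Gr, lambda = lambda, k = k, cap = cap,
                     ex_min = ex_min, p_max = p_max,
                     null_samples = null_samples, drop_s = drop_s,
                     require_connected = require_connected, label = label,
                     seed = seed, null = null)
}

# Shared phase-0: influence matrix -> influence graph -> reduced graph,
# with the mutation matrix restricted to the mutated network genes.
prepare_graph <- function(A, network, beta = 0.4, avg_degree = 15) {
  Fmat <- if (inherits(network, "influence_matrix")) network else
    compute_influence(network, beta = beta)
  A <- restrict_to_network(A, colnames(Fmat))
  G <- build_influence_graph(Fmat, colnames(A))
  Gr <- reduce_graph(G, target_avg_degree = avg_degree)
  list(A = A, Gr = Gr)
}

run_covex_prepared <- function(A, Gr, lambda, k, cap, ex_min, p_max,
                               null_samples, drop_s, require_connected,
                               label, seed, null = NULL) {
  cands <- enumerate_candidates(Gr, A, k = k, lam = lambda, cap = cap,
                                require_connected = require_connected)
  cands$source <- label
  if (is.null(null)) {
    sizes <- sort(unique(lengths(cands$genes)))
    null <- lapply(sizes, function(kk) {
      sample_null(Gr, A, k = kk, n_samples = null_samples,
                  seed = if (is.null(seed)) NULL else seed + kk)
    })
  } else if (inherits(null, "covex_null")) {
    null <- list(null)
  }
  kept <- filter_candidates(cands, null, A, ex_min = ex_min, p_max = p_max)
  if (nrow(kept) == 0L) {
    sol <- NULL
    final <- kept
  } else {
    sol <- greedy_cover(kept, A)
    final <- if (!is.null(drop_s)) filter_s_modules(sol, drop_s) else
      sol$chosen
  }
  structure(list(
    modules = final, cover = sol, graph = Gr, null = null,
    counts = c(candidates = nrow(cands), filtered = nrow(kept),
               covered = if (is.null(sol)) 0L else nrow(sol$chosen),
               final = nrow(final)),
    params = list(lambda = lambda, k = k, cap = cap, ex_min = ex_min,
                  p_max = p_max, null_samples = null_samples,
                  drop_s = drop_s, require_connected = require_connected,
                  label = label, seed = seed)),
    class = "covex_solution")
}

#' @export
print.covex_solution <- function(x, ...) {
  cat(sprintf(
    "<covex_solution> %s, lambda = %g, k = %d: %d candidates -> %d significant -> %d crucial\n",
    x$params$label, x$params$lambda, x$params$k,
    x$counts[["candidates"]], x$counts[["filtered"]], x$counts[["final"]]))
  invisible(x)
}

#' @export
tidy.covex_solution <- function(x, ...) {
  out <- x$modules
  if (nrow(out)) out$module <- vapply(out$genes, paste, "", collapse = ";")
  out
}

#' @export
glance.covex_solution <- function(x, ...) {
  tibble::tibble(network = x$params$label, lambda = x$params$lambda,
                 k = x$params$k,
                 n_candidates = x$counts[["candidates"]],
                 n_significant = x$counts[["filtered"]],
                 n_crucial = x$counts[["covered"]],
                 n_final = x$counts[["final"]])
}

#' Run the pipeline over a parameter grid and build the consensus
#'
#' Applies [run_covex()] to every combination of network, `lambda` and `k`
#' (the conventional grid is \eqn{\lambda \in \{0, 1\}},
#' \eqn{k \in \{2,3,4,5\}}, giving 8 single predictions per network), then
#' combines all single predictions with [consensus_modules()].  Influence
#' graphs are computed once per network and null distributions once per
#' (network, module size); both are reused across `lambda`.
#'
#' @param A A [mutation_matrix()].
#' @param networks Named list of `igraph` networks and/or
#'   `influence_matrix` objects; names are the network labels.
#' @param lambdas Numeric vector of trade-offs (default `c(0, 1)`).
#' @param ks Integer vector of size bounds (default `2:5`).
#' @inheritParams run_covex
#' @param core_weight,extend_weight Consensus thresholds, needed when the
#'   number of networks differs from 3.
#' @return A list of class `covex_run`: `solutions` (list of
#'   `covex_solution`), `solution_modules` (tibble of all final modules
#'   with `network`, `lambda`, `k`), and `consensus` (see
#'   [consensus_modules()]; `NULL` when no modules survive).
#' @export
run_covex_grid <- function(A, networks, lambdas = c(0, 1), ks = 2:5,
                           beta = 0.4, avg_degree = 15, cap = 300L,
                           ex_min = 0.8, p_max = 0.05,
                           null_samples = 100000L, drop_s = NULL,
                           require_connected = FALSE, seed = NULL,
                           core_weight = NULL, extend_weight = NULL) {
  if (length(networks) == 0L) abort("need at least one network")
  if (is.null(names(networks)) || any(!nzchar(names(networks)))) {
    abort("`networks` must be a named list")
  }
  solutions <- list()
  for (nw in names(networks)) {
    prep <- prepare_graph(A, networks[[nw]], beta = beta,
                          avg_degree = avg_degree)
    # one null per (network, module size), shared across lambda and k
    nulls_by_size <- list()
    for (k in sort(unique(as.integer(ks)))) {
      for (kk in seq_len(k)) {
        if (is.null(nulls_by_size[[as.character(kk)]])) {
          nulls_by_size[[as.character(kk)]] <- sample_null(
            prep$Gr, prep$A, k = kk, n_samples = null_samples,
            seed = if (is.null(seed)) NULL else seed + 1000L * kk)
        }
      }
      for (lam in lambdas) {
        key <- sprintf("%s|lambda=%g|k=%d", nw, lam, k)
        solutions[[key]] <- run_covex_prepared(
          prep$A, prep$Gr, lambda = lam, k = k, cap = cap,
          ex_min = ex_min, p_max = p_max, null_samples = null_samples,
          drop_s = drop_s, require_connected = require_connected,
          label = nw, seed = seed,
          null = unname(nulls_by_size[as.character(seq_len(k))]))
      }
    }
  }
  solution_modules <- dplyr::bind_rows(lapply(solutions, function(s) {
    if (nrow(s$modules) == 0L) return(NULL)
    tibble::tibble(network = s$params$label, lambda = s$params$lambda,
                   k = s$params$k, genes = s$modules$genes)
  }))
  consensus <- if (nrow(solution_modules) > 0L) {
    consensus_modules(solution_modules, n_networks = length(networks),
                      core_weight = core_weight,
                      extend_weight = extend_weight)
  } else NULL
  structure(list(solutions = solutions, solution_modules = solution_modules,
                 consensus = consensus),
            class = "covex_run")
}

#' @export
print.covex_run <- function(x, ...) {
  cat(sprintf("<covex_run> %d single predictions, %d consensus modules\n",
              length(x$solutions),
              if (is.null(x$consensus)) 0L else nrow(x$consensus$modules)))
  invisible(x)
}
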