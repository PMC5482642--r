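#' Gene-pair co-occurrence indicators per network
#'
#' For each interaction network, a gene pair gets indicator 1 if the two
#' genes appear together in at least one module of any of that network's
#' solutions, 0 otherwise (OR over the network's solutions).
#'
#' @param solutions Tibble of per-solution modules: one row per module with
#'   a `network` label column and a `genes` list-column (columns such as
#'   `lambda`, `k` may be present and are ignored here).
#' @return Tibble with columns `network`, `gene_a`, `gene_b`
#'   (`gene_a < gene_b`), one row per present pair.
#' @export
pair_indicators <- function(solutions) {
  if (nrow(solutions) == 0L) abort("no solution modules")
  if (!all(c("network", "genes") %in% names(solutions))) {
    abort("`solutions` needs `network` and `genes` columns")
  }
  rows <- purrr::map2_dfr(solutions$network, solutions$genes, function(nw, M) {
    M <- sort(unique(M))
    if (length(M) < 2L) return(NULL)
    p <- combn(M, 2L)
    tibble::tibble(network = nw, gene_a = p[1, ], gene_b = p[2, ])
  })
  dplyr::distinct(rows)
}

#' Build the double-weighted consensus network
#'
#' Edge weight = number of networks in which the pair co-occurred in a
#' module (0..number of networks); node weight = maximum weight of the
#' incident edges.
#'
#' @param indicators Pair-indicator tibble from [pair_indicators()].
#' @param n_networks Number of networks the solutions came from; defaults
#'   to the number of distinct labels present in `indicators`.
#' @return An object of class `covex_consensus_net`: list with `graph` (a
#'   weighted `igraph`), `node_weight` (named numeric) and `n_networks`.
#' @export
build_consensus <- function(indicators, n_networks = NULL) {
  n_networks <- n_networks %||% length(unique(indicators$network))
  counted <- dplyr::count(indicators, .data$gene_a, .data$gene_b,
                          name = "weight")
  if (any(counted$weight > n_networks)) {
    abort("pair counted in more networks than `n_networks`")
  }
  g <- igraph::graph_from_data_frame(counted, directed = FALSE)
  nw <- vapply(igraph::V(g)$name, function(v) {
    max(igraph::E(g)$weight[igraph::incident(g, v)])
  }, 1)
  structure(list(graph = g, node_weight = nw,
                 n_networks = as.integer(n_networks)),
            class = "covex_consensus_net")
}

#' @export
print.covex_consensus_net <- function(x, ...) {
  cat(sprintf("<covex_consensus_net> %d genes, %d pairs, %d networks\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$n_networks))
  invisible(x)
}

consensus_thresholds <- function(N, core_weight, extend_weight) {
  if (is.null(core_weight) || is.null(extend_weight)) {
    if (N$n_networks != 3L) {
      abort(paste("the 3-level core/extension semantics are defined for",
                  "exactly 3 networks; give `core_weight` and",
                  "`extend_weight` explicitly"))
    }
    core_weight <- core_weight %||% 3L
    extend_weight <- extend_weight %||% 2L
  }
  list(core = core_weight, extend = extend_weight)
}

#' Cores and consensus modules of the double-weighted network
#'
#' Cores are the connected components of the subgraph induced by the
#' maximum-weight (weight-3) edges.  A type 1 module is a core extended by
#' every weight-2 edge with exactly one end in the core; a weight-2 node
#' attached to several cores is a *linker gene* and belongs to all the
#' corresponding type 1 modules.  Type 2 modules are the components induced
#' by the weight-2 edges after removing every node of node-weight 3.
#' Weight-1 edges and genes play no role in either step.
#'
#' With a number of networks other than 3 the 3/2 levels are undefined and
#' `core_weight` / `extend_weight` must be given explicitly.
#'
#' @param N A `covex_consensus_net` from [build_consensus()].
#' @param core_weight Edge weight defining cores (default 3 for 3 networks).
#' @param extend_weight Edge weight used for extension and type 2 modules
#'   (default 2 for 3 networks).
#' @param cores For `type1_modules()`, the core list from [extract_cores()].
#' @return `extract_cores()`: list of character vectors (sorted gene sets),
#'   ordered lexicographically.  `type1_modules()` / `type2_modules()`:
#'   tibble with `module_type`, `genes` (list), `core` (list; `NULL` for
#'   type 2) and `linkers` (list of linker genes in the module).
#' @export
extract_cores <- function(N, core_weight = NULL) {
  tw <- consensus_thresholds(N, core_weight, core_weight %||% -1L)
  g3 <- igraph::subgraph_from_edges(
    N$graph, igraph::E(N$graph)[igraph::E(N$graph)$weight == tw$core],
    delete.vertices = TRUE)
  if (igraph::ecount(g3) == 0L) return(list())
  comp <- igraph::components(g3)
  cores <- lapply(seq_len(comp$no), function(i) {
    sort(igraph::V(g3)$name[comp$membership == i])
  })
  cores[order(vapply(cores, `[[`, "", 1L))]
}

#' @rdname extract_cores
#' @export
type1_modules <- function(N, cores = NULL, core_weight = NULL,
                          extend_weight = NULL) {
  tw <- consensus_thresholds(N, core_weight, extend_weight)
  cores <- cores %||% extract_cores(N, core_weight = tw$core)
  if (length(cores) == 0L) {
    return(empty_consensus_modules())
  }
  g <- N$graph
  ends2 <- igraph::as_edgelist(g)[igraph::E(g)$weight == tw$extend, ,
                                  drop = FALSE]
  ext <- lapply(cores, function(core) {
    a_in <- ends2[, 1] %in% core; b_in <- ends2[, 2] %in% core
    one_end <- xor(a_in, b_in)
    sort(unique(c(ends2[one_end & b_in, 1], ends2[one_end & a_in, 2])))
  })
  counts <- table(unlist(ext, use.names = FALSE))
  linkers <- names(counts)[counts > 1L]
  tibble::tibble(
    module_type = 1L,
    genes = purrr::map2(cores, ext, ~ sort(unique(c(.x, .y)))),
    core = cores,
    linkers = lapply(ext, function(e) intersect(e, linkers))
  )
}

#' @rdname extract_cores
#' @export
type2_modules <- function(N, core_weight = NULL, extend_weight = NULL) {
  tw <- consensus_thresholds(N, core_weight, extend_weight)
  keep <- names(N$node_weight)[N$node_weight < tw$core]
  gp <- igraph::induced_subgraph(N$graph, keep)
  g2 <- igraph::subgraph_from_edges(
    gp, igraph::E(gp)[igraph::E(gp)$weight == tw$extend],
    delete.vertices = TRUE)
  if (igraph::ecount(g2) == 0L) return(empty_consensus_modules())
  comp <- igraph::components(g2)
  mods <- lapply(seq_len(comp$no), function(i) {
    sort(igraph::V(g2)$name[comp$membership == i])
  })
  mods <- mods[order(vapply(mods, `[[`, "", 1L))]
  tibble::tibble(module_type = 2L, genes = mods,
                 core = vector("list", length(mods)),
                 linkers = vector("list", length(mods)))
}

empty_consensus_modules <- function() {
  tibble::tibble(module_type = integer(), genes = list(), core = list(),
                 linkers = list())
}

#' End-to-end consensus over single predictions
#'
#' Convenience wrapper: [pair_indicators()] then [build_consensus()],
#' [extract_cores()], [type1_modules()] and [type2_modules()].
#'
#' @inheritParams pair_indicators
#' @inheritParams extract_cores
#' @param n_networks Number of networks (default: distinct labels present).
#' @return A list with `network` (the `covex_consensus_net`), `cores`, and
#'   `modules` (tibble of type 1 and type 2 consensus modules).
#' @export
consensus_modules <- function(solutions, n_networks = NULL,
                              core_weight = NULL, extend_weight = NULL) {
  ind <- pair_indicators(solutions)
  N <- build_consensus(ind, n_networks = n_networks)
  cores <- extract_cores(N, core_weight = core_weight)
  mods <- dplyr::bind_rows(
    type1_modules(N, cores = cores, core_weight = core_weight,
                  extend_weight = extend_weight),
    type2_modules(N, core_weight = core_weight,
                  extend_weight = extend_weight)
  )
  list(network = N, cores = cores, modules = mods)
}
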