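#' Insulated heat-diffusion influence matrix
#'
#' Runs the insulated heat diffusion (random walk with restart) on an
#' interaction network: \eqn{F = \beta (I - (1-\beta)\bar W)^{-1}} where
#' \eqn{\bar W} is the column-degree-normalized adjacency matrix and
#' \eqn{\beta} the restart probability.  `F[i, j]` measures the influence of
#' node `j` on node `i`; the matrix is generally asymmetric.  Each column of
#' `F` sums to 1 and the diagonal dominates (`F[i, i] >= beta`).
#'
#' @param net An undirected `igraph` interaction network with named vertices.
#' @param beta Restart probability in (0, 1).  Default 0.4, the value
#'   commonly used for human interactomes of this size.
#' @return An `influence_matrix` (dense numeric, genes x genes).
#' @export
compute_influence <- function(net, beta = 0.4) {
  if (!igraph::is_igraph(net)) abort("`net` must be an igraph graph")
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) ||
      beta <= 0 || beta >= 1) {
    abort("`beta` must be a single number in (0, 1)")
  }
  deg <- igraph::degree(net)
  if (any(deg == 0)) {
    abort(sprintf("isolated node(s) in network: %s",
                  paste(head(names(deg)[deg == 0], 5), collapse = ", ")))
  }
  adj <- as.matrix(igraph::as_adjacency_matrix(net, sparse = TRUE))
  Wbar <- sweep(adj, 2, colSums(adj), "/")
  n <- nrow(Wbar)
  Fmat <- beta * solve(diag(n) - (1 - beta) * Wbar)
  Fmat[Fmat < 0] <- 0  # guard against tiny negative round-off
  dimnames(Fmat) <- list(igraph::V(net)$name, igraph::V(net)$name)
  new_influence_matrix(Fmat)
}

#' Weighted influence graph over the mutated genes
#'
#' Builds the undirected influence graph on a set of (mutated) genes: the
#' weight of edge \eqn{(g_i, g_j)} is \eqn{\min\{F(i,j), F(j,i)\}}, the more
#' conservative of the two directed influences.  Pairs with weight exactly 0
#' are omitted, as are self-loops.
#'
#' @param Fmat An `influence_matrix` (see [compute_influence()]).
#' @param mutated Character vector of gene symbols; must all be present in
#'   `Fmat`.
#' @return A weighted undirected `igraph` graph on `mutated`.
#' @export
build_influence_graph <- function(Fmat, mutated) {
  mutated <- sort(unique(mutated))
  missing <- setdiff(mutated, colnames(Fmat))
  if (length(missing)) {
    abort(sprintf("gene(s) absent from influence matrix: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  sub <- unclass(Fmat)[mutated, mutated, drop = FALSE]
  W <- pmin(sub, t(sub))
  diag(W) <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  g
}

#' Reduce an influence graph to a target average degree
#'
#' Removes all edges lighter than a threshold \eqn{\delta}, with
#' \eqn{\delta} chosen so that the reduced graph has average degree
#' `target_avg_degree` (default 15, approximately the average degree of a
#' real protein-interaction network).  Implemented as an exact edge-count
#' cut: the \eqn{E^* = \lceil \mathrm{target} \cdot n / 2 \rceil} heaviest
#' edges are kept, ties broken by lexicographic endpoint pair, and
#' \eqn{\delta} is recorded as the weight of the lightest kept edge.  If the
#' graph has fewer positive-weight edges than \eqn{E^*} it is returned
#' unchanged with a warning.
#'
#' @param G A weighted `igraph` influence graph.
#' @param target_avg_degree Desired average node degree (default 15).
#' @return The reduced `igraph` graph, with graph attributes `delta` (the
#'   threshold) and `target_avg_degree`.
#' @export
reduce_graph <- function(G, target_avg_degree = 15) {
  n <- igraph::vcount(G)
  if (n == 0L) abort("empty graph")
  e_star <- ceiling(target_avg_degree * n / 2)
  m <- igraph::ecount(G)
  if (m <= e_star) {
    if (m < e_star) {
      warn(sprintf(
        "graph has %d edges, fewer than the %d needed for average degree %g; keeping all",
        m, e_star, target_avg_degree))
    }
    delta <- if (m > 0) min(igraph::E(G)$weight) else NA_real_
    G <- igraph::set_graph_attr(G, "delta", delta)
    return(igraph::set_graph_attr(G, "target_avg_degree", target_avg_degree))
  }
  ends <- igraph::as_edgelist(G, names = TRUE)
  a <- pmin(ends[, 1], ends[, 2]); b <- pmax(ends[, 1], ends[, 2])
  w <- igraph::E(G)$weight
  ord <- order(-w, a, b)
  keep <- ord[seq_len(e_star)]
  delta <- w[keep[e_star]]
  Gr <- igraph::subgraph_from_edges(G, igraph::E(G)[keep], delete.vertices = FALSE)
  Gr <- igraph::set_graph_attr(Gr, "delta", delta)
  igraph::set_graph_attr(Gr, "target_avg_degree", target_avg_degree)
}

#' Extract the local network rooted at a gene
#'
#' Breadth-first search from `root` over the reduced influence graph.  Whole
#' BFS levels are added while the total stays within `cap`; if the next
#' level would overflow, its nodes are added in descending order of their
#' maximum edge weight to the already-included set (lexicographic
#' tie-break) until the size reaches `cap`.  The search never goes beyond
#' `radius` levels.
#'
#' @param Gr A (reduced) weighted `igraph` graph.
#' @param root Gene symbol of the root node.
#' @param cap Maximum number of nodes in the local network (default 300).
#' @param radius Maximum BFS depth (default `Inf`: the cap alone governs).
#' @return Character vector of member genes; the root comes first, the rest
#'   sorted.  Attribute `root` carries the root symbol.
#' @export
extract_local_network <- function(Gr, root, cap = 300L, radius = Inf) {
  bfs <- bfs_structures(Gr)
  local_network_members(bfs, root, cap = cap, radius = radius)
}

# Precompute adjacency structures once so per-root BFS is cheap.
bfs_structures <- function(Gr) {
  vn <- igraph::V(Gr)$name
  adj <- lapply(igraph::as_adj_list(Gr, mode = "all"), as.integer)
  has_w <- "weight" %in% igraph::edge_attr_names(Gr)
  Wadj <- igraph::as_adjacency_matrix(
    Gr, attr = if (has_w) "weight" else NULL, sparse = TRUE)
  list(vn = vn, adj = adj, Wadj = Wadj)
}

local_network_members <- function(bfs, root, cap = 300L, radius = Inf) {
  vn <- bfs$vn
  ri <- match(root, vn)
  if (is.na(ri)) abort(sprintf("unknown root gene: %s", root))
  members <- ri
  frontier <- ri
  depth <- 0
  while (length(members) < cap && depth < radius) {
    level_idx <- setdiff(unique(unlist(bfs$adj[frontier], use.names = FALSE)),
                         members)
    if (length(level_idx) == 0L) break
    level_idx <- level_idx[order(vn[level_idx])]
    room <- cap - length(members)
    if (length(level_idx) <= room) {
      members <- c(members, level_idx)
      frontier <- level_idx
      depth <- depth + 1
    } else {
      # overflow level: rank nodes by their strongest tie to the included set
      sub <- as.matrix(bfs$Wadj[level_idx, members, drop = FALSE])
      best_w <- apply(sub, 1, max)
      ord <- order(-best_w, vn[level_idx])
      members <- c(members, level_idx[ord][seq_len(room)])
      break
    }
  }
  structure(c(root, sort(vn[setdiff(members, ri)])), root = root)
}
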