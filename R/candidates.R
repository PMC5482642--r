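#' Exact optimization of the Dendrix weight around a root gene
#'
#' Solves, exactly, the binary program behind phase 1: over all gene sets
#' `M` drawn from `universe` that contain the root `v` and have
#' `|M| <= k`, maximize
#' \eqn{W(M) = (1+\lambda)|\Gamma(M)| - \lambda \sum_{g \in M} |\Gamma(g)|}.
#' Ties are broken by smaller module size, then lexicographically on the
#' sorted gene list, so results are fully deterministic.
#'
#' The search is a branch-and-bound over subsets containing `v`.  Because
#' the marginal gain of a gene can only shrink as the module grows, genes
#' whose marginal gain is not positive can be discarded permanently (a set
#' containing such a gene is always dominated by the same set without it
#' under the tie-break), and the sum of the top remaining gains bounds any
#' completion.  With `k <= 5` and local universes of a few hundred genes the
#' exact optimum is found in milliseconds.
#'
#' @param A A [mutation_matrix()].
#' @param universe Character vector of genes the module may draw from (the
#'   root's local network).  Must be columns of `A`.
#' @param root The root gene `v`, forced into the module.
#' @param k Maximum module size (`k >= 1`).
#' @param lam Trade-off \eqn{\lambda \ge 0}.
#' @param graph Optional `igraph` graph over (a superset of) `universe`.
#'   Required when `require_connected = TRUE`.
#' @param require_connected If `TRUE`, only modules that induce a connected
#'   subgraph of `graph` are feasible.  The default (`FALSE`) mirrors the
#'   plain program, where topological relatedness comes only from the
#'   local-network restriction.
#' @return A one-row tibble with columns `root`, `k`, `lambda`, `genes`
#'   (list-column, sorted), `W`.
#' @export
solve_root_blp <- function(A, universe, root, k, lam = 0,
                           graph = NULL, require_connected = FALSE) {
  if (k < 1) abort("`k` must be at least 1")
  if (lam < 0) abort("`lam` must be nonnegative")
  check_genes(A, universe)
  if (!root %in% universe) abort(sprintf("root %s not in universe", root))
  universe <- sort(unique(universe))
  adj <- NULL
  if (require_connected) {
    if (is.null(graph)) abort("`require_connected` needs `graph`")
    sub_g <- igraph::induced_subgraph(graph, intersect(igraph::V(graph)$name,
                                                       universe))
    vn <- igraph::V(sub_g)$name
    al <- igraph::as_adj_list(sub_g, mode = "all")
    adj <- setNames(lapply(al, function(v) match(vn[as.integer(v)], universe)),
                    vn)[universe]
    adj <- lapply(adj, function(x) x[!is.na(x)])
  }
  fit <- bb_search(unclass(A)[, universe, drop = FALSE],
                  root_idx = match(root, universe),
                  k = as.integer(k), lam = lam, adj = adj)
  tibble::tibble(root = root, k = as.integer(k), lambda = lam,
                 genes = list(fit$genes), W = fit$W)
}

# Branch-and-bound core.  `sub` is the m x n 0/1 matrix over the universe;
# `adj` (optional) an adjacency list of universe indices for connected mode.
bb_search <- function(sub, root_idx, k, lam, adj = NULL) {
  storage.mode(sub) <- "double"
  gene_names <- colnames(sub)
  gammas <- colSums(sub)
  eps <- 1e-9
  best <- new.env(parent = emptyenv())
  best$W <- -Inf; best$size <- Inf; best$genes <- character()

  consider <- function(sel, W) {
    gset <- gene_names[sel]
    gset <- gset[order(gset)]
    if (W > best$W + eps ||
        (abs(W - best$W) <= eps &&
         (length(sel) < best$size ||
          (length(sel) == best$size && lex_less(gset, best$genes))))) {
      best$W <- W; best$size <- length(sel); best$genes <- gset
    }
  }

  recurse <- function(sel, covered, W, allowed) {
    consider(sel, W)
    if (length(sel) >= k || length(allowed) == 0L) return(invisible())
    newcov <- if (any(!covered)) {
      colSums(sub[!covered, allowed, drop = FALSE])
    } else {
      numeric(length(allowed))
    }
    gains <- unname((1 + lam) * newcov - lam * gammas[allowed])
    r <- k - length(sel)
    if (is.null(adj)) {
      # A gene whose marginal gain is not positive has non-positive gain in
      # every extension (gains only shrink), so any set containing it is
      # dominated under the (W, size, lex) tie-break: drop it permanently.
      pos <- gains > eps
      allowed <- allowed[pos]; gains <- gains[pos]
      if (length(allowed) == 0L) return(invisible())
      ord <- order(-gains, gene_names[allowed])
      allowed <- allowed[ord]; gains <- gains[ord]
      n_all <- length(allowed)
      for (i in seq_len(n_all)) {
        ub <- W + sum(gains[i:min(i + r - 1L, n_all)])
        if (ub < best$W - eps) break
        g <- allowed[i]
        recurse(c(sel, g),
                covered | (sub[, g] > 0),
                W + gains[i],
                if (i < n_all) allowed[(i + 1L):n_all] else integer())
      }
    } else {
      # Connected mode: a non-positive-gain gene may still be needed as a
      # bridge, and non-adjacent genes stay available for deeper levels, so
      # no dominance drop and no positional break.
      cand_ok <- allowed %in% unique(unlist(adj[sel], use.names = FALSE))
      ord <- order(-gains, gene_names[allowed])
      allowed <- allowed[ord]; gains <- gains[ord]; cand_ok <- cand_ok[ord]
      n_all <- length(allowed)
      exc <- rep(FALSE, n_all)
      for (i in seq_len(n_all)) {
        if (!cand_ok[i]) next        # deferred: remains available below
        rest <- gains[!exc & seq_len(n_all) != i]
        rest <- rest[rest > eps]
        ub <- W + gains[i] +
          sum(rest[seq_len(min(r - 1L, length(rest)))])
        if (ub >= best$W - eps) {
          g <- allowed[i]
          recurse(c(sel, g),
                  covered | (sub[, g] > 0),
                  W + gains[i],
                  allowed[!exc & seq_len(n_all) != i])
        }
        exc[i] <- TRUE
      }
    }
    invisible()
  }

  w0 <- (1 + lam) * gammas[root_idx] - lam * gammas[root_idx]
  recurse(root_idx, sub[, root_idx] > 0, unname(w0),
          setdiff(seq_along(gene_names), root_idx))
  list(genes = best$genes, W = best$W)
}

lex_less <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Exhaustive oracle for the root-module optimum
#'
#' Enumerates every subset of `universe` that contains `root` and has at
#' most `k` genes, scores each with [dendrix_weight()], and returns the
#' maximizer under the same (higher `W`, smaller size, lexicographic)
#' tie-break as [solve_root_blp()].  Exponential; refuses universes beyond
#' 20 genes.  Intended as an independent correctness check.
#'
#' @inheritParams solve_root_blp
#' @return A one-row tibble like [solve_root_blp()].
#' @export
brute_force_best_module <- function(A, universe, root, k, lam = 0) {
  universe <- sort(unique(universe))
  if (length(universe) > 20L) abort("universe too large for enumeration (> 20)")
  if (!root %in% universe) abort(sprintf("root %s not in universe", root))
  if (k < 1) abort("`k` must be at least 1")
  others <- setdiff(universe, root)
  best <- list(W = -Inf, genes = character())
  for (extra in 0:min(k - 1, length(others))) {
    sets <- if (extra == 0) list(character()) else
      combn(others, extra, simplify = FALSE)
    for (s in sets) {
      M <- sort(c(root, s))
      W <- dendrix_weight(A, M, lam)
      if (W > best$W + 1e-9 ||
          (abs(W - best$W) <= 1e-9 &&
           (length(M) < length(best$genes) ||
            (length(M) == length(best$genes) && lex_less(M, best$genes))))) {
        best <- list(W = W, genes = M)
      }
    }
  }
  tibble::tibble(root = root, k = as.integer(k), lambda = lam,
                 genes = list(best$genes), W = best$W)
}

#' Enumerate candidate modules: one exact optimum per root gene
#'
#' For every node of the reduced influence graph, extracts the root's local
#' network ([extract_local_network()]) and solves the root's program with
#' [solve_root_blp()].  Results are deduplicated by gene set, keeping the
#' provenance of the first root (in sorted gene order) that produced each
#' set.
#'
#' @param Gr Reduced influence `igraph` graph; its nodes define the roots.
#' @param A A [mutation_matrix()] restricted to the nodes of `Gr` (see
#'   [restrict_to_network()]).
#' @inheritParams solve_root_blp
#' @param cap Local-network size cap (default 300).
#' @return A tibble of candidate modules: `root`, `k`, `lambda`, `genes`
#'   (list-column), `W`, one row per distinct gene set.
#' @export
enumerate_candidates <- function(Gr, A, k, lam = 0, cap = 300L,
                                 require_connected = FALSE) {
  roots <- sort(igraph::V(Gr)$name)
  missing <- setdiff(roots, colnames(A))
  if (length(missing)) {
    abort(sprintf("graph node(s) missing from mutation matrix: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  bfs <- bfs_structures(Gr)
  rows <- lapply(roots, function(v) {
    members <- local_network_members(bfs, v, cap = cap)
    tryCatch(
      solve_root_blp(A, members, v, k = k, lam = lam,
                     graph = if (require_connected) Gr else NULL,
                     require_connected = require_connected),
      error = function(e) {
        abort(sprintf("candidate search failed at root %s: %s",
                      v, conditionMessage(e)))
      })
  })
  out <- dplyr::bind_rows(rows)
  key <- vapply(out$genes, paste, "", collapse = ";")
  out[!duplicated(key), , drop = FALSE]
}
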