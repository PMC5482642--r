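#' Coverage, exclusivity and the CovEx score of a module
#'
#' A patient with exactly one mutated gene in a module is a *module
#' exclusive patient*.  For each gene the *exclusive ratio* is the number of
#' module exclusive patients mutated in that gene divided by the number of
#' all patients mutated in that gene; `Ex` is the mean of those ratios over
#' the module's genes.  `Cov` is the fraction of the cohort with at least
#' one mutated module gene, and `CovEx = Cov * Ex` is the combined score
#' used for filtering.  All three live in `[0, 1]`.
#'
#' @param A A [mutation_matrix()].
#' @param M Character vector of module genes, each mutated in at least one
#'   patient.
#' @return `module_exclusive_patients()`: character vector of patient
#'   identifiers.  `exclusivity_ex()`, `coverage_cov()`, `covex_score()`: a
#'   number in `[0, 1]`.
#' @examples
#' A <- mutation_matrix(data.frame(patient = c("P1", "P2", "P2"),
#'                                 gene    = c("G1", "G1", "G2")))
#' module_exclusive_patients(A, c("G1", "G2"))  # P1 only
#' covex_score(A, c("G1", "G2"))
#' @export
module_exclusive_patients <- function(A, M) {
  check_genes(A, M)
  cnt <- rowSums(unclass(A)[, M, drop = FALSE])
  rownames(A)[cnt == 1L]
}

#' @rdname module_exclusive_patients
#' @export
exclusivity_ex <- function(A, M) {
  module_stats(A, M)$Ex
}

#' @rdname module_exclusive_patients
#' @export
coverage_cov <- function(A, M) {
  check_genes(A, M)
  coverage(A, M) / nrow(A)
}

#' @rdname module_exclusive_patients
#' @export
covex_score <- function(A, M) {
  s <- module_stats(A, M)
  s$Cov * s$Ex
}

# One pass over the module's submatrix; errors on zero-mutation genes.
module_stats <- function(A, M) {
  check_genes(A, M)
  sub <- unclass(A)[, M, drop = FALSE]
  gam <- colSums(sub)
  if (any(gam == 0L)) {
    abort(sprintf("gene(s) with no mutations: %s",
                  paste(M[gam == 0L], collapse = ", ")))
  }
  cnt <- rowSums(sub)
  excl <- cnt == 1L
  ratios <- colSums(sub[excl, , drop = FALSE]) / gam
  list(Cov = sum(cnt > 0L) / nrow(A), Ex = mean(ratios),
       ratios = unname(ratios))
}

#' Annotate a module table with Cov, Ex and CovEx
#'
#' @param modules A tibble with a `genes` list-column (e.g. from
#'   [enumerate_candidates()]).
#' @param A A [mutation_matrix()].
#' @return `modules` with numeric columns `Cov`, `Ex`, `CovEx` added.
#' @export
score_modules <- function(modules, A) {
  stats <- lapply(modules$genes, function(M) module_stats(A, M))
  modules$Cov <- vapply(stats, `[[`, 1, "Cov")
  modules$Ex <- vapply(stats, `[[`, 1, "Ex")
  modules$CovEx <- modules$Cov * modules$Ex
  modules
}

#' Empirical null distribution of CovEx over random connected subnetworks
#'
#' Samples `n_samples` connected subnetworks of size `k` from the reduced
#' influence graph and records their CovEx scores.  The sampler picks a
#' uniform start node and repeatedly adds the outside endpoint of a
#' uniformly chosen boundary edge (an edge with exactly one endpoint in the
#' current set) until the set has `k` nodes, restarting from a fresh start
#' node on dead ends.
#'
#' @param Gr Reduced influence `igraph` graph; nodes must be columns of `A`.
#' @param A A [mutation_matrix()].
#' @param k Subnetwork size (the module size whose null this is).
#' @param n_samples Number of subnetworks (default 100000).
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `covex_null`: list with `k`, `scores`
#'   (numeric, length `n_samples`), `n_samples`, `seed`.
#' @export
sample_null <- function(Gr, A, k, n_samples = 100000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vn <- igraph::V(Gr)$name
  missing <- setdiff(vn, colnames(A))
  if (length(missing)) {
    abort(sprintf("graph node(s) missing from mutation matrix: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  comp_big <- max(igraph::components(Gr)$csize)
  if (k > comp_big) {
    abort(sprintf("no connected subnetwork of size %d (largest component: %d)",
                  k, comp_big))
  }
  adj <- lapply(igraph::as_adj_list(Gr, mode = "all"), as.integer)
  n <- length(vn)
  eligible <- if (k > 1) which(lengths(adj) > 0L) else seq_len(n)
  picks <- matrix(0L, n_samples, k)
  for (s in seq_len(n_samples)) {
    repeat {
      S <- eligible[sample.int(length(eligible), 1L)]
      while (length(S) < k) {
        nb <- unlist(adj[S], use.names = FALSE)
        nb <- nb[!(nb %in% S)]       # boundary edges, with multiplicity
        if (length(nb) == 0L) break  # dead end: restart
        S <- c(S, nb[sample.int(length(nb), 1L)])
      }
      if (length(S) == k) break
    }
    picks[s, ] <- sort(S)
  }
  keys <- apply(picks, 1, paste, collapse = ",")
  uk <- !duplicated(keys)
  Amat <- unclass(A)[, vn, drop = FALSE]
  uniq_scores <- vapply(which(uk), function(i) {
    sub <- Amat[, picks[i, ], drop = FALSE]
    gam <- colSums(sub)
    cnt <- rowSums(sub)
    ok <- gam > 0L
    ex <- if (any(ok)) {
      mean(colSums(sub[cnt == 1L, ok, drop = FALSE]) / gam[ok])
    } else 0
    (sum(cnt > 0L) / nrow(sub)) * ex
  }, 1)
  scores <- unname(uniq_scores[match(keys, keys[uk])])
  structure(list(k = as.integer(k), scores = scores,
                 n_samples = as.integer(n_samples), seed = seed),
            class = "covex_null")
}

#' @export
print.covex_null <- function(x, ...) {
  cat(sprintf("<covex_null> k = %d, %d samples, CovEx range [%.4g, %.4g]\n",
              x$k, x$n_samples, min(x$scores), max(x$scores)))
  invisible(x)
}

#' Empirical p-value of a CovEx score against a null distribution
#'
#' Uses the add-one estimator \eqn{p = (1 + \#\{null \ge score\}) /
#' (n + 1)}, so p is never zero and ties with null values count against the
#' candidate.
#'
#' @param score Numeric vector of CovEx scores.
#' @param null A `covex_null` from [sample_null()].
#' @return Numeric vector of p-values in `(0, 1]`.
#' @export
empirical_p <- function(score, null) {
  if (!inherits(null, "covex_null")) abort("`null` must come from sample_null()")
  n <- length(null$scores)
  if (n == 0L) abort("empty null distribution")
  sorted <- sort(null$scores)
  n_lt <- findInterval(score, sorted, left.open = TRUE)
  (1 + (n - n_lt)) / (n + 1)
}

#' Filter candidate modules on exclusivity and CovEx significance
#'
#' Keeps candidates with `Ex >= ex_min` (default 0.8) and empirical CovEx
#' p-value `<= p_max` (default 0.05) against the null for their size.
#' Survivors carry their `Cov`, `Ex`, `CovEx` and `p_value` annotations.
#'
#' @param cands Candidate tibble with a `genes` list-column (see
#'   [enumerate_candidates()]).
#' @param nulls A single `covex_null` or a list of them covering every
#'   module size present in `cands` (list names are ignored; sizes are read
#'   from the objects).
#' @param A A [mutation_matrix()].
#' @param ex_min Exclusivity threshold (modules below it are removed
#'   regardless of p-value).
#' @param p_max Significance threshold on the empirical p-value.
#' @return The filtered, annotated candidate tibble.
#' @export
filter_candidates <- function(cands, nulls, A, ex_min = 0.8, p_max = 0.05) {
  if (inherits(nulls, "covex_null")) nulls <- list(nulls)
  null_by_k <- setNames(nulls, vapply(nulls, function(x) as.character(x$k), ""))
  cands <- score_modules(cands, A)
  sizes <- lengths(cands$genes)
  missing <- setdiff(unique(sizes), as.integer(names(null_by_k)))
  if (length(missing)) {
    abort(sprintf("no null distribution for module size(s): %s",
                  paste(sort(missing), collapse = ", ")))
  }
  cands$p_value <- vapply(seq_len(nrow(cands)), function(i) {
    empirical_p(cands$CovEx[i], null_by_k[[as.character(sizes[i])]])
  }, 1)
  cands[cands$Ex >= ex_min & cands$p_value <= p_max, , drop = FALSE]
}
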