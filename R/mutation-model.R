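#' Combinatorial quantities on the mutation matrix
#'
#' For a gene `g`, `gamma_patients()` returns the support
#' \eqn{\Gamma(g) = \{i : a_{ig} = 1\}}, the set of patients in which `g` is
#' mutated.  For a gene set `M`:
#' \itemize{
#'   \item `coverage(A, M)` is \eqn{|\Gamma(M)| = |\cup_{g \in M} \Gamma(g)|},
#'     the number of patients with at least one mutated module gene;
#'   \item `coverage_overlap(A, M)` is
#'     \eqn{\omega(M) = \sum_{g \in M} |\Gamma(g)| - |\Gamma(M)|}, the excess
#'     mutation count beyond one per covered patient (0 iff the gene supports
#'     are pairwise disjoint);
#'   \item `dendrix_weight(A, M, lam)` is
#'     \eqn{W(M) = |\Gamma(M)| - \lambda\,\omega(M)
#'          = (1+\lambda)|\Gamma(M)| - \lambda \sum_{g \in M} |\Gamma(g)|},
#'     trading coverage against overlap with \eqn{\lambda \ge 0}.
#' }
#'
#' @param A A [mutation_matrix()].
#' @param g A gene symbol (column of `A`).
#' @param M Character vector of gene symbols (a module).
#' @param lam Exclusivity trade-off \eqn{\lambda \ge 0}.
#' @return `gamma_patients()`: character vector of patient identifiers.
#'   The others: a single number.
#' @examples
#' A <- mutation_matrix(data.frame(patient = c("P1", "P1", "P2"),
#'                                 gene    = c("G1", "G2", "G1")))
#' gamma_patients(A, "G1")
#' coverage(A, c("G1", "G2"))
#' dendrix_weight(A, c("G1", "G2"), lam = 1)
#' @export
gamma_patients <- function(A, g) {
  check_genes(A, g)
  rownames(A)[A[, g] == 1L]
}

#' @rdname gamma_patients
#' @export
coverage <- function(A, M) {
  check_genes(A, M)
  sum(rowSums(unclass(A)[, M, drop = FALSE]) > 0L)
}

#' @rdname gamma_patients
#' @export
coverage_overlap <- function(A, M) {
  check_genes(A, M)
  sum(unclass(A)[, M, drop = FALSE]) - coverage(A, M)
}

#' @rdname gamma_patients
#' @export
dendrix_weight <- function(A, M, lam = 0) {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0) {
    abort("`lam` must be a single nonnegative number")
  }
  check_genes(A, M)
  sub <- unclass(A)[, M, drop = FALSE]
  cov <- sum(rowSums(sub) > 0L)
  (1 + lam) * cov - lam * sum(sub)
}

check_genes <- function(A, M) {
  if (length(M) == 0L) abort("empty gene set")
  missing <- setdiff(M, colnames(A))
  if (length(missing)) {
    abort(sprintf("gene(s) not in mutation matrix: %s",
                  paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}
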