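#' Greedy minimum set cover of patients by significant modules
#'
#' The universe `I` is the set of patients covered by the union of all the
#' supplied (significant) modules.  Modules are selected greedily: at each
#' step the module covering the largest number of still-uncovered patients
#' is chosen, with ties broken by higher CovEx and then by lexicographic
#' gene list.  The number of newly covered patients at selection time (the
#' *marginal*) is recorded per chosen module; it drives the s-module logic.
#'
#' @param modules Tibble of significant modules with a `genes` list-column;
#'   a `CovEx` column, when present, is used for tie-breaking.
#' @param A A [mutation_matrix()].
#' @return An object of class `covex_cover`: list with `chosen` (the input
#'   rows in selection order, plus a `marginal` integer column), and
#'   `universe` (the covered patient identifiers).
#' @export
greedy_cover <- function(modules, A) {
  if (nrow(modules) == 0L) abort("no modules to cover with")
  supports <- lapply(modules$genes, function(M) which(
    rowSums(unclass(A)[, M, drop = FALSE]) > 0L))
  universe <- sort(unique(unlist(supports, use.names = FALSE)))
  covex <- if ("CovEx" %in% names(modules)) modules$CovEx else
    rep(0, nrow(modules))
  gene_keys <- vapply(modules$genes, paste, "", collapse = ";")
  uncovered <- universe
  order_sel <- integer()
  marginal <- integer()
  remaining <- seq_len(nrow(modules))
  while (length(uncovered) > 0L && length(remaining) > 0L) {
    gains <- vapply(remaining, function(i) {
      sum(supports[[i]] %in% uncovered)
    }, 0L)
    if (max(gains) == 0L) break  # cannot happen when universe is the union
    ord <- order(-gains, -covex[remaining], gene_keys[remaining])
    pick <- remaining[ord[1]]
    order_sel <- c(order_sel, pick)
    marginal <- c(marginal, max(gains))
    uncovered <- setdiff(uncovered, supports[[pick]])
    remaining <- setdiff(remaining, pick)
  }
  chosen <- modules[order_sel, , drop = FALSE]
  chosen$marginal <- marginal
  structure(list(chosen = chosen, universe = rownames(A)[universe]),
            class = "covex_cover")
}

#' @export
print.covex_cover <- function(x, ...) {
  cat(sprintf("<covex_cover> %d modules covering %d patients\n",
              nrow(x$chosen), length(x$universe)))
  invisible(x)
}

#' @export
tidy.covex_cover <- function(x, ...) {
  out <- x$chosen
  out$step <- seq_len(nrow(out))
  out$module <- vapply(out$genes, paste, "", collapse = ";")
  dplyr::relocate(out, "step", "module")
}

#' @export
glance.covex_cover <- function(x, ...) {
  tibble::tibble(n_modules = nrow(x$chosen),
                 n_patients = length(x$universe),
                 max_marginal = max(x$chosen$marginal),
                 min_marginal = min(x$chosen$marginal))
}

#' Classify and filter s-modules
#'
#' A chosen module is an *s-module* if it covered at most `s` previously
#' uncovered patients when the greedy cover selected it.  `classify_s_modules()`
#' flags them; `filter_s_modules()` drops them (keeping the original
#' selection order and intentionally sacrificing full coverage of the
#' universe).
#'
#' @param sol A `covex_cover` from [greedy_cover()].
#' @param s Nonnegative integer threshold on the marginal coverage.
#' @return `classify_s_modules()`: the chosen-module tibble with a logical
#'   `s_module` column.  `filter_s_modules()`: the tibble of retained
#'   modules (marginal `> s`).
#' @export
classify_s_modules <- function(sol, s) {
  if (!inherits(sol, "covex_cover")) abort("`sol` must come from greedy_cover()")
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0) {
    abort("`s` must be a single nonnegative integer")
  }
  out <- sol$chosen
  out$s_module <- out$marginal <= s
  out
}

#' @rdname classify_s_modules
#' @export
filter_s_modules <- function(sol, s) {
  cls <- classify_s_modules(sol, s)
  cls[!cls$s_module, setdiff(names(cls), "s_module"), drop = FALSE]
}
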