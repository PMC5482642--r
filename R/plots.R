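#' Plot methods
#'
#' `autoplot.mutation_matrix()` draws the classic mutation waterfall: a
#' patient-by-gene tile plot, optionally restricted to a module.
#' `autoplot.covex_null()` shows the null CovEx distribution with optional
#' observed scores overlaid.  `autoplot.covex_cover()` shows the marginal
#' coverage of each greedily chosen module (non-increasing by
#' construction); modules at or below an `s` threshold are the s-modules.
#'
#' @param object The object to plot.
#' @param genes Optional character vector restricting the matrix plot to a
#'   module's genes.
#' @param observed Optional numeric vector of observed CovEx scores to mark.
#' @param s Optional s-module threshold drawn as a horizontal line.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @name covex-plots
NULL

#' @rdname covex-plots
#' @export
autoplot.mutation_matrix <- function(object, genes = NULL, ...) {
  if (!is.null(genes)) {
    check_genes(object, genes)
    object <- new_mutation_matrix(unclass(object)[, genes, drop = FALSE])
  }
  ev <- tidy(object)
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$gene, y = .data$patient)) +
    ggplot2::geom_tile(fill = "#2c7fb8") +
    ggplot2::scale_y_discrete(limits = rev(rownames(object))) +
    ggplot2::labs(x = NULL, y = NULL, title = "Mutation matrix") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @rdname covex-plots
#' @export
autoplot.covex_null <- function(object, observed = NULL, ...) {
  df <- tibble::tibble(CovEx = object$scores)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$CovEx)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey65") +
    ggplot2::labs(
      title = sprintf("Null CovEx distribution (size %d, %d samples)",
                      object$k, object$n_samples),
      x = "CovEx", y = "count") +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_vline(xintercept = observed, colour = "#d7301f",
                                 linetype = "dashed")
  }
  p
}

#' @rdname covex-plots
#' @export
autoplot.covex_cover <- function(object, s = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$step,
                                        y = .data$marginal)) +
    ggplot2::geom_col(fill = "#31a354") +
    ggplot2::labs(title = "Greedy cover: newly covered patients per module",
                  x = "selection step", y = "marginal coverage") +
    ggplot2::theme_minimal()
  if (!is.null(s)) {
    p <- p + ggplot2::geom_hline(yintercept = s + 0.5, colour = "#d7301f",
                                 linetype = "dashed")
  }
  p
}
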