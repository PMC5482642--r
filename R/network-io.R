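#' Read a protein-interaction network from an edge list
#'
#' Expects two (optionally three, the third a positive edge weight)
#' whitespace-separated columns per line.  Lines starting with `#` are
#' comments.  The graph is made simple: self-loops are dropped with a
#' warning and repeated edges are merged (weights: maximum of the
#' duplicates).  Gene symbols are normalized to uppercase.
#'
#' @param path Path to the edge-list file.
#' @return An undirected simple `igraph` graph with vertex attribute `name`
#'   and edge attribute `weight` (1 where no weight column is given).
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) abort(sprintf("no edges in %s", path))
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    abort(sprintf("malformed edge line %d in %s (need 2 columns)", bad[1], path))
  }
  a <- normalize_symbols(vapply(parts, `[[`, "", 1L))
  b <- normalize_symbols(vapply(parts, `[[`, "", 2L))
  if (any(a == "#") || any(b == "#")) {
    abort("a node named '#' collides with the comment sentinel")
  }
  w <- vapply(parts, function(p) {
    if (length(p) >= 3L) suppressWarnings(as.numeric(p[3])) else 1
  }, 1)
  if (anyNA(w)) abort("non-numeric edge weight")
  loops <- a == b
  if (any(loops)) {
    warn(sprintf("dropped %d self-loop(s) from %s", sum(loops), path))
    a <- a[!loops]; b <- b[!loops]; w <- w[!loops]
  }
  if (length(a) == 0L) {
    return(igraph::make_empty_graph(directed = FALSE))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, weight = w), directed = FALSE)
  igraph::simplify(g, edge.attr.comb = list(weight = "max"))
}

#' Read a benchmark gene list (one symbol per line)
#'
#' @param path Path to the gene list.
#' @param name Label for the list (default: the file name).
#' @return A list with fields `name` and `genes` (sorted unique uppercase
#'   symbols).
#' @export
read_gene_set <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  g <- normalize_symbols(lines)
  g <- sort(unique(g[nzchar(g)]))
  if (length(g) == 0L) abort(sprintf("empty gene list: %s", path))
  list(name = name, genes = g)
}

#' Read / write a dense influence matrix TSV
#'
#' The format has a header row of gene symbols, one row per gene with the
#' gene symbol in the first column, and `F[i, j]` = influence of gene `j`
#' on gene `i`.  Precomputed influence matrices from heat-diffusion releases
#' can be reused this way.
#'
#' @param path File path.
#' @return For `read_influence_matrix()`, an `influence_matrix`: a dense
#'   nonnegative square numeric matrix with identical row and column names.
#' @export
read_influence_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) abort(sprintf("no influence rows in %s", path))
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  gene_names <- normalize_symbols(header[-1])
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  bad <- which(lengths(body) != length(header))
  if (length(bad)) abort(sprintf("malformed influence row %d in %s", bad[1] + 1L, path))
  rn <- normalize_symbols(vapply(body, `[[`, "", 1L))
  vals <- t(vapply(body, function(p) as.numeric(p[-1]), numeric(length(gene_names))))
  if (length(gene_names) == 1L) vals <- matrix(vals, ncol = 1L)
  dimnames(vals) <- list(rn, gene_names)
  if (!identical(rownames(vals), colnames(vals))) {
    abort("influence matrix rows and columns must name the same genes in the same order")
  }
  new_influence_matrix(vals)
}

#' @rdname read_influence_matrix
#' @param Fmat An `influence_matrix`.
#' @export
write_influence_matrix <- function(Fmat, path) {
  header <- paste(c("gene", colnames(Fmat)), collapse = "\t")
  rows <- vapply(seq_len(nrow(Fmat)), function(i) {
    paste(c(rownames(Fmat)[i], format(Fmat[i, ], digits = 17, trim = TRUE)),
          collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}

new_influence_matrix <- function(mat) {
  if (any(mat < 0) || any(!is.finite(mat))) {
    abort("influence matrix entries must be finite and nonnegative")
  }
  structure(mat, class = c("influence_matrix", "matrix", "array"))
}
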