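#' Binary patient-by-gene mutation matrix
#'
#' `mutation_matrix()` builds the central data structure of the package: a
#' binary incidence matrix `A` with `m` rows (patients) and `n` columns
#' (genes), where `A[i, j] = 1` means gene `j` carries a somatic aberration
#' in patient `i`.  Input is either a long-form data frame of mutation events
#' (one row per observed patient/gene pair, first column patients, second
#' column gene symbols) or an already-binary numeric matrix with patient row
#' names and gene column names.
#'
#' Gene symbols are normalized to uppercase and stripped of surrounding
#' whitespace; duplicate events collapse to a single 1; rows and columns are
#' sorted so all downstream tie-breaks are reproducible.
#'
#' @param x A data frame with columns `patient` and `gene` (names are
#'   positional: the first two columns are used), or a binary matrix with
#'   dimnames.
#' @return An object of class `mutation_matrix`: an integer 0/1 matrix with
#'   sorted, unique patient row names and gene column names.
#' @examples
#' events <- data.frame(patient = c("P1", "P1", "P2"),
#'                      gene    = c("TP53", "KRAS", "TP53"))
#' A <- mutation_matrix(events)
#' unclass(A)
#' @export
mutation_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort("a mutation matrix needs patient row names and gene column names")
    }
    if (!all(x %in% c(0, 1))) {
      abort("mutation matrix entries must all be 0 or 1")
    }
    mat <- x
    colnames(mat) <- normalize_symbols(colnames(mat))
    storage.mode(mat) <- "integer"
    if (anyDuplicated(rownames(mat))) abort("duplicate patient identifiers")
    if (anyDuplicated(colnames(mat))) abort("duplicate gene identifiers")
    mat <- mat[order(rownames(mat)), order(colnames(mat)), drop = FALSE]
    return(new_mutation_matrix(mat))
  }
  if (!is.data.frame(x) || ncol(x) < 2) {
    abort("`x` must be a matrix or a data frame with patient and gene columns")
  }
  pats  <- trimws(as.character(x[[1]]))
  genes <- normalize_symbols(as.character(x[[2]]))
  keep <- nzchar(pats) & nzchar(genes)
  if (!any(keep)) abort("no mutation events in input")
  pats <- pats[keep]; genes <- genes[keep]
  up <- sort(unique(pats)); ug <- sort(unique(genes))
  mat <- matrix(0L, length(up), length(ug), dimnames = list(up, ug))
  mat[cbind(match(pats, up), match(genes, ug))] <- 1L
  new_mutation_matrix(mat)
}

new_mutation_matrix <- function(mat) {
  structure(mat, class = c("mutation_matrix", "matrix", "array"))
}

normalize_symbols <- function(x) toupper(trimws(x))

#' @export
print.mutation_matrix <- function(x, ...) {
  cat(sprintf("<mutation_matrix> %d patients x %d genes, %d events\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' List the patients / genes of a mutation matrix
#' @param A A [mutation_matrix()].
#' @return Character vector of identifiers, in matrix order.
#' @export
patients <- function(A) rownames(A)

#' @rdname patients
#' @export
genes <- function(A) colnames(A)

#' @export
tidy.mutation_matrix <- function(x, ...) {
  idx <- which(x == 1L, arr.ind = TRUE)
  tibble::tibble(patient = rownames(x)[idx[, 1]],
                 gene    = colnames(x)[idx[, 2]]) |>
    dplyr::arrange(.data$patient, .data$gene)
}

#' @export
glance.mutation_matrix <- function(x, ...) {
  tibble::tibble(
    n_patients = nrow(x),
    n_genes = ncol(x),
    n_events = sum(x),
    mean_mutations_per_patient = sum(x) / nrow(x)
  )
}

#' Read a mutation table into a binary matrix
#'
#' Three dialects are supported.  `"long"`: headerless two-column
#' tab-separated `patient<TAB>gene` event lists (the format distributed with
#' pan-cancer heat-diffusion releases).  `"maf"`: a MAF-lite table with
#' columns `Tumor_Sample_Barcode` and `Hugo_Symbol` (case-insensitive;
#' `Variant_Classification`, when present, is filtered against
#' `exclude_classes`).  `"binary"`: a dense 0/1 TSV whose header row names
#' the genes and whose first column names the patients.
#'
#' @param path Path to the input file.
#' @param format One of `"long"`, `"maf"`, `"binary"`.
#' @param exclude_classes For MAF input, variant classifications that do not
#'   count as mutation events.  Default `"Silent"`.
#' @return A [mutation_matrix()].
#' @export
read_mutation_table <- function(path, format = c("long", "maf", "binary"),
                                exclude_classes = "Silent") {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(sprintf("empty mutation input: %s", path))
  switch(format,
    long = {
      parts <- strsplit(lines, "\t", fixed = TRUE)
      bad <- which(lengths(parts) < 2L)
      if (length(bad)) {
        abort(sprintf("malformed long-form line %d in %s (need 2 tab-separated fields)",
                      bad[1], path))
      }
      mutation_matrix(data.frame(
        patient = vapply(parts, `[[`, "", 1L),
        gene    = vapply(parts, `[[`, "", 2L)
      ))
    },
    maf = {
      header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
      lh <- tolower(header)
      si <- match("tumor_sample_barcode", lh)
      gi <- match("hugo_symbol", lh)
      vi <- match("variant_classification", lh)
      if (is.na(si) || is.na(gi)) {
        abort("MAF input needs Tumor_Sample_Barcode and Hugo_Symbol columns")
      }
      body <- strsplit(lines[-1], "\t", fixed = TRUE)
      if (length(body) == 0L) abort(sprintf("no MAF records in %s", path))
      need <- max(si, gi, if (!is.na(vi)) vi else 0L)
      bad <- which(lengths(body) < need)
      if (length(bad)) {
        abort(sprintf("malformed MAF line %d in %s", bad[1] + 1L, path))
      }
      sample <- vapply(body, `[[`, "", si)
      gene   <- vapply(body, `[[`, "", gi)
      if (!is.na(vi)) {
        cls <- vapply(body, `[[`, "", vi)
        keep <- !(tolower(cls) %in% tolower(exclude_classes))
        sample <- sample[keep]; gene <- gene[keep]
      }
      if (length(sample) == 0L) abort("all MAF records filtered out")
      mutation_matrix(data.frame(patient = sample, gene = gene))
    },
    binary = {
      header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
      gene_names <- header[-1]
      if (length(gene_names) == 0L) abort("binary TSV has no gene columns")
      body <- strsplit(lines[-1], "\t", fixed = TRUE)
      if (length(body) == 0L) abort(sprintf("no data rows in %s", path))
      bad <- which(lengths(body) != length(header))
      if (length(bad)) {
        abort(sprintf("malformed binary TSV line %d in %s (expected %d fields)",
                      bad[1] + 1L, path, length(header)))
      }
      pats <- vapply(body, `[[`, "", 1L)
      vals <- t(vapply(body, function(p) {
        v <- suppressWarnings(as.integer(p[-1]))
        if (anyNA(v) || !all(v %in% c(0L, 1L))) {
          abort("binary TSV entries must be 0 or 1")
        }
        v
      }, integer(length(gene_names))))
      if (length(gene_names) == 1L) vals <- matrix(vals, ncol = 1L)
      dimnames(vals) <- list(pats, gene_names)
      mutation_matrix(vals)
    }
  )
}

#' Write a mutation matrix
#'
#' @param A A [mutation_matrix()].
#' @param path Output path.
#' @param format `"binary"` (dense TSV, round-trips exactly through
#'   [read_mutation_table()]) or `"long"` (event list; all-zero columns are
#'   not representable in this dialect).
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(A, path, format = c("binary", "long")) {
  format <- match.arg(format)
  if (format == "binary") {
    header <- paste(c("patient", colnames(A)), collapse = "\t")
    rows <- vapply(seq_len(nrow(A)), function(i) {
      paste(c(rownames(A)[i], A[i, ]), collapse = "\t")
    }, "")
    writeLines(c(header, rows), path)
  } else {
    ev <- tidy(A)
    writeLines(paste(ev$patient, ev$gene, sep = "\t"), path)
  }
  invisible(path)
}

#' Restrict a mutation matrix to the genes of an interaction network
#'
#' Keeps only genes that are present in both the matrix and the network and
#' are mutated in at least one patient.  Patients are left intact even if
#' they end up with all-zero rows (such patients simply cannot be covered by
#' any module).
#'
#' @param A A [mutation_matrix()].
#' @param net An igraph network (or a character vector of gene symbols).
#' @return A [mutation_matrix()] over the gene intersection.
#' @export
restrict_to_network <- function(A, net) {
  universe <- if (igraph::is_igraph(net)) igraph::V(net)$name else
    normalize_symbols(as.character(net))
  keep <- colnames(A) %in% universe & colSums(A) > 0L
  if (!any(keep)) {
    abort("no mutated genes of the matrix appear in the network")
  }
  new_mutation_matrix(unclass(A)[, keep, drop = FALSE])
}
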