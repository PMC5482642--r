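#' Write a module report (TSV plus JSON twin)
#'
#' One module per row: genes joined by `;`, then `k`, `lambda`, `W`,
#' `Cov`, `Ex`, `CovEx`, `p_value`, `source`.  Rows are ordered by
#' descending CovEx with lexicographic gene-list tie-break, so reports are
#' byte-stable.  A machine-readable JSON twin (same base name, `.json`
#' extension) is written alongside and round-trips through
#' [read_modules_report()].
#'
#' @param modules Tibble of modules with a `genes` list-column; score
#'   columns that are absent are written as `NA`.
#' @param dest Path of the TSV report.
#' @return `dest`, invisibly.
#' @export
write_modules_report <- function(modules, dest) {
  cols <- c("k", "lambda", "W", "Cov", "Ex", "CovEx", "p_value", "source")
  out <- tibble::tibble(
    genes = vapply(modules$genes %||% list(), paste, "", collapse = ";"))
  for (cl in cols) {
    out[[cl]] <- if (cl %in% names(modules)) modules[[cl]] else
      rep(NA, nrow(out))
  }
  if (nrow(out)) {
    key_covex <- if (all(is.na(out$CovEx))) rep(0, nrow(out)) else out$CovEx
    out <- out[order(-key_covex, out$genes), , drop = FALSE]
  }
  header <- paste(c("genes", cols), collapse = "\t")
  lines <- vapply(seq_len(nrow(out)), function(i) {
    paste(vapply(out[i, ], function(v) {
      if (is.na(v)) "NA" else format(v, digits = 15, trim = TRUE)
    }, ""), collapse = "\t")
  }, "")
  con <- tryCatch(file(dest, "w"), error = function(e) {
    abort(sprintf("cannot write report to %s: %s", dest, conditionMessage(e)))
  })
  on.exit(close(con))
  writeLines(c(header, lines), con)
  json_path <- paste0(sub("\\.[A-Za-z0-9]+$", "", dest), ".json")
  recs <- lapply(seq_len(nrow(out)), function(i) {
    c(list(genes = strsplit(out$genes[i], ";", fixed = TRUE)[[1]]),
      lapply(out[i, cols], identity))
  })
  jsonlite::write_json(recs, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(dest)
}

#' Read a module report back from its JSON twin
#'
#' @param path Path to the `.json` report written by
#'   [write_modules_report()].
#' @return A module tibble with a `genes` list-column and the score
#'   columns.
#' @export
read_modules_report <- function(path) {
  recs <- jsonlite::read_json(path)
  cols <- c("k", "lambda", "W", "Cov", "Ex", "CovEx", "p_value", "source")
  if (length(recs) == 0L) {
    out <- tibble::tibble(genes = list())
    for (cl in cols) out[[cl]] <- if (cl == "source") character() else numeric()
    return(out)
  }
  tibble::tibble(
    genes = lapply(recs, function(r) unlist(r$genes)),
    k = vapply(recs, function(r) as.integer(r$k %||% NA_integer_), 1L),
    lambda = vapply(recs, function(r) as.numeric(r$lambda %||% NA_real_), 1),
    W = vapply(recs, function(r) as.numeric(r$W %||% NA_real_), 1),
    Cov = vapply(recs, function(r) as.numeric(r$Cov %||% NA_real_), 1),
    Ex = vapply(recs, function(r) as.numeric(r$Ex %||% NA_real_), 1),
    CovEx = vapply(recs, function(r) as.numeric(r$CovEx %||% NA_real_), 1),
    p_value = vapply(recs, function(r) as.numeric(r$p_value %||% NA_real_), 1),
    source = vapply(recs, function(r) as.character(r$source %||% NA_character_), "")
  )
}
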