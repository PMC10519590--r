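#' Construct an expression matrix object
#'
#' A genes-by-cells expression matrix with named dimensions and a record of
#' which transform has been applied. This is the container every other stage
#' consumes: rows are genes (and become the nodes of the prior graph, with the
#' row itself serving as the node feature vector), columns are cells.
#'
#' @param values Numeric matrix, genes in rows, cells in columns. Must carry
#'   unique, non-empty `rownames` (genes) and `colnames` (cells).
#' @param transform One of `"raw_counts"`, `"log_cpm"`, `"log_tpm"`,
#'   `"log_expression"`. `"raw_counts"` additionally requires all values >= 0.
#' @return An object of class `expr_mat`: the numeric matrix with a
#'   `transform` attribute.
#' @export
expression_matrix <- function(values,
                              transform = c("raw_counts", "log_cpm", "log_tpm",
                                            "log_expression")) {
  transform <- match.arg(transform)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x cells).")
  }
  genes <- rownames(values)
  cells <- colnames(values)
  if (is.null(genes) || is.null(cells) || any(genes == "") || any(cells == "")) {
    abort("`values` must have non-empty rownames (genes) and colnames (cells).")
  }
  if (anyDuplicated(genes)) {
    abort(sprintf("duplicate gene name(s): %s",
                  paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  }
  if (anyDuplicated(cells)) {
    abort(sprintf("duplicate cell name(s): %s",
                  paste(unique(cells[duplicated(cells)]), collapse = ", ")))
  }
  if (!all(is.finite(values))) abort("expression values must all be finite.")
  if (transform == "raw_counts" && any(values < 0)) {
    abort("raw counts must be non-negative.")
  }
  structure(values, transform = transform, class = c("expr_mat", "matrix", "array"))
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d genes x %d cells [%s]\n",
              nrow(x), ncol(x), attr(x, "transform")))
  n <- min(5L, nrow(x)); m <- min(5L, ncol(x))
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE])
  invisible(x)
}

#' Transform state of an expression matrix
#' @param expr An [expression_matrix()].
#' @return A string, e.g. `"raw_counts"` or `"log_cpm"`.
#' @export
transform_state <- function(expr) attr(expr, "transform")

#' Read an expression matrix from a comma-separated file
#'
#' Expects the genes-by-cells dialect used by single-cell GRN benchmarks: a
#' header row of cell IDs whose first field is empty (or `"gene"`), then one
#' row per gene with the gene name in the first column.
#'
#' @param path File path.
#' @param transform Transform state to record; files are assumed to hold raw
#'   counts unless told otherwise.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, transform = "raw_counts") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(tab) < 2L) abort("expression file needs a gene column plus >= 1 cell column.")
  genes <- tab[[1L]]
  if (anyDuplicated(genes)) {
    abort(sprintf("duplicate gene name(s) in %s: %s", path,
                  paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  }
  cells <- colnames(tab)[-1L]
  vals <- suppressWarnings(
    vapply(tab[-1L], as.numeric, numeric(length(genes)))
  )
  vals <- matrix(vals, nrow = length(genes),
                 dimnames = list(genes, cells))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    abort(sprintf("non-numeric value at gene '%s' (row %d), cell '%s' (column %d).",
                  genes[bad[1L]], bad[1L], cells[bad[2L]], bad[2L]))
  }
  expression_matrix(vals, transform = transform)
}

#' Write an expression matrix to a comma-separated file
#'
#' Inverse of [read_expression()]: header row of cell IDs with an empty first
#' field, one row per gene. Values are written with enough digits to
#' round-trip doubles exactly.
#'
#' @param expr An [expression_matrix()].
#' @param path Output path.
#' @param digits Significant digits (default 15, enough for exact
#'   double round-trips in practice; use fewer for compact files).
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, digits = 15) {
  vals <- unclass(expr)
  lines <- c(
    paste0(",", paste(colnames(vals), collapse = ",")),
    vapply(seq_len(nrow(vals)), function(i) {
      paste0(rownames(vals)[i], ",",
             paste(formatC(vals[i, ], digits = digits, format = "g"),
                   collapse = ","))
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a transcription-factor name list
#'
#' Plain text, one symbol per line; `#` starts a comment; blank lines ignored.
#'
#' @param path File path.
#' @return Character vector of unique TF names in file order.
#' @export
read_tf_list <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}
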