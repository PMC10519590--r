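#' Construct a ground-truth regulatory network
#'
#' A directed, optionally signed edge set over a fixed gene universe. Signs
#' follow the usual convention: `+1` activating, `-1` inhibitory.
#'
#' @param edges A data frame with columns `regulator`, `target` and optionally
#'   `sign` (values in `c(-1, 1)`).
#' @param gene_universe Ordered character vector of all genes the network is
#'   defined over. Defaults to the genes appearing in `edges`.
#' @return A `grn_network`: a tibble of edges with attributes `gene_universe`
#'   and `signed`.
#' @export
grn_network <- function(edges, gene_universe = NULL) {
  edges <- as_tibble(edges)
  if (!all(c("regulator", "target") %in% names(edges))) {
    abort("`edges` needs columns `regulator` and `target`.")
  }
  edges$regulator <- as.character(edges$regulator)
  edges$target <- as.character(edges$target)
  if (any(edges$regulator == edges$target)) {
    abort("self-regulating edges are not allowed in a ground-truth network.")
  }
  if (anyDuplicated(paste(edges$regulator, edges$target, sep = "\r"))) {
    abort("duplicate edges in network.")
  }
  signed <- "sign" %in% names(edges)
  if (signed) {
    edges$sign <- as.integer(edges$sign)
    if (!all(edges$sign %in% c(-1L, 1L))) abort("`sign` must be -1 or +1.")
  }
  if (is.null(gene_universe)) {
    gene_universe <- unique(c(rbind(edges$regulator, edges$target)))
  }
  if (anyDuplicated(gene_universe)) abort("`gene_universe` has duplicates.")
  missing <- setdiff(unique(c(edges$regulator, edges$target)), gene_universe)
  if (length(missing)) {
    abort(sprintf("edge endpoint(s) outside gene universe: %s",
                  paste(missing, collapse = ", ")))
  }
  structure(edges,
            gene_universe = gene_universe,
            signed = signed,
            class = c("grn_network", class(edges)))
}

#' @export
print.grn_network <- function(x, ...) {
  cat(sprintf("<grn_network> %d edges over %d genes (%s), density %.3f\n",
              nrow(x), length(attr(x, "gene_universe")),
              if (isTRUE(attr(x, "signed"))) "signed" else "unsigned",
              network_density(x)))
  NextMethod()
}

#' Gene universe of a network
#' @param network A [grn_network()].
#' @return Character vector of gene names.
#' @export
gene_universe <- function(network) attr(network, "gene_universe")

#' Edge density of a directed network
#'
#' Number of edges divided by the number of ordered non-self gene pairs
#' `M (M - 1)`.
#'
#' @param network A [grn_network()].
#' @return A number in (0, 1].
#' @export
network_density <- function(network) {
  m <- length(attr(network, "gene_universe"))
  nrow(network) / (m * (m - 1))
}

#' Read a regulatory edge list
#'
#' Comma-separated `regulator,target[,sign]` rows, with an optional header
#' (`Gene1,Gene2[,Type]`). Sign tokens may be `+`/`-` or `1`/`-1`/`+1`.
#' Self-edge rows are skipped; their count is reported as a warning and kept
#' in the `n_self_skipped` attribute.
#'
#' @param path File path.
#' @param gene_universe Optional explicit gene universe (e.g. all genes of the
#'   matched expression matrix); defaults to the genes seen in the file.
#' @return A [grn_network()].
#' @export
read_network <- function(path, gene_universe = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort(sprintf("empty network file: %s", path))
  first <- tolower(strsplit(lines[[1L]], ",")[[1L]][1L])
  if (first %in% c("gene1", "regulator", "tf", "source")) lines <- lines[-1L]
  fields <- strsplit(lines, ",")
  nf <- lengths(fields)
  if (any(nf < 2L | nf > 3L)) {
    abort("network rows must have 2 or 3 comma-separated fields.")
  }
  reg <- trimws(vapply(fields, `[[`, character(1), 1L))
  tgt <- trimws(vapply(fields, `[[`, character(1), 2L))
  sgn <- rep(NA_integer_, length(fields))
  has3 <- nf == 3L
  if (any(has3)) {
    tok <- trimws(vapply(fields[has3], `[[`, character(1), 3L))
    parsed <- c("+" = 1L, "+1" = 1L, "1" = 1L, "-" = -1L, "-1" = -1L)[tok]
    if (anyNA(parsed)) {
      abort(sprintf("unknown sign token(s): %s",
                    paste(unique(tok[is.na(parsed)]), collapse = ", ")))
    }
    sgn[has3] <- parsed
  }
  self <- reg == tgt
  if (any(self)) {
    warn(sprintf("skipped %d self-edge row(s) in %s", sum(self), path))
    reg <- reg[!self]; tgt <- tgt[!self]; sgn <- sgn[!self]
  }
  edges <- tibble(regulator = reg, target = tgt)
  if (all(!is.na(sgn)) && length(sgn)) edges$sign <- sgn
  out <- grn_network(dplyr::distinct(edges), gene_universe = gene_universe)
  attr(out, "n_self_skipped") <- sum(self)
  out
}

#' Write a ranked edge list
#'
#' Writes `Gene1,Gene2,Score` rows in descending absolute score, ties broken
#' lexicographically by (regulator, target) — the package-wide deterministic
#' edge order.
#'
#' @param ranked A tibble with columns `regulator`, `target`, `score`
#'   (as produced by [infer_grn()]).
#' @param path Output path.
#' @param digits Significant digits for scores (default 6).
#' @return `path`, invisibly.
#' @export
write_ranked_edges <- function(ranked, path, digits = 6) {
  ranked <- rank_edge_list(ranked)
  lines <- c("Gene1,Gene2,Score",
             sprintf("%s,%s,%s", ranked$regulator, ranked$target,
                     formatC(ranked$score, digits = digits, format = "g")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a ranked edge list written by [write_ranked_edges()]
#' @param path File path.
#' @return A tibble `regulator`, `target`, `score`, in ranked order.
#' @export
read_ranked_edges <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- tibble(regulator = as.character(tab[[1L]]),
                target = as.character(tab[[2L]]),
                score = as.numeric(tab[[3L]]))
  rank_edge_list(out)
}

#' Order an edge table into the canonical ranked form
#'
#' Descending absolute score; ties resolved lexicographically by
#' (regulator, target) so that outputs are reproducible byte for byte.
#'
#' @param edges Tibble with `regulator`, `target`, `score`.
#' @return The same tibble, reordered.
#' @export
rank_edge_list <- function(edges) {
  edges <- as_tibble(edges)[, c("regulator", "target", "score")]
  ord <- order(-abs(edges$score), edges$regulator, edges$target, method = "radix")
  edges[ord, ]
}
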