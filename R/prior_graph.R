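#' Spearman rank correlation matrix between genes
#'
#' Computes the gene-by-gene Spearman correlation across cells: the Pearson
#' correlation of rank vectors, with ties given average (fractional) ranks.
#' A gene with zero rank variance (constant across cells) carries no
#' co-expression evidence; its correlations with every other gene are set to
#' 0 with a warning rather than erroring, so dropout-heavy matrices never
#' crash the pipeline. The diagonal is 1 by definition.
#'
#' @param expr A log-transformed [expression_matrix()] with at least 2 genes
#'   and 3 cells. (Spearman correlations are rank-based, so any strictly
#'   monotone transform of the values gives the identical matrix.)
#' @return A symmetric matrix of class `corr_mat` with unit diagonal and
#'   entries in `[-1, 1]`, gene names on both dimensions.
#' @export
spearman_matrix <- function(expr) {
  vals <- unclass(expr)
  if (nrow(vals) < 2L) abort("need at least 2 genes.")
  if (ncol(vals) < 3L) abort("need at least 3 cells.")
  r <- suppressWarnings(stats::cor(t(vals), method = "spearman"))
  if (anyNA(r)) {
    const <- apply(vals, 1L, function(x) length(unique(x)) == 1L)
    warn(sprintf("%d constant gene(s); their correlations set to 0: %s",
                 sum(const),
                 paste(utils::head(rownames(vals)[const], 5L), collapse = ", ")))
    r[is.na(r)] <- 0
  }
  diag(r) <- 1
  structure(r, class = c("corr_mat", "matrix", "array"))
}

#' Build the weighted co-expression prior graph
#'
#' Converts a correlation matrix into the prior regulatory graph driving the
#' graph autoencoder: edge weights are absolute correlations (optionally
#' thresholded), the diagonal is zeroed, self-loops of weight 1 are added,
#' and the GCN "renormalized" adjacency
#' \eqn{\hat A = \tilde D^{-1/2} \tilde A \tilde D^{-1/2}} is cached.
#'
#' @param corr A [spearman_matrix()] result (or any symmetric correlation
#'   matrix with gene names).
#' @param threshold Minimum absolute correlation for an edge, in `[0, 1)`.
#'   Default 0: retain every correlation.
#' @return A list of class `prior_graph`: `A` (weighted adjacency, zero
#'   diagonal), `A_tilde` (`A + I`), `D_tilde` (degree vector of `A_tilde`),
#'   `A_hat` (renormalized adjacency), `R_signed` (the signed correlations
#'   with zero diagonal, the reconstruction target of the autoencoder),
#'   `threshold`, `gene_names`.
#' @export
build_prior_graph <- function(corr, threshold = 0) {
  stopifnot_scalar_number(threshold, "threshold")
  if (threshold < 0 || threshold >= 1) abort("`threshold` must be in [0, 1).")
  r <- unclass(corr)
  if (!isTRUE(all.equal(r, t(r), tolerance = 1e-8))) {
    abort("correlation matrix must be symmetric.")
  }
  if (max(abs(r)) > 1 + 1e-8) abort("correlations must lie in [-1, 1].")
  a <- abs(r)
  a[a < threshold] <- 0
  diag(a) <- 0
  a_tilde <- a + diag(nrow(a))
  d_tilde <- rowSums(a_tilde)
  inv_sqrt <- 1 / sqrt(d_tilde)
  a_hat <- a_tilde * tcrossprod(inv_sqrt)
  r_signed <- r
  diag(r_signed) <- 0
  r_signed[a == 0] <- 0  # thresholded edges carry no prior signal
  structure(list(A = a, A_tilde = a_tilde, D_tilde = d_tilde, A_hat = a_hat,
                 R_signed = r_signed,
                 threshold = threshold, gene_names = rownames(r)),
            class = "prior_graph")
}

#' @export
print.prior_graph <- function(x, ...) {
  m <- length(x$gene_names)
  cat(sprintf("<prior_graph> %d genes, %d weighted edges (threshold %.2f)\n",
              m, sum(x$A > 0) / 2, x$threshold))
  invisible(x)
}

#' Renormalized adjacency of a prior graph
#'
#' Returns \eqn{\hat A = \tilde D^{-1/2}(A + I)\tilde D^{-1/2}}, the
#' symmetric GCN propagation matrix. Self-loops guarantee every degree is at
#' least 1, so the inverse square root always exists.
#'
#' @param graph A [build_prior_graph()] result.
#' @return A symmetric numeric matrix with entries in `[0, 1]`.
#' @export
renormalized_adjacency <- function(graph) graph$A_hat

#' Export prior-graph edges as a tibble
#'
#' One row per undirected co-expression edge with positive weight, for
#' inspection or writing as `Gene1,Gene2,Weight`.
#'
#' @param graph A [build_prior_graph()] result.
#' @return A tibble `gene1`, `gene2`, `weight` (gene1 < gene2, weight > 0),
#'   ordered by descending weight then lexicographically.
#' @export
prior_graph_edges <- function(graph) {
  a <- graph$A
  idx <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  out <- tibble(gene1 = graph$gene_names[idx[, 1L]],
                gene2 = graph$gene_names[idx[, 2L]],
                weight = a[idx])
  out[order(-out$weight, out$gene1, out$gene2, method = "radix"), ]
}
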