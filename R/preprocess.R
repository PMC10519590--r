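#' Filter low-quality cells and sparsely detected genes
#'
#' Drops cells detecting fewer than `min_cell_detected_genes` genes, then
#' keeps genes with nonzero expression in at least `min_gene_cell_fraction`
#' of the retained cells. The two filters are interleaved until a fixed point
#' so the operation is idempotent.
#'
#' The gene filter defaults to 10% of cells. Requiring detection in the vast
#' majority of cells (e.g. 90%) is also expressible via
#' `min_gene_cell_fraction = 0.9`, but with typical scRNA-seq sparsity that
#' retains almost nothing, so the permissive default is used.
#'
#' @param expr An [expression_matrix()] of raw counts.
#' @param min_gene_cell_fraction Fraction of retained cells in which a gene
#'   must be nonzero, in `[0, 1]`. Default 0.1.
#' @param min_cell_detected_genes Minimum number of detected (nonzero) genes
#'   per cell. Default 1 (drop empty cells only).
#' @return A filtered [expression_matrix()], original row/column order kept.
#' @export
filter_genes_cells <- function(expr, min_gene_cell_fraction = 0.1,
                               min_cell_detected_genes = 1L) {
  if (transform_state(expr) != "raw_counts") {
    abort("filter_genes_cells() expects raw counts (filter before normalizing).")
  }
  stopifnot_scalar_number(min_gene_cell_fraction, "min_gene_cell_fraction")
  if (min_gene_cell_fraction < 0 || min_gene_cell_fraction > 1) {
    abort("`min_gene_cell_fraction` must be in [0, 1].")
  }
  vals <- unclass(expr)
  repeat {
    keep_cells <- colSums(vals > 0) >= min_cell_detected_genes
    vals2 <- vals[, keep_cells, drop = FALSE]
    if (ncol(vals2) == 0L) abort("all cells filtered out.")
    keep_genes <- rowSums(vals2 > 0) >= min_gene_cell_fraction * ncol(vals2)
    vals2 <- vals2[keep_genes, , drop = FALSE]
    if (nrow(vals2) == 0L) abort("all genes filtered out.")
    stable <- identical(dim(vals2), dim(vals))
    vals <- vals2
    if (stable) break
  }
  expression_matrix(vals, transform = "raw_counts")
}

#' Library-size normalize and log-transform
#'
#' Scales each cell to counts-per-million (the `tpm_with_lengths` scheme first
#' divides each gene by its length so the per-million scaling yields TPM),
#' then applies the elementwise natural `log(1 + x)`. Zeros map to zeros.
#'
#' @param expr An [expression_matrix()] of raw counts.
#' @param scheme `"cpm"` (default) or `"tpm_with_lengths"`.
#' @param gene_lengths Named numeric vector of gene lengths (required for the
#'   TPM scheme; names must cover all genes in `expr`).
#' @return An [expression_matrix()] with transform `"log_cpm"` or `"log_tpm"`.
#' @export
normalize_log <- function(expr, scheme = c("cpm", "tpm_with_lengths"),
                          gene_lengths = NULL) {
  scheme <- match.arg(scheme)
  if (transform_state(expr) != "raw_counts") {
    abort("normalize_log() expects raw counts.")
  }
  vals <- unclass(expr)
  if (scheme == "tpm_with_lengths") {
    if (is.null(gene_lengths)) abort("TPM needs `gene_lengths`.")
    len <- gene_lengths[rownames(vals)]
    if (anyNA(len) || any(len <= 0)) {
      abort("`gene_lengths` must cover every gene with a positive length.")
    }
    vals <- vals / as.numeric(len)
  }
  lib <- colSums(vals)
  if (any(lib == 0)) {
    abort(sprintf("zero library-size cell(s): %s",
                  paste(colnames(vals)[lib == 0], collapse = ", ")))
  }
  vals <- log1p(sweep(vals, 2L, lib, "/") * 1e6)
  expression_matrix(vals, transform = if (scheme == "cpm") "log_cpm" else "log_tpm")
}

#' Select transcription factors plus highly variable genes
#'
#' All TFs present in the matrix are kept. Non-TF genes are scanned for excess
#' variance: genes are binned by mean expression, each gene's variance is
#' compared with the median variance of its bin (a robust mean-variance
#' baseline), the standardized dispersion `(N - 1) * var / expected_var` is
#' referred to a chi-square distribution with `N - 1` degrees of freedom, and
#' p-values are Bonferroni-corrected. Significant genes are ranked by
#' dispersion and the top `n_top` join the selection.
#'
#' @param expr A log-transformed [expression_matrix()].
#' @param tf_names Character vector of TF names; genes absent from `expr` are
#'   silently ignored.
#' @param n_top Number of highly variable non-TF genes to keep (default 500).
#' @param alpha Significance level before Bonferroni correction (default 0.01).
#' @return A list of class `gene_selection` with elements `tf_names` (present
#'   TFs), `hvg_names` (ranked HVGs), `selected` (deduplicated union, TFs
#'   first), and `hvg_table` (a tibble with per-gene mean, variance,
#'   dispersion and adjusted p-value).
#' @export
select_variable_genes <- function(expr, tf_names = character(), n_top = 500,
                                  alpha = 0.01) {
  if (transform_state(expr) == "raw_counts") {
    abort("select_variable_genes() expects log-transformed expression.")
  }
  if (n_top < 1) abort("`n_top` must be >= 1.")
  vals <- unclass(expr)
  genes <- rownames(vals)
  tfs_present <- intersect(tf_names, genes)
  n_cells <- ncol(vals)
  mu <- rowMeans(vals)
  v <- apply(vals, 1L, stats::var)
  # expected variance at each gene's mean: median variance of its
  # mean-expression bin (robust to a few highly variable genes)
  n_bins <- max(1L, min(20L, length(genes) %/% 5L))
  expected <- if (n_bins > 1L && stats::sd(mu) > 0) {
    breaks <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
    bin <- cut(mu, breaks = breaks, include.lowest = TRUE)
    med <- tapply(v, bin, stats::median)
    pmax(as.numeric(med[bin]), 1e-12)
  } else {
    rep(max(stats::median(v), 1e-12), length(genes))
  }
  dispersion <- (n_cells - 1) * v / expected
  p <- stats::pchisq(dispersion, df = n_cells - 1, lower.tail = FALSE)
  non_tf <- setdiff(genes, tfs_present)
  p_adj <- pmin(p * length(non_tf), 1)
  tab <- tibble(gene = genes, mean = mu, variance = v,
                dispersion = dispersion, p_adjusted = p_adj)
  cand <- tab[tab$gene %in% non_tf & tab$p_adjusted <= alpha, ]
  cand <- cand[order(-cand$dispersion, cand$gene, method = "radix"), ]
  hvg <- utils::head(cand$gene, n_top)
  structure(list(tf_names = tfs_present,
                 hvg_names = hvg,
                 selected = unique(c(tfs_present, hvg)),
                 hvg_table = tab),
            class = "gene_selection")
}

#' @export
print.gene_selection <- function(x, ...) {
  cat(sprintf("<gene_selection> %d TFs + %d HVGs -> %d genes selected\n",
              length(x$tf_names), length(x$hvg_names), length(x$selected)))
  invisible(x)
}
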