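#' Random k-fold partition of ground-truth edges
#'
#' Splits the positive edges into `k` near-equal, pairwise-disjoint folds for
#' edge-level cross-validation: each fold serves once as the held-out test
#' set while the remainder trains the model, so training and test edges
#' never mix.
#'
#' @param truth A [grn_network()].
#' @param k Number of folds (default 3).
#' @param seed Integer seed; the same seed reproduces the partition.
#' @return A list of class `edge_folds`: `folds` (list of edge tibbles),
#'   `k`, `seed`.
#' @export
kfold_edge_split <- function(truth, k = 3, seed = 1) {
  if (k < 2) abort("`k` must be >= 2.")
  n <- nrow(truth)
  if (n < k) abort(sprintf("need at least %d edges for %d folds.", k, k))
  assignment <- withr::with_seed(as.integer(seed), {
    sample(rep_len(seq_len(k), n))
  })
  folds <- lapply(seq_len(k), function(f) as_tibble(truth)[assignment == f, ])
  structure(list(folds = folds, k = as.integer(k), seed = as.integer(seed)),
            class = "edge_folds")
}

#' Area under the ROC curve
#'
#' Computed exactly as the Mann-Whitney statistic: the probability that a
#' uniformly chosen positive outscores a uniformly chosen negative, with
#' ties counted one half.
#'
#' @param scores Numeric scores, higher meaning more confident positive.
#' @param labels Binary labels (0/1), same length.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) abort("both classes must be present.")
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Steps through score thresholds in descending order (tied scores enter as
#' one block, giving a deterministic curve) and accumulates
#' `sum (R_t - R_{t-1}) * P_t` — the average-precision form of the area.
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) abort("at least one positive is required.")
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1L - y)
  last_of_block <- c(s[-1L] != s[-length(s)], TRUE)
  tp <- tp[last_of_block]; fp <- fp[last_of_block]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Early precision ratio
#'
#' Takes the top `k` predictions (k = number of ground-truth edges inside
#' the evaluation universe), computes their precision against the truth, and
#' divides by the network density — the precision a random predictor attains
#' in expectation — so that a random ranking scores 1 and a perfect one
#' scores `1 / density`.
#'
#' @param ranked A ranked edge tibble (`regulator`, `target`, `score`), as
#'   from [infer_grn()]; only edges inside `eval_universe` are considered.
#' @param truth A [grn_network()].
#' @param eval_universe Optional tibble of `regulator`, `target` pairs
#'   defining the evaluation universe; defaults to all ordered non-self
#'   pairs over the truth's gene universe.
#' @return The EPR, a non-negative number.
#' @export
early_precision_ratio <- function(ranked, truth, eval_universe = NULL) {
  genes <- gene_universe(truth)
  pair_key <- function(a, b) paste(a, b, sep = "\r")
  if (is.null(eval_universe)) {
    grid <- expand.grid(regulator = genes, target = genes,
                        stringsAsFactors = FALSE)
    eval_universe <- grid[grid$regulator != grid$target, ]
  }
  universe_keys <- pair_key(eval_universe$regulator, eval_universe$target)
  truth_keys <- intersect(pair_key(truth$regulator, truth$target), universe_keys)
  k <- length(truth_keys)
  if (k < 1L) abort("no ground-truth edges inside the evaluation universe.")
  ranked <- rank_edge_list(ranked)
  ranked_keys <- pair_key(ranked$regulator, ranked$target)
  ranked_keys <- ranked_keys[ranked_keys %in% universe_keys]
  if (length(ranked_keys) < k) {
    abort(sprintf("ranked list has %d edges in the universe but k = %d.",
                  length(ranked_keys), k))
  }
  top_k <- ranked_keys[seq_len(k)]
  precision <- length(intersect(top_k, truth_keys)) / k
  density <- k / length(universe_keys)
  precision / density
}

#' AUPRC ratio
#'
#' AUPRC divided by the network density, the AUPRC a random predictor
#' attains, so values above 1 beat random.
#'
#' @param auprc_value An AUPRC.
#' @param density Network density in `(0, 1]`.
#' @return The ratio.
#' @export
aupr_ratio <- function(auprc_value, density) {
  if (density <= 0 || density > 1) abort("`density` must be in (0, 1].")
  auprc_value / density
}

#' Root-mean-square error of signed predictions
#'
#' Discretizes the (normalized) score matrix to \{-1, 0, +1\} — sign of the
#' score where its absolute value exceeds `threshold`, else 0 — and compares
#' with signed ground truth labeled +1 (activating), -1 (inhibitory), 0 (no
#' regulation) over all ordered non-self gene pairs.
#'
#' @param scores The signed, `[0, 1]`-normalized score matrix from
#'   [infer_grn()].
#' @param truth A signed [grn_network()].
#' @param threshold Absolute-score cutoff for calling a regulation
#'   (default 0.2, the reporting cutoff).
#' @return The RMSE, a number in `[0, 2]`.
#' @export
signed_rmse <- function(scores, truth, threshold = 0.2) {
  if (!isTRUE(attr(truth, "signed"))) {
    abort("`truth` is unsigned; use auroc()/auprc()/early_precision_ratio() instead.")
  }
  genes <- gene_universe(truth)
  if (!all(genes %in% rownames(scores))) {
    abort("score matrix does not cover the truth's gene universe.")
  }
  s <- scores[genes, genes]
  pred <- sign(s) * (abs(s) > threshold)
  label <- matrix(0, length(genes), length(genes),
                  dimnames = list(genes, genes))
  label[cbind(truth$regulator, truth$target)] <- truth$sign
  off <- row(s) != col(s)
  sqrt(mean((pred[off] - label[off])^2))
}

#' Topology analytics of an inferred or reference network
#'
#' Computes per-gene hub statistics on the directed graph: total and
#' out-degree, exact shortest-path betweenness centrality, PageRank (damping
#' 0.85, converged to 1e-8), closeness and Kleinberg hub score. Genes whose
#' out-degree exceeds a chosen cutoff (20 in the applications) are candidate
#' core regulators.
#'
#' @param network A [grn_network()] or a ranked edge tibble with `regulator`
#'   and `target` columns (scores, if present, are ignored: topology is
#'   computed on the unweighted directed graph).
#' @return A tibble with one row per gene: `gene`, `degree`, `out_degree`,
#'   `betweenness`, `pagerank`, `closeness`, `hub_score`.
#' @export
topology_metrics <- function(network) {
  edges <- as_tibble(network)[, c("regulator", "target")]
  if (!nrow(edges)) abort("empty network.")
  vertices <- if (inherits(network, "grn_network")) gene_universe(network) else
    unique(c(rbind(edges$regulator, edges$target)))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = vertices))
  tibble(gene = vertices,
         degree = as.numeric(igraph::degree(g, mode = "all")),
         out_degree = as.numeric(igraph::degree(g, mode = "out")),
         betweenness = as.numeric(igraph::betweenness(g, directed = TRUE)),
         pagerank = as.numeric(igraph::page_rank(g, damping = 0.85)$vector),
         closeness = as.numeric(igraph::closeness(g, mode = "out")),
         hub_score = as.numeric(igraph::hits_scores(g)$hub))
}
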