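# small in-code fixtures shared across tests

toy_expression <- function(n_genes = 5, n_cells = 20, seed = 1,
                           transform = "log_expression") {
  withr::with_seed(seed, {
    vals <- matrix(stats::rexp(n_genes * n_cells), n_genes, n_cells,
                   dimnames = list(paste0("g", seq_len(n_genes)),
                                   paste0("c", seq_len(n_cells))))
    expression_matrix(vals, transform = transform)
  })
}

toy_counts <- function(n_genes = 6, n_cells = 10, seed = 1) {
  withr::with_seed(seed, {
    vals <- matrix(as.numeric(stats::rpois(n_genes * n_cells, lambda = 5)),
                   n_genes, n_cells,
                   dimnames = list(paste0("g", seq_len(n_genes)),
                                   paste0("c", seq_len(n_cells))))
    expression_matrix(vals, transform = "raw_counts")
  })
}

toy_network <- function() {
  grn_network(
    tibble::tibble(regulator = c("g1", "g2", "g3", "g1"),
                   target = c("g2", "g3", "g4", "g3"),
                   sign = c(1L, -1L, 1L, 1L)),
    gene_universe = paste0("g", 1:5))
}

# brute-force Spearman: explicit rank covariance formula
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# brute-force AUROC: all positive-negative comparisons, ties counted 1/2
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# brute-force AUPRC: explicit threshold sweep over unique scores
oracle_auprc <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  recall_prev <- 0
  area <- 0
  for (t in ths) {
    called <- scores >= t
    tp <- sum(labels == 1 & called)
    precision <- tp / sum(called)
    recall <- tp / sum(labels == 1)
    area <- area + (recall - recall_prev) * precision
    recall_prev <- recall
  }
  area
}

# brute-force betweenness on a small directed graph via path enumeration
oracle_betweenness <- function(edges, vertices) {
  n <- length(vertices)
  adj <- matrix(FALSE, n, n, dimnames = list(vertices, vertices))
  adj[cbind(edges$regulator, edges$target)] <- TRUE
  # all simple paths between s and t by DFS, keep shortest
  shortest_paths <- function(s, t) {
    found <- list(); best <- Inf
    walk <- function(path) {
      last <- path[length(path)]
      if (length(path) - 1 > best) return()
      if (last == t && length(path) > 1) {
        len <- length(path) - 1
        if (len < best) { best <<- len; found <<- list(path) }
        else if (len == best) found[[length(found) + 1]] <<- path
        return()
      }
      for (v in vertices[adj[last, ]]) if (!v %in% path) walk(c(path, v))
    }
    walk(s)
    found
  }
  bw <- stats::setNames(numeric(n), vertices)
  for (s in vertices) for (t in vertices) {
    if (s == t) next
    paths <- shortest_paths(s, t)
    if (!length(paths)) next
    for (p in paths) {
      inner <- setdiff(p, c(s, t))
      for (v in inner) bw[v] <- bw[v] + 1 / length(paths)
    }
  }
  bw
}
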