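#' Hyperparameters for the graph autoencoder
#'
#' Published training defaults: GCN encoder layers of 200 neurons, 500
#' training epochs with early stopping after 10 epochs without validation
#' improvement, Adam with learning rate 0.01, L2 penalty 1e-4 on the first
#' GCN weight matrix, and dropout rate 0.7 on every GCN input (including the
#' expression features, controlled by `dropout_input`).
#'
#' Three further knobs are numerical choices of this implementation (see the
#' methods vignette): `lambda_recon`/`kappa` weight the autoencoder's
#' prior-graph reconstruction term, `neg_replicates` averages the sampled-
#' negative part of the loss over several independent draws (a
#' variance-reduced estimator of the same expected loss), and `min_epochs`
#' lets the optimizer pass its warm-up transient before early stopping may
#' trigger.
#'
#' @param hidden_dims Integer vector of encoder layer widths. Default
#'   `c(200, 200)`.
#' @param epochs Maximum training epochs. Default 500.
#' @param learning_rate Adam learning rate. Default 0.01.
#' @param l2_first_layer L2 penalty on the first GCN weights. Default 1e-4.
#' @param dropout_rate Inverted-dropout rate on GCN layer inputs, in `[0, 1)`.
#'   Default 0.7.
#' @param patience Early-stopping patience in epochs. Default 10.
#' @param seed Integer seed governing initialization, dropout and negative
#'   sampling. Default 1.
#' @param dropout_input Apply dropout to the expression features themselves
#'   (first layer input) during training? Default `TRUE`.
#' @param decoder `"full"` for the full bilinear c-by-c decoder weight
#'   (asymmetric scores, hence directed edges) or `"diagonal"` for a strict
#'   DistMult diagonal weight (symmetric scores).
#' @param val_fraction Fraction of training positives held out as an early
#'   stopping validation set when no explicit validation edges are supplied
#'   to [gae_fit()]. Default 0.1.
#' @param lambda_recon Weight of the prior-graph reconstruction term.
#'   Default 1.
#' @param kappa Score scale of the reconstruction target (`S` is pulled
#'   toward `kappa * r`). Default 3, placing a perfect correlation at
#'   sigmoid(3) = 0.95 edge probability.
#' @param neg_replicates Independent negative-sample draws averaged per
#'   epoch. Default 8.
#' @param min_epochs Epochs guaranteed before early stopping engages.
#'   Default 20.
#' @param feature_norm `"center_unit"` (default) centers each gene's feature
#'   vector and scales it to unit norm before entering the encoder;
#'   `"none"` feeds raw values.
#' @param final_activation Activation of the last encoder layer: `"linear"`
#'   (default, the usual autoencoder embedding layer) or `"relu"`.
#' @return A list of class `gae_params`.
#' @export
gae_params <- function(hidden_dims = c(200L, 200L), epochs = 500L,
                       learning_rate = 0.01, l2_first_layer = 1e-4,
                       dropout_rate = 0.7, patience = 10L, seed = 1L,
                       dropout_input = TRUE, decoder = c("full", "diagonal"),
                       val_fraction = 0.1, lambda_recon = 1, kappa = 3,
                       neg_replicates = 8L, min_epochs = 20L,
                       feature_norm = c("center_unit", "none"),
                       final_activation = c("linear", "relu")) {
  decoder <- match.arg(decoder)
  feature_norm <- match.arg(feature_norm)
  final_activation <- match.arg(final_activation)
  if (!length(hidden_dims) || any(hidden_dims < 1)) {
    abort("`hidden_dims` must be a non-empty vector of positive widths.")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) abort("`dropout_rate` must be in [0, 1).")
  if (epochs < 1 || patience < 1 || learning_rate < 0 || l2_first_layer < 0) {
    abort("`epochs`, `patience` must be >= 1; `learning_rate`, `l2_first_layer` >= 0.")
  }
  if (lambda_recon < 0 || kappa <= 0 || neg_replicates < 1) {
    abort("`lambda_recon` >= 0, `kappa` > 0, `neg_replicates` >= 1 required.")
  }
  structure(list(hidden_dims = as.integer(hidden_dims), epochs = as.integer(epochs),
                 learning_rate = learning_rate, l2_first_layer = l2_first_layer,
                 dropout_rate = dropout_rate, patience = as.integer(patience),
                 seed = as.integer(seed), dropout_input = isTRUE(dropout_input),
                 decoder = decoder, val_fraction = val_fraction,
                 lambda_recon = lambda_recon, kappa = kappa,
                 neg_replicates = as.integer(neg_replicates),
                 min_epochs = as.integer(min_epochs),
                 feature_norm = feature_norm,
                 final_activation = final_activation),
            class = "gae_params")
}

#' Glorot (Xavier) uniform initialization
#'
#' Entries drawn i.i.d. from uniform(-a, a) with
#' `a = sqrt(6 / (fan_in + fan_out))`, the scaling that keeps activation
#' variance stable across layers.
#'
#' @param fan_in,fan_out Matrix dimensions (both >= 1).
#' @param seed Optional integer seed; the same seed reproduces the matrix
#'   bit for bit. When `NULL`, draws from the ambient RNG stream.
#' @return A `fan_in` x `fan_out` numeric matrix.
#' @export
glorot_init <- function(fan_in, fan_out, seed = NULL) {
  if (fan_in < 1 || fan_out < 1) abort("fans must be >= 1.")
  a <- sqrt(6 / (fan_in + fan_out))
  draw <- function() matrix(stats::runif(fan_in * fan_out, -a, a), fan_in, fan_out)
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

# inverted dropout mask: entries are 0 with probability `rate`, else 1/(1-rate)
dropout_mask <- function(n_row, n_col, rate) {
  keep <- 1 - rate
  matrix((stats::runif(n_row * n_col) < keep) / keep, n_row, n_col)
}

# feature preprocessing applied before the first GCN layer
normalize_features <- function(H0, mode) {
  if (mode == "none") return(H0)
  H0 <- H0 - rowMeans(H0)
  nrm <- sqrt(rowSums(H0^2))
  nrm[nrm == 0] <- 1
  H0 / nrm
}

#' Single graph-convolution layer
#'
#' Computes `ReLU(A_hat %*% H %*% W)`. In training mode, inverted dropout is
#' first applied to `H`; evaluation mode is deterministic.
#'
#' @param H Input feature matrix (genes x features).
#' @param A_hat Renormalized adjacency from [renormalized_adjacency()].
#' @param W Layer weight matrix (features x output width).
#' @param dropout_rate Dropout rate in `[0, 1)`.
#' @param training Logical; apply dropout (consuming the ambient RNG stream)?
#' @param activation `"relu"` (default) or `"linear"`.
#' @return The output feature matrix (genes x output width).
#' @export
gcn_layer <- function(H, A_hat, W, dropout_rate = 0, training = FALSE,
                      activation = "relu") {
  if (ncol(A_hat) != nrow(H)) abort("A_hat and H are not conformable.")
  if (ncol(H) != nrow(W)) abort("H and W are not conformable.")
  if (training && dropout_rate > 0) {
    H <- H * dropout_mask(nrow(H), ncol(H), dropout_rate)
  }
  Z <- A_hat %*% H %*% W
  if (identical(activation, "relu")) pmax(Z, 0) else Z
}

# forward pass through the encoder, caching intermediates for backprop;
# the last layer is linear unless final_relu
encode_forward <- function(H0, A_hat, weights, dropout_rate, training,
                           dropout_input = TRUE, final_relu = FALSE) {
  n_layers <- length(weights)
  cache <- list(AX = vector("list", n_layers), Z = vector("list", n_layers),
                mask = vector("list", n_layers),
                relu = logical(n_layers))
  H <- H0
  for (l in seq_len(n_layers)) {
    use_dropout <- training && dropout_rate > 0 && (l > 1L || dropout_input)
    if (use_dropout) {
      m <- dropout_mask(nrow(H), ncol(H), dropout_rate)
      cache$mask[[l]] <- m
      X <- H * m
    } else {
      X <- H
    }
    AX <- A_hat %*% X
    Z <- AX %*% weights[[l]]
    cache$AX[[l]] <- AX
    cache$Z[[l]] <- Z
    cache$relu[l] <- l < n_layers || final_relu
    H <- if (cache$relu[l]) pmax(Z, 0) else Z
  }
  cache$E <- H
  cache
}

#' Encode genes into embeddings with a GCN stack
#'
#' Sequentially applies graph convolutions with the given weight matrices:
#' ReLU activations on hidden layers, a linear (by default) embedding layer
#' last. With the default two layers of width 200, the result is a genes x
#' 200 embedding matrix whose rows are the convolved gene representations.
#'
#' @param H0 Node feature matrix: the genes x cells expression values
#'   (already feature-normalized if desired; [gae_fit()] handles this).
#' @param A_hat Renormalized adjacency.
#' @param weights List of layer weight matrices (chained shapes).
#' @param dropout_rate,training As in [gcn_layer()].
#' @param dropout_input Apply dropout to `H0` itself in training mode?
#' @param final_activation `"linear"` (default) or `"relu"` for the last
#'   layer.
#' @return The embedding matrix (genes x final width), gene names as rownames.
#' @export
gae_encode <- function(H0, A_hat, weights, dropout_rate = 0, training = FALSE,
                       dropout_input = TRUE, final_activation = "linear") {
  if (!length(weights)) abort("`weights` must contain at least one layer.")
  E <- encode_forward(H0, A_hat, weights, dropout_rate, training, dropout_input,
                      final_relu = identical(final_activation, "relu"))$E
  rownames(E) <- rownames(H0)
  E
}

#' Bilinear (DistMult-style) pair scores
#'
#' Scores every ordered gene pair as `score(i, j) = e_i' W e_j`, implemented
#' as `E %*% W %*% t(E)`. No activation is applied; the sign of a score is
#' the predicted regulation sign (positive activating, negative inhibitory).
#' The diagonal is reported but excluded from ranking downstream.
#'
#' @param E Embedding matrix (genes x c).
#' @param W_dec Decoder weight, c x c. An asymmetric `W_dec` yields
#'   asymmetric scores and therefore directed edges; a symmetric one forces
#'   `S = t(S)`.
#' @return A genes x genes score matrix.
#' @export
bilinear_scores <- function(E, W_dec) {
  if (ncol(E) != nrow(W_dec) || nrow(W_dec) != ncol(W_dec)) {
    abort("`W_dec` must be square with the embedding width.")
  }
  S <- E %*% W_dec %*% t(E)
  dimnames(S) <- list(rownames(E), rownames(E))
  S
}

#' Sample negative gene pairs for edge classification
#'
#' Draws, uniformly without replacement, ordered non-self gene pairs that are
#' not positives (nor in `exclude`), exactly as many as there are positives,
#' and returns both with binary labels.
#'
#' @param positives Integer matrix (or data frame) with two columns of gene
#'   indices, one ordered positive pair per row.
#' @param n_genes Number of genes M; pairs live in the M(M-1) ordered
#'   non-self pairs.
#' @param seed Optional integer seed; `NULL` uses the ambient RNG stream.
#' @param exclude Optional extra pairs (same format) that must not be drawn
#'   as negatives, e.g. validation positives.
#' @return A tibble `i`, `j`, `label` with all positives (label 1) followed
#'   by the sampled negatives (label 0).
#' @export
negative_sampling <- function(positives, n_genes, seed = NULL, exclude = NULL) {
  pos <- as.matrix(positives)[, 1:2, drop = FALSE]
  storage.mode(pos) <- "integer"
  if (any(pos[, 1L] == pos[, 2L])) abort("positives contain self-pairs.")
  pos_idx <- pair_index(pos[, 1L], pos[, 2L], n_genes)
  if (anyDuplicated(pos_idx)) abort("positives contain duplicate pairs.")
  banned <- pos_idx
  if (!is.null(exclude) && nrow(as.matrix(exclude))) {
    exc <- as.matrix(exclude)[, 1:2, drop = FALSE]
    banned <- c(banned, pair_index(exc[, 1L], exc[, 2L], n_genes))
  }
  self_idx <- pair_index(seq_len(n_genes), seq_len(n_genes), n_genes)
  candidates <- setdiff(seq_len(n_genes^2), c(self_idx, banned))
  n_pos <- nrow(pos)
  if (length(candidates) < n_pos) {
    abort(sprintf("cannot sample %d negatives from %d available non-positive pairs.",
                  n_pos, length(candidates)))
  }
  draw <- function() sample(candidates, n_pos)
  neg_idx <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  neg <- index_pair(neg_idx, n_genes)
  tibble(i = c(pos[, 1L], neg[, 1L]),
         j = c(pos[, 2L], neg[, 2L]),
         label = rep(c(1L, 0L), c(n_pos, n_pos)))
}

#' Binary cross-entropy loss over labeled pairs
#'
#' Mean over the batch of `-[y log s(score) + (1 - y) log(1 - s(score))]`
#' with `s` the logistic sigmoid, computed in a numerically stabilized form,
#' plus an optional L2 penalty `l2/2 * ||W0||^2` on the first encoder layer.
#'
#' @param S Score matrix from [bilinear_scores()] (or a vector of per-pair
#'   scores aligned with `batch`).
#' @param batch A labeled pair tibble from [negative_sampling()].
#' @param W0 Optional first-layer weight matrix for the L2 term.
#' @param l2 L2 penalty coefficient (default 0).
#' @param weights Optional per-pair weights (default uniform 1/n).
#' @return The scalar loss.
#' @export
bce_loss <- function(S, batch, W0 = NULL, l2 = 0, weights = NULL) {
  if (!nrow(batch)) abort("empty batch.")
  s <- if (is.matrix(S)) S[cbind(batch$i, batch$j)] else S
  per_pair <- log1pexp(s) - s * batch$label
  loss <- if (is.null(weights)) mean(per_pair) else sum(weights * per_pair)
  if (!is.null(W0) && l2 > 0) loss <- loss + l2 * sum(W0^2) / 2
  loss
}

# ---- full training objective -------------------------------------------
# loss = class-balanced BCE over the labeled batch
#      + lambda_recon * mean off-diagonal (S - kappa * r)^2
#      + l2/2 * ||W0||^2
# The reconstruction term is the autoencoder half: the decoder must rebuild
# the signed co-expression structure of the prior graph from the embeddings,
# which anchors the score matrix to the data-wide signal while the (few)
# supervised labels calibrate it.

gae_loss_forward <- function(H0, A_hat, weights, W_dec, batch, l2,
                             lambda_recon, kappa, target,
                             pair_weights = NULL, dropout_rate = 0,
                             training = FALSE, dropout_input = TRUE,
                             final_relu = FALSE, abs_scores = FALSE) {
  cache <- encode_forward(H0, A_hat, weights, dropout_rate, training,
                          dropout_input, final_relu)
  E <- cache$E
  s <- rowSums((E[batch$i, , drop = FALSE] %*% W_dec) *
                 E[batch$j, , drop = FALSE])
  # abs_scores: edge confidence is |score| (sign only encodes regulation
  # mode), the convention used when ranking inferred edges
  if (abs_scores) s <- abs(s)
  loss <- bce_loss(s, batch, weights = pair_weights)
  if (lambda_recon > 0) {
    S <- E %*% W_dec %*% t(E)
    m <- nrow(S)
    off <- row(S) != col(S)
    loss <- loss + lambda_recon * mean((S[off] - kappa * target[off])^2)
  }
  loss + l2 * sum(weights[[1L]]^2) / 2
}

gae_loss_backward <- function(H0, A_hat, weights, W_dec, batch, l2,
                              lambda_recon, kappa, target,
                              pair_weights = NULL, dropout_rate = 0,
                              training = FALSE, dropout_input = TRUE,
                              final_relu = FALSE, decoder = "full") {
  cache <- encode_forward(H0, A_hat, weights, dropout_rate, training,
                          dropout_input, final_relu)
  E <- cache$E
  m <- nrow(E)
  pi <- batch$i; pj <- batch$j; y <- batch$label
  n <- length(pi)
  if (is.null(pair_weights)) pair_weights <- rep(1 / n, n)
  Ei <- E[pi, , drop = FALSE]; Ej <- E[pj, , drop = FALSE]
  s <- rowSums((Ei %*% W_dec) * Ej)
  loss <- sum(pair_weights * (log1pexp(s) - s * y)) +
    l2 * sum(weights[[1L]]^2) / 2
  g <- (sigmoid(s) - y) * pair_weights

  d_wdec <- crossprod(Ei * g, Ej)
  contrib <- rbind((Ej %*% t(W_dec)) * g, (Ei %*% W_dec) * g)
  rs <- rowsum(contrib, group = c(pi, pj))
  dE <- matrix(0, m, ncol(E))
  dE[as.integer(rownames(rs)), ] <- rs

  if (lambda_recon > 0) {
    S <- E %*% W_dec %*% t(E)
    off <- row(S) != col(S)
    resid <- S - kappa * target
    loss <- loss + lambda_recon * mean(resid[off]^2)
    dS <- matrix(0, m, m)
    dS[off] <- 2 * lambda_recon * resid[off] / (m * (m - 1))
    d_wdec <- d_wdec + crossprod(E, dS %*% E)
    dE <- dE + dS %*% E %*% t(W_dec) + t(dS) %*% E %*% W_dec
  }
  if (decoder == "diagonal") d_wdec <- diag(diag(d_wdec))

  n_layers <- length(weights)
  d_weights <- vector("list", n_layers)
  dH <- dE
  for (l in rev(seq_len(n_layers))) {
    dZ <- if (cache$relu[l]) dH * (cache$Z[[l]] > 0) else dH
    d_weights[[l]] <- crossprod(cache$AX[[l]], dZ)
    if (l > 1L) {
      dX <- (A_hat %*% dZ) %*% t(weights[[l]])
      dH <- if (is.null(cache$mask[[l]])) dX else dX * cache$mask[[l]]
    }
  }
  d_weights[[1L]] <- d_weights[[1L]] + l2 * weights[[1L]]
  list(loss = loss, scores = s, d_weights = d_weights, d_wdec = d_wdec)
}

adam_state <- function(mats) {
  lapply(mats, function(w) list(m = w * 0, v = w * 0))
}

adam_update <- function(w, g, state, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  m_hat <- state$m / (1 - beta1^t)
  v_hat <- state$v / (1 - beta2^t)
  list(w = w - lr * m_hat / (sqrt(v_hat) + eps), state = state)
}

edges_to_indices <- function(edges, gene_names) {
  i <- match(edges$regulator, gene_names)
  j <- match(edges$target, gene_names)
  if (anyNA(i) || anyNA(j)) abort("edge endpoints missing from gene set.")
  cbind(i, j)
}

# closed-form warm start for the decoder: the ridge least-squares W that
# reconstructs the target score matrix from the initial embeddings,
# W = argmin ||E W E' - kappa * target||^2 + ridge penalty.
# The relative ridge keeps the solution from leaning on near-null embedding
# directions, whose amplification would make training-mode (dropout)
# forward passes blow up; the reconstruction is exact in the directions the
# embeddings support well.
decoder_warm_start <- function(E, target, kappa, ridge = 1e-12, refine = 3L) {
  sv <- svd(E)
  d <- sv$d
  dinv <- d / (d^2 + ridge * max(d^2, 1e-300))
  Dinv <- diag(dinv, nrow = length(dinv))
  solve_once <- function(rhs) {
    sv$v %*% (Dinv %*% t(sv$u) %*% rhs %*% sv$u %*% Dinv) %*% t(sv$v)
  }
  W <- solve_once(kappa * target)
  # iterative refinement drives the reconstruction residual toward
  # machine precision despite the ridge bias
  for (k in seq_len(refine)) {
    resid <- kappa * target - E %*% W %*% t(E)
    W <- W + solve_once(resid)
  }
  W
}

# build the per-epoch training batch: positives once, `reps` independent
# negative draws, class-balanced weights (positives 1/2P, negatives 1/2PR)
balanced_batch <- function(train_pos, m, exclude, reps) {
  np <- nrow(train_pos)
  draws <- lapply(seq_len(reps), function(r) {
    b <- negative_sampling(train_pos, m, exclude = exclude)
    b[b$label == 0L, ]
  })
  negs <- dplyr::bind_rows(draws)
  batch <- tibble(i = c(train_pos[, 1L], negs$i),
                  j = c(train_pos[, 2L], negs$j),
                  label = rep(c(1L, 0L), c(np, np * reps)))
  wts <- c(rep(1 / (2 * np), np), rep(1 / (2 * np * reps), np * reps))
  list(batch = batch, weights = wts)
}

#' Fit the graph autoencoder to expression data and known regulations
#'
#' Trains the GCN encoder and bilinear decoder with Adam against a two-part
#' objective evaluated on a full-graph forward pass each epoch: (i) the
#' autoencoder reconstruction of the prior graph — the decoded score matrix
#' is pulled toward `kappa` times the signed co-expression correlations — and
#' (ii) binary cross-entropy classification of known regulator-target edges
#' against per-epoch resampled negative pairs (class-balanced, averaged over
#' `neg_replicates` draws). The decoder is warm-started with the closed-form
#' ridge solution of the reconstruction problem at the initial embeddings,
#' so scores begin at the prior-graph structure rather than at noise.
#' Validation positives with the full complement of non-edges as negatives
#' give the early-stopping signal: after `min_epochs`, training halts once
#' `patience` epochs pass without improvement, and the best-validation
#' weights are restored (epoch 0, the warm start itself, included).
#'
#' @param expr A log-transformed [expression_matrix()]; its values are the
#'   node features.
#' @param prior A [build_prior_graph()] over the same genes, same order.
#' @param train_edges A tibble/data frame of training positives with columns
#'   `regulator`, `target` (e.g. folds from [kfold_edge_split()]).
#' @param val_edges Optional validation positives, disjoint from
#'   `train_edges`. When `NULL`, a fraction `params$val_fraction` of the
#'   training positives is carved out (at least one edge).
#' @param params A [gae_params()] configuration.
#' @return A `gae_fit` object: encoder `weights`, decoder `W_dec`, `params`,
#'   `gene_names`, the cached (feature-normalized) `H0` and `A_hat`,
#'   `history` (per-epoch train and validation loss tibble) and `best_epoch`.
#' @export
gae_fit <- function(expr, prior, train_edges, val_edges = NULL, params = gae_params()) {
  vals <- unclass(expr)
  if (!identical(rownames(vals), prior$gene_names)) {
    abort("expression genes and prior-graph genes must match in order.")
  }
  genes <- prior$gene_names
  m <- length(genes)
  train_edges <- as_tibble(train_edges)
  if (!nrow(train_edges)) abort("no training edges.")
  H0 <- normalize_features(vals, params$feature_norm)
  final_relu <- identical(params$final_activation, "relu")

  withr::with_seed(params$seed, {
    if (is.null(val_edges)) {
      if (nrow(train_edges) < 2L) {
        val_edges <- train_edges[0L, ]
      } else {
        n_val <- max(1L, floor(params$val_fraction * nrow(train_edges)))
        pick <- sample(nrow(train_edges), n_val)
        val_edges <- train_edges[pick, ]
        train_edges <- train_edges[-pick, ]
      }
    } else {
      val_edges <- as_tibble(val_edges)
      key <- function(d) paste(d$regulator, d$target, sep = "\r")
      if (length(intersect(key(train_edges), key(val_edges)))) {
        abort("training and validation edges overlap.")
      }
    }
    train_pos <- edges_to_indices(train_edges, genes)
    val_pos <- if (nrow(val_edges)) edges_to_indices(val_edges, genes) else
      matrix(integer(), 0L, 2L)
    have_val <- nrow(val_pos) > 0L

    dims <- c(ncol(H0), params$hidden_dims)
    weights <- lapply(seq_along(params$hidden_dims), function(l) {
      glorot_init(dims[l], dims[l + 1L])
    })
    # the reconstruction problem restricted to the decoder has a closed-form
    # ridge solution at the initial embeddings; that model is the epoch-0
    # candidate every trained epoch must beat on validation. The gradient
    # trajectory itself starts from a zero decoder (scores 0), which keeps
    # the early dynamics stable.
    E0 <- encode_forward(H0, prior$A_hat, weights, 0, FALSE,
                         final_relu = final_relu)$E
    W_warm <- decoder_warm_start(E0, prior$R_signed, params$kappa)
    if (params$decoder == "diagonal") W_warm <- diag(diag(W_warm))
    c_dim <- utils::tail(params$hidden_dims, 1L)
    W_dec <- matrix(0, c_dim, c_dim)

    # validation monitor: val positives against the full complement of
    # known positives, class-balanced -- deterministic in eval mode
    val_batch <- NULL
    val_weights <- NULL
    if (have_val) {
      known <- pair_index(c(train_pos[, 1L], val_pos[, 1L]),
                          c(train_pos[, 2L], val_pos[, 2L]), m)
      self_idx <- pair_index(seq_len(m), seq_len(m), m)
      comp <- setdiff(seq_len(m^2), c(self_idx, known))
      comp_ij <- index_pair(comp, m)
      nv <- nrow(val_pos); nc <- nrow(comp_ij)
      val_batch <- tibble(i = c(val_pos[, 1L], comp_ij[, 1L]),
                          j = c(val_pos[, 2L], comp_ij[, 2L]),
                          label = rep(c(1L, 0L), c(nv, nc)))
      val_weights <- c(rep(1 / (2 * nv), nv), rep(1 / (2 * nc), nc))
    }

    mats <- c(weights, list(W_dec))
    opt <- adam_state(mats)
    history <- matrix(NA_real_, params$epochs, 2L)
    best_loss <- if (have_val) {
      gae_loss_forward(H0, prior$A_hat, weights, W_warm, val_batch,
                       l2 = 0, lambda_recon = params$lambda_recon,
                       kappa = params$kappa, target = prior$R_signed,
                       pair_weights = val_weights, final_relu = final_relu,
                       abs_scores = TRUE)
    } else Inf
    best_epoch <- 0L
    best <- list(weights = weights, W_dec = W_warm)
    epoch <- 0L
    while (epoch < params$epochs) {
      epoch <- epoch + 1L
      bb <- balanced_batch(train_pos, m, exclude = val_pos,
                           reps = params$neg_replicates)
      bk <- gae_loss_backward(H0, prior$A_hat, weights, W_dec, bb$batch,
                              l2 = params$l2_first_layer,
                              lambda_recon = params$lambda_recon,
                              kappa = params$kappa,
                              target = prior$R_signed,
                              pair_weights = bb$weights,
                              dropout_rate = params$dropout_rate,
                              training = TRUE,
                              dropout_input = params$dropout_input,
                              final_relu = final_relu,
                              decoder = params$decoder)
      grads <- c(bk$d_weights, list(bk$d_wdec))
      mats <- c(weights, list(W_dec))
      for (k in seq_along(mats)) {
        upd <- adam_update(mats[[k]], grads[[k]], opt[[k]],
                           params$learning_rate, epoch)
        mats[[k]] <- upd$w
        opt[[k]] <- upd$state
      }
      weights <- mats[seq_along(weights)]
      W_dec <- mats[[length(mats)]]

      monitor <- if (have_val) {
        gae_loss_forward(H0, prior$A_hat, weights, W_dec, val_batch,
                         l2 = 0, lambda_recon = params$lambda_recon,
                         kappa = params$kappa, target = prior$R_signed,
                         pair_weights = val_weights, final_relu = final_relu,
                         abs_scores = TRUE)
      } else bk$loss
      history[epoch, ] <- c(bk$loss, if (have_val) monitor else NA_real_)
      if (monitor < best_loss - 1e-12) {
        best_loss <- monitor
        best_epoch <- epoch
        best <- list(weights = weights, W_dec = W_dec)
      }
      if (epoch >= params$min_epochs && epoch - best_epoch >= params$patience) break
    }
    structure(list(weights = best$weights, W_dec = best$W_dec, params = params,
                   gene_names = genes, H0 = H0, A_hat = prior$A_hat,
                   history = {
                     ep <- seq_len(epoch)
                     tibble(epoch = ep,
                            train_loss = history[ep, 1L],
                            val_loss = history[ep, 2L])
                   },
                   best_epoch = best_epoch,
                   train_edges = train_edges, val_edges = val_edges),
              class = "gae_fit")
  })
}

#' @export
print.gae_fit <- function(x, ...) {
  cat(sprintf("<gae_fit> %d genes, encoder %s, trained %d epochs (best %d)\n",
              length(x$gene_names),
              paste(vapply(x$weights, ncol, integer(1)), collapse = "-"),
              nrow(x$history), x$best_epoch))
  invisible(x)
}

#' Infer the regulatory network from a trained model
#'
#' Runs the deterministic (evaluation-mode) encoder and bilinear decoder to
#' produce the full signed score matrix, optionally max-normalizes absolute
#' scores to `[0, 1]`, drops edges at or below `weight_cutoff`, and ranks the
#' remaining ordered pairs by absolute score (sign preserved; an inhibitory
#' -0.9 outranks an activating +0.5).
#'
#' @param fit A [gae_fit()] result.
#' @param normalize Scale scores so the largest off-diagonal absolute score
#'   is 1? Default `TRUE`.
#' @param weight_cutoff Drop edges with normalized absolute score <= this
#'   value, in `[0, 1)`. Default 0 keeps every pair. (0.2 is the cutoff used
#'   for reporting applications.)
#' @return A list with `scores` (the genes x genes signed score matrix) and
#'   `edges` (a ranked tibble `regulator`, `target`, `score`).
#' @export
infer_grn <- function(fit, normalize = TRUE, weight_cutoff = 0) {
  stopifnot_scalar_number(weight_cutoff, "weight_cutoff")
  if (weight_cutoff < 0 || weight_cutoff >= 1) {
    abort("`weight_cutoff` must be in [0, 1).")
  }
  E <- gae_encode(fit$H0, fit$A_hat, fit$weights, dropout_rate = 0,
                  training = FALSE,
                  final_activation = fit$params$final_activation)
  S <- bilinear_scores(E, fit$W_dec)
  off <- abs(S); diag(off) <- 0
  if (normalize && max(off) > 0) S <- S / max(off)
  # snap sub-reporting-precision differences so genuine ties stay ties and
  # the lexicographic tie-break is reproducible across runs
  if (normalize) S <- round(S, 9)
  idx <- which(row(S) != col(S), arr.ind = TRUE)
  edges <- tibble(regulator = fit$gene_names[idx[, 1L]],
                  target = fit$gene_names[idx[, 2L]],
                  score = S[idx])
  edges <- edges[abs(edges$score) > weight_cutoff, ]
  list(scores = S, edges = rank_edge_list(edges))
}

#' @rdname gae_fit
#' @param x A `gae_fit` object.
#' @param ... Unused.
#' @return `tidy()`: the per-epoch loss history; `glance()`: a one-row
#'   summary with epochs run, best epoch and best losses.
#' @export
tidy.gae_fit <- function(x, ...) x$history

#' @rdname gae_fit
#' @export
glance.gae_fit <- function(x, ...) {
  b <- x$best_epoch
  tibble(n_genes = length(x$gene_names),
         epochs_run = nrow(x$history),
         best_epoch = b,  # 0 = the warm-started model was never beaten
         train_loss = if (b >= 1) x$history$train_loss[b] else NA_real_,
         val_loss = if (b >= 1) x$history$val_loss[b] else NA_real_)
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint is a single JSON text file holding the encoder and decoder
#' weights at full precision, the hyperparameters and the gene-name order.
#' `read_gae_checkpoint()` restores an equivalent `gae_fit`; pass the
#' matching `expr` and `prior` to reattach the node features needed by
#' [infer_grn()].
#'
#' @param fit A [gae_fit()].
#' @param path Checkpoint path.
#' @return `write_gae_checkpoint()`: `path` invisibly;
#'   `read_gae_checkpoint()`: a `gae_fit`.
#' @export
write_gae_checkpoint <- function(fit, path) {
  # doubles are serialized as %.17g strings so the round-trip is bit-exact
  payload <- list(
    gene_names = fit$gene_names,
    hyper = unclass(fit$params),
    weights = lapply(fit$weights, function(w)
      list(dim = dim(w), x = sprintf("%.17g", as.numeric(w)))),
    W_dec = list(dim = dim(fit$W_dec),
                 x = sprintf("%.17g", as.numeric(fit$W_dec))),
    best_epoch = fit$best_epoch
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gae_checkpoint
#' @param expr,prior Expression matrix and prior graph to attach (must match
#'   the checkpoint's gene order); optional.
#' @export
read_gae_checkpoint <- function(path, expr = NULL, prior = NULL) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  rebuild <- function(w) {
    matrix(as.numeric(unlist(w$x)), unlist(w$dim)[1L], unlist(w$dim)[2L])
  }
  weights <- lapply(payload$weights, rebuild)
  hyper <- lapply(payload$hyper, function(x) unlist(x))
  params <- gae_params(hidden_dims = hyper$hidden_dims, epochs = hyper$epochs,
                       learning_rate = hyper$learning_rate,
                       l2_first_layer = hyper$l2_first_layer,
                       dropout_rate = hyper$dropout_rate,
                       patience = hyper$patience, seed = hyper$seed,
                       dropout_input = hyper$dropout_input,
                       decoder = hyper$decoder,
                       val_fraction = hyper$val_fraction,
                       lambda_recon = hyper$lambda_recon, kappa = hyper$kappa,
                       neg_replicates = hyper$neg_replicates,
                       min_epochs = hyper$min_epochs,
                       feature_norm = hyper$feature_norm,
                       final_activation = hyper$final_activation)
  H0 <- if (!is.null(expr)) {
    normalize_features(unclass(expr), params$feature_norm)
  }
  structure(list(weights = weights, W_dec = rebuild(payload$W_dec),
                 params = params, gene_names = unlist(payload$gene_names),
                 H0 = H0,
                 A_hat = if (!is.null(prior)) prior$A_hat else NULL,
                 history = tibble(epoch = integer(), train_loss = numeric(),
                                  val_loss = numeric()),
                 best_epoch = unlist(payload$best_epoch)),
            class = "gae_fit")
}
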