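test_that("glorot initialization has the right distribution and determinism", {
  w1 <- glorot_init(40, 60, seed = 7)
  w2 <- glorot_init(40, 60, seed = 7)
  expect_identical(w1, w2)
  big <- glorot_init(500, 200, seed = 1)  # 1e5 draws
  a <- sqrt(6 / 700)
  expect_true(all(abs(big) <= a))
  n <- length(big)
  expect_lt(abs(mean(big)), 3 * a / sqrt(3 * n))         # mean ~ 0 within 3 sigma
  expect_equal(var(as.numeric(big)), a^2 / 3, tolerance = 0.05)
  expect_equal(a^2 / 3, 2 / 700, tolerance = 1e-12)      # closed form
  expect_error(glorot_init(0, 3), "fans")
})

test_that("gcn layer computes ReLU(A H W) with identity and hand cases", {
  H <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(gcn_layer(H, diag(2), diag(2)), H)
  # negative pre-activations clamp to zero
  W_neg <- -diag(2)
  expect_equal(gcn_layer(H, diag(2), W_neg), matrix(0, 2, 2))
  # 2-gene hand computation
  A <- matrix(0.5, 2, 2)
  W <- matrix(c(1, 0, 1, 1), 2, 2)
  AH <- A %*% H
  expect_equal(gcn_layer(H, A, W), pmax(AH %*% W, 0))
  expect_error(gcn_layer(H, diag(3), W), "conformable")
})

test_that("encoder composes layers and is deterministic in evaluation mode", {
  expr <- toy_expression(n_genes = 3, n_cells = 8, seed = 2)
  g <- build_prior_graph(spearman_matrix(expr))
  H0 <- unclass(expr)
  w <- list(glorot_init(8, 4, seed = 1), glorot_init(4, 4, seed = 2))
  e1 <- gae_encode(H0, g$A_hat, w)
  e2 <- gae_encode(H0, g$A_hat, w)
  expect_identical(e1, e2)
  # matches manual composition of gcn_layer calls (final layer linear)
  manual <- g$A_hat %*% gcn_layer(H0, g$A_hat, w[[1]]) %*% w[[2]]
  expect_equal(unname(e1), unname(manual))
  expect_equal(dim(e1), c(3L, 4L))
  expect_error(gae_encode(H0, g$A_hat, list()), "at least one")
})

test_that("bilinear scores follow E W E^T with symmetry semantics", {
  E <- matrix(c(1, 0, 2, 1, -1, 3), 3, 2,
              dimnames = list(paste0("g", 1:3), NULL))
  expect_equal(bilinear_scores(E, diag(2)), E %*% t(E),
               ignore_attr = TRUE)
  W_asym <- matrix(c(0, 1, 0, 0), 2, 2)
  S <- bilinear_scores(E, W_asym)
  expect_equal(S["g1", "g2"], sum(E[1, ] * (W_asym %*% E[2, ])))
  expect_false(isTRUE(all.equal(S, t(S))))
  # symmetric decoder weight forces symmetric scores
  W_sym <- matrix(c(1, 0.3, 0.3, 2), 2, 2)
  S2 <- bilinear_scores(E, W_sym)
  expect_equal(S2, t(S2))
  expect_equal(bilinear_scores(E * 0, diag(2)),
               matrix(0, 3, 3), ignore_attr = TRUE)
  expect_error(bilinear_scores(E, diag(3)), "width")
})

test_that("negative sampling draws from the exact complement", {
  pos <- cbind(c(1L, 2L, 3L), c(2L, 3L, 4L))
  out <- negative_sampling(pos, n_genes = 4, seed = 5)
  expect_equal(sum(out$label == 0), sum(out$label == 1))
  negs <- out[out$label == 0, ]
  expect_false(any(negs$i == negs$j))
  pos_keys <- paste(pos[, 1], pos[, 2])
  expect_false(any(paste(negs$i, negs$j) %in% pos_keys))
  expect_identical(out, negative_sampling(pos, n_genes = 4, seed = 5))
  # exhaustive check on M = 4: complement has 12 - 3 = 9 candidates
  all_draws <- replicate(50, {
    o <- negative_sampling(pos, 4)
    paste(o$i[o$label == 0], o$j[o$label == 0])
  })
  expect_true(all(!all_draws %in% pos_keys))
  # requesting more negatives than exist errors
  m2_pos <- cbind(c(1L, 2L), c(2L, 1L))
  expect_error(negative_sampling(m2_pos, n_genes = 2), "cannot sample")
})

test_that("bce loss hits its analytic anchors", {
  batch <- tibble::tibble(i = c(1L, 1L, 2L, 2L), j = c(2L, 3L, 3L, 1L),
                          label = c(1L, 0L, 1L, 0L))
  S0 <- matrix(0, 3, 3)
  expect_equal(bce_loss(S0, batch), log(2))
  # saturated correct prediction contributes ~0
  expect_lt(bce_loss(rep(50, 2), tibble::tibble(i = 1:2, j = c(2L, 3L),
                                                label = c(1L, 1L))), 1e-20)
  # hand evaluation of a mixed batch
  S <- matrix(0, 3, 3)
  S[1, 2] <- 2; S[1, 3] <- -1; S[2, 3] <- 0.5; S[2, 1] <- -0.2
  sig <- function(x) 1 / (1 + exp(-x))
  hand <- -mean(c(log(sig(2)), log(1 - sig(-1)), log(sig(0.5)),
                  log(1 - sig(-0.2))))
  expect_equal(bce_loss(S, batch), hand)
  # L2 term on the first-layer weights
  W0 <- matrix(2, 2, 2)
  expect_equal(bce_loss(S0, batch, W0 = W0, l2 = 1e-4),
               log(2) + 1e-4 * 16 / 2)
  expect_error(bce_loss(S0, batch[0, ]), "empty")
})

test_that("analytic gradients match central finite differences", {
  # 4-gene toy, no dropout, so the loss is a deterministic function
  expr <- toy_expression(n_genes = 4, n_cells = 6, seed = 10)
  prior <- build_prior_graph(spearman_matrix(expr))
  H0 <- unclass(expr)
  batch <- tibble::tibble(i = c(1L, 2L, 3L, 1L), j = c(2L, 3L, 4L, 4L),
                          label = c(1L, 1L, 0L, 0L))
  withr::with_seed(3, {
    weights <- list(glorot_init(6, 5), glorot_init(5, 5))
    W_dec <- matrix(rnorm(25, sd = 0.3), 5, 5)
  })
  target <- prior$R_signed
  loss_fn <- function(weights, W_dec) {
    grnae:::gae_loss_forward(H0, prior$A_hat, weights, W_dec, batch,
                             l2 = 1e-3, lambda_recon = 0.5, kappa = 2,
                             target = target)
  }
  grads <- grnae:::gae_loss_backward(H0, prior$A_hat, weights, W_dec, batch,
                                     l2 = 1e-3, lambda_recon = 0.5, kappa = 2,
                                     target = target)
  eps <- 1e-5
  check_matrix <- function(get, set, analytic) {
    m <- get()
    idx <- cbind(sample(nrow(m), 6, replace = TRUE),
                 sample(ncol(m), 6, replace = TRUE))
    for (r in seq_len(6)) {
      i <- idx[r, 1]; j <- idx[r, 2]
      up <- m; up[i, j] <- up[i, j] + eps
      dn <- m; dn[i, j] <- dn[i, j] - eps
      num <- (set(up) - set(dn)) / (2 * eps)
      expect_equal(unname(analytic[i, j]), unname(num), tolerance = 1e-5)
    }
  }
  withr::with_seed(99, {
    check_matrix(function() weights[[1]],
                 function(w) loss_fn(list(w, weights[[2]]), W_dec),
                 grads$d_weights[[1]])
    check_matrix(function() weights[[2]],
                 function(w) loss_fn(list(weights[[1]], w), W_dec),
                 grads$d_weights[[2]])
    check_matrix(function() W_dec,
                 function(w) loss_fn(weights, w),
                 grads$d_wdec)
  })
})

test_that("training descends on a separable toy and stops early when flat", {
  # two disjoint 3-gene cliques in expression space
  withr::with_seed(4, {
    base1 <- rnorm(30); base2 <- rnorm(30)
    vals <- rbind(
      g1 = base1 + rnorm(30, sd = 0.1), g2 = base1 + rnorm(30, sd = 0.1),
      g3 = base1 + rnorm(30, sd = 0.1), g4 = base2 + rnorm(30, sd = 0.1),
      g5 = base2 + rnorm(30, sd = 0.1), g6 = base2 + rnorm(30, sd = 0.1))
    colnames(vals) <- paste0("c", 1:30)
  })
  expr <- expression_matrix(vals, "log_expression")
  prior <- build_prior_graph(spearman_matrix(expr))
  train <- tibble::tibble(regulator = c("g1", "g2", "g4", "g5"),
                          target = c("g2", "g3", "g5", "g6"))
  params <- gae_params(hidden_dims = c(16, 16), epochs = 60, seed = 2,
                       dropout_rate = 0, min_epochs = 60, patience = 60)
  fit <- gae_fit(expr, prior, train, params = params)
  h <- fit$history$train_loss
  expect_lt(mean(tail(h, 5)), h[1])
  expect_equal(fit$params$epochs, 60L)

  # early stopping mechanics: a zero learning rate makes the validation
  # loss constant, so training halts after `patience` fruitless epochs and
  # the warm-started (epoch 0) parameters are retained
  p2 <- gae_params(hidden_dims = c(8), epochs = 400, seed = 3,
                   dropout_rate = 0, learning_rate = 0, patience = 10,
                   min_epochs = 1)
  fit2 <- gae_fit(expr, prior, train, params = p2)
  expect_equal(nrow(fit2$history), 10L)  # patience epochs, none improving
  expect_equal(fit2$best_epoch, 0L)
})

test_that("training and inference are deterministic given a seed", {
  sim <- simulate_dataset(sim_config(network_kind = "CY", n_cells = 120,
                                     seed = 6))
  expr <- log_transform(sim$expr)
  prior <- build_prior_graph(spearman_matrix(expr))
  train <- tibble::as_tibble(sim$network)[1:4, ]
  params <- gae_params(hidden_dims = c(12, 12), epochs = 15, seed = 11,
                       min_epochs = 15, patience = 15)
  f1 <- gae_fit(expr, prior, train, params = params)
  f2 <- gae_fit(expr, prior, train, params = params)
  expect_identical(f1$weights, f2$weights)
  expect_identical(infer_grn(f1)$edges, infer_grn(f2)$edges)
})

test_that("inference normalizes, cuts and ranks by absolute score", {
  sim <- simulate_dataset(sim_config(network_kind = "CY", n_cells = 100,
                                     seed = 9))
  expr <- log_transform(sim$expr)
  prior <- build_prior_graph(spearman_matrix(expr))
  train <- tibble::as_tibble(sim$network)[1:4, ]
  fit <- gae_fit(expr, prior, train,
                 params = gae_params(hidden_dims = c(10, 10), epochs = 20,
                                     seed = 1, min_epochs = 20, patience = 20))
  out <- infer_grn(fit)
  expect_equal(max(abs(out$edges$score)), 1)
  expect_true(all(diff(abs(out$edges$score)) <= 1e-12))
  # ranking key is |score|: the top edge beats every lower |score|, signs kept
  cut <- infer_grn(fit, weight_cutoff = 0.2)
  expect_true(all(abs(cut$edges$score) > 0.2))
  expect_error(infer_grn(fit, weight_cutoff = 1), "cutoff")
  # tidy/glance accessors
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(glance(fit)), 1L)
})

test_that("checkpoints round-trip weights and gene order", {
  expr <- toy_expression(n_genes = 4, n_cells = 10, seed = 13)
  prior <- build_prior_graph(spearman_matrix(expr))
  train <- tibble::tibble(regulator = c("g1", "g2", "g3"),
                          target = c("g2", "g3", "g4"))
  fit <- gae_fit(expr, prior, train,
                 params = gae_params(hidden_dims = c(6, 6), epochs = 5,
                                     seed = 1, min_epochs = 5, patience = 5))
  path <- withr::local_tempfile(fileext = ".json")
  write_gae_checkpoint(fit, path)
  back <- read_gae_checkpoint(path, expr = expr, prior = prior)
  expect_equal(lapply(back$weights, unname), lapply(fit$weights, unname),
               tolerance = 1e-12)
  expect_equal(unname(back$W_dec), unname(fit$W_dec), tolerance = 1e-12)
  expect_identical(back$gene_names, fit$gene_names)
  e1 <- infer_grn(back)$edges; e2 <- infer_grn(fit)$edges
  expect_identical(e1[, c("regulator", "target")],
                   e2[, c("regulator", "target")])
  expect_equal(e1$score, e2$score, tolerance = 1e-12)
})
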