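test_that("kfold splits are disjoint, exhaustive, near-equal and seeded", {
  net <- make_benchmark_network("BFC")
  folds <- kfold_edge_split(net, k = 3, seed = 9)
  key <- function(d) paste(d$regulator, d$target)
  all_keys <- unlist(lapply(folds$folds, key))
  expect_equal(sort(all_keys), sort(key(net)))
  expect_equal(anyDuplicated(all_keys), 0L)
  sizes <- vapply(folds$folds, nrow, integer(1))
  expect_lte(max(sizes) - min(sizes), 1L)
  again <- kfold_edge_split(net, k = 3, seed = 9)
  expect_identical(lapply(folds$folds, key), lapply(again$folds, key))
  # 9 edges, k = 3 -> (3,3,3)
  nine <- grn_network(tibble::tibble(
    regulator = paste0("g", 1:9), target = paste0("g", c(2:9, 1))))
  expect_equal(vapply(kfold_edge_split(nine, 3, 1)$folds, nrow, integer(1)),
               rep(3L, 3))
  expect_error(kfold_edge_split(net, k = 1), "k")
})

test_that("auroc equals the pairwise comparison oracle and handles ties", {
  expect_equal(auroc(c(5, 4, 3, 2), c(1, 1, 0, 0)), 1)
  withr::with_seed(21, {
    for (rep in 1:8) {
      n <- 12
      scores <- sample(1:6, n, replace = TRUE)  # forces ties
      labels <- sample(0:1, n, replace = TRUE, prob = c(0.5, 0.5))
      if (length(unique(labels)) < 2) next
      expect_equal(auroc(scores, labels), oracle_auroc(scores, labels))
    }
  })
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("auroc agrees with the pROC implementation", {
  withr::with_seed(17, {
    scores <- c(rnorm(40), sample(seq(0, 2, 0.5), 10, replace = TRUE))
    labels <- rbinom(50, 1, 0.4)
  })
  reference <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<")))
  expect_equal(auroc(scores, labels), reference, tolerance = 1e-12)
})

test_that("auroc is invariant under strictly increasing score transforms", {
  withr::with_seed(5, {
    scores <- rnorm(30); labels <- rbinom(30, 1, 0.4)
  })
  expect_equal(auroc(scores, labels), auroc(exp(scores), labels))
  expect_equal(auroc(scores, labels), auroc(rank(scores), labels))
})

test_that("auprc equals the threshold-sweep oracle and obeys anchors", {
  expect_equal(auprc(c(9, 8, 1, 0.5), c(1, 1, 0, 0)), 1)
  withr::with_seed(33, {
    for (rep in 1:8) {
      n <- 10
      scores <- sample(seq(0, 1, 0.25), n, replace = TRUE)
      labels <- c(1, sample(0:1, n - 1, replace = TRUE))
      expect_equal(auprc(scores, labels), oracle_auprc(scores, labels))
    }
  })
  # random scores, large n -> close to prevalence
  withr::with_seed(1, {
    scores <- runif(20000); labels <- rbinom(20000, 1, 0.3)
  })
  expect_equal(auprc(scores, labels), 0.3, tolerance = 0.02)
  expect_error(auprc(1:3, c(0, 0, 0)), "positive")
})

test_that("early precision ratio matches its definition on a 5-gene toy", {
  truth <- grn_network(tibble::tibble(
    regulator = c("g1", "g2", "g3"), target = c("g2", "g3", "g4")),
    gene_universe = paste0("g", 1:5))
  # perfect ranking: truth edges first -> EPR = 1/density
  good <- tibble::tibble(
    regulator = c("g1", "g2", "g3", "g5", "g4"),
    target = c("g2", "g3", "g4", "g1", "g2"),
    score = c(0.9, 0.8, 0.7, 0.2, 0.1))
  k <- 3; universe <- 20  # 5*4 ordered pairs
  expect_equal(early_precision_ratio(good, truth), 1 / (k / universe))
  # one hit in top 3 -> precision 1/3 -> EPR = (1/3)/(3/20)
  mixed <- tibble::tibble(
    regulator = c("g5", "g4", "g1", "g2", "g3"),
    target = c("g1", "g2", "g2", "g3", "g4"),
    score = c(0.9, 0.8, 0.7, 0.2, 0.1))
  expect_equal(early_precision_ratio(mixed, truth), (1 / 3) / (3 / 20))
  # exhaustive enumeration oracle over all top-k subsets
  withr::with_seed(2, {
    ranked <- tibble::tibble(
      regulator = rep(paste0("g", 1:5), each = 5),
      target = rep(paste0("g", 1:5), times = 5))
    ranked <- ranked[ranked$regulator != ranked$target, ]
    ranked$score <- runif(20)
    ranked <- rank_edge_list(ranked)
    key <- function(d) paste(d$regulator, d$target)
    hits <- sum(key(ranked[1:3, ]) %in% key(truth))
    expect_equal(early_precision_ratio(ranked, truth),
                 (hits / 3) / (3 / 20))
  })
  expect_error(early_precision_ratio(good[1:2, ], truth), "k = 3")
})

test_that("aupr ratio is auprc over density", {
  expect_equal(aupr_ratio(0.5, 0.25), 2)
  expect_equal(aupr_ratio(0.3, 0.3), 1)
  expect_error(aupr_ratio(0.5, 0), "density")
})

test_that("signed RMSE counts sign errors over ordered pairs", {
  truth <- toy_network()  # 4 signed edges over 5 genes -> 20 ordered pairs
  genes <- gene_universe(truth)
  scores <- matrix(0, 5, 5, dimnames = list(genes, genes))
  # perfect reconstruction
  scores[cbind(truth$regulator, truth$target)] <- truth$sign * 0.9
  expect_equal(signed_rmse(scores, truth), 0)
  # one sign flip among 20 pairs contributes (2)^2
  flipped <- scores
  flipped["g1", "g2"] <- -0.9
  expect_equal(signed_rmse(flipped, truth), sqrt(4 / 20))
  # all-zero prediction misses each signed edge with squared error 1
  expect_equal(signed_rmse(scores * 0, truth), sqrt(4 / 20))
  # sub-threshold scores count as "no regulation"
  weak <- scores * 0.1
  expect_equal(signed_rmse(weak, truth, threshold = 0.2), sqrt(4 / 20))
  unsigned <- grn_network(tibble::tibble(regulator = "g1", target = "g2"),
                          gene_universe = genes)
  expect_error(signed_rmse(scores, unsigned), "unsigned")
})

test_that("topology metrics match igraph-independent oracles on toys", {
  # directed 3-cycle: pagerank exactly 1/3 each
  cyc <- grn_network(tibble::tibble(regulator = c("a", "b", "c"),
                                    target = c("b", "c", "a")))
  top <- topology_metrics(cyc)
  expect_equal(top$pagerank, rep(1 / 3, 3), tolerance = 1e-6)
  expect_equal(top$degree, rep(2, 3))
  expect_equal(top$out_degree, rep(1, 3))
  expect_equal(top$betweenness, rep(1, 3))  # each node bridges one s-t pair

  # star hub: maximal degree and betweenness at the centre
  star <- grn_network(tibble::tibble(
    regulator = c("hub", "hub", "hub", "x1"),
    target = c("x1", "x2", "x3", "hub")))
  ts <- topology_metrics(star)
  expect_equal(ts$gene[which.max(ts$degree)], "hub")
  expect_equal(ts$gene[which.max(ts$betweenness)], "hub")

  # 5-node toy vs brute-force path-enumeration betweenness
  toy <- grn_network(tibble::tibble(
    regulator = c("a", "a", "b", "c", "d"),
    target = c("b", "c", "d", "d", "e")))
  bt <- topology_metrics(toy)
  oracle <- oracle_betweenness(toy, gene_universe(toy))
  expect_equal(bt$betweenness, as.numeric(oracle[bt$gene]))
})
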