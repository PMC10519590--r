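test_that("archetype networks have the canonical sizes and densities", {
  sizes <- c(LI = 7L, LL = 18L, CY = 6L, BF = 8L, BFC = 10L, TF = 8L)
  densities <- c(LI = 0.17, LL = 0.06, CY = 0.2, BF = 0.24, BFC = 0.17,
                 TF = 0.3)
  for (kind in names(sizes)) {
    net <- make_benchmark_network(kind)
    m <- length(gene_universe(net))
    expect_equal(m, sizes[[kind]], info = kind)
    # density counted explicitly: |edges| / (M (M-1))
    expect_lte(abs(nrow(net) / (m * (m - 1)) - densities[[kind]]), 0.05)
    expect_true(attr(net, "signed"), info = kind)
    expect_false(any(net$regulator == net$target))
  }
})

test_that("the cycle archetype is a directed cycle covering all genes", {
  net <- make_benchmark_network("CY")
  in_deg <- table(factor(net$target, levels = gene_universe(net)))
  expect_true(all(in_deg >= 1))
  g <- igraph::graph_from_data_frame(net[, c("regulator", "target")])
  expect_true(igraph::girth(g)$girth == length(gene_universe(net)))
})

test_that("custom networks honour density and are seed-deterministic", {
  net <- make_benchmark_network("custom", n_genes = 10, density = 0.2, seed = 4)
  expect_equal(nrow(net), round(0.2 * 90))
  again <- make_benchmark_network("custom", n_genes = 10, density = 0.2, seed = 4)
  expect_identical(as.data.frame(net), as.data.frame(again))
  expect_error(make_benchmark_network("custom"), "n_genes")
})

test_that("simulation is reproducible and non-negative", {
  cfg <- sim_config(network_kind = "LI", n_cells = 50, seed = 3)
  net <- make_benchmark_network("LI")
  a <- simulate_cells(net, cfg)
  b <- simulate_cells(net, cfg)
  expect_identical(unclass(a), unclass(b))
  expect_true(all(unclass(a) >= 0))
  expect_equal(dim(a), c(7L, 50L))
})

test_that("an unregulated gene with no noise settles at alpha/gamma", {
  net <- grn_network(tibble::tibble(regulator = "g1", target = "g2",
                                    sign = 1L),
                     gene_universe = c("g1", "g2"))
  cfg <- sim_config(network_kind = "custom", n_cells = 20, noise_sd = 0,
                    seed = 1)
  out <- unclass(simulate_cells(net, cfg, alpha = 2, gamma = 1, t_max = 60,
                                dt = 0.02))
  # late snapshots of the root gene sit at the fixed point 2
  expect_true(all(abs(out["g1", ] - 2) < 0.05 | out["g1", ] < 2))
  expect_lte(max(out["g1", ]), 2 + 1e-6)
})

test_that("single-edge sign is recovered in the expression correlation", {
  act <- grn_network(tibble::tibble(regulator = "A", target = "B", sign = 1L),
                     gene_universe = c("A", "B"))
  rep_ <- grn_network(tibble::tibble(regulator = "A", target = "B",
                                     sign = -1L),
                      gene_universe = c("A", "B"))
  cfg <- sim_config(network_kind = "custom", n_cells = 2000, seed = 8)
  r_act <- spearman_matrix(log_transform(simulate_cells(act, cfg)))["A", "B"]
  r_rep <- spearman_matrix(log_transform(simulate_cells(rep_, cfg)))["A", "B"]
  expect_gt(r_act, 0)
  expect_lt(r_rep, 0)
})

test_that("dropout injection zeroes the right entries at the right rate", {
  expr <- toy_counts(n_genes = 40, n_cells = 100, seed = 2)
  expect_identical(unclass(inject_dropout(expr, 0)), unclass(expr))

  out <- inject_dropout(expr, 50, seed = 11)
  vals <- unclass(expr); dropped <- unclass(out)
  expect_true(all(dropped <= vals))            # never increases
  expect_true(all(dropped[vals == 0] == 0))    # zeros stay zeros
  # eligible entries (below the median of nonzeros) zeroed at ~0.5
  cutoff <- quantile(vals[vals > 0], 0.5, names = FALSE)
  eligible <- vals > 0 & vals < cutoff
  frac <- mean(dropped[eligible] == 0)
  n <- sum(eligible)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
  # entries at or above the cutoff untouched
  expect_identical(dropped[vals >= cutoff], vals[vals >= cutoff])
  # deterministic per seed
  expect_identical(unclass(inject_dropout(expr, 50, seed = 11)), dropped)
})

test_that("simulate_dataset writes the three artifact files", {
  dir <- withr::local_tempdir()
  res <- simulate_dataset(sim_config(network_kind = "CY", n_cells = 30,
                                     seed = 5), dir = dir)
  expect_true(file.exists(file.path(dir, "ExpressionData.csv")))
  expect_true(file.exists(file.path(dir, "refNetwork.csv")))
  expect_true(file.exists(file.path(dir, "simulation-config.yaml")))
  back <- read_expression(file.path(dir, "ExpressionData.csv"))
  expect_equal(unclass(back), unclass(res$expr), tolerance = 1e-12)
  net <- read_network(file.path(dir, "refNetwork.csv"))
  expect_equal(nrow(net), nrow(res$network))
  cfg <- yaml::read_yaml(file.path(dir, "simulation-config.yaml"))
  expect_equal(cfg$seed, 5)
})
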