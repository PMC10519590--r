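archetype_edges <- function(kind) {
  e <- function(reg, tgt, sign) tibble(regulator = reg, target = tgt, sign = sign)
  switch(kind,
    # linear cascade, 7 genes: a chain with mixed activation/repression
    LI = e(paste0("g", 1:6), paste0("g", 2:7),
           c(1L, 1L, -1L, 1L, -1L, 1L)),
    # long linear cascade, 18 genes
    LL = e(paste0("g", 1:17), paste0("g", 2:18),
           ifelse(1:17 %in% c(4L, 9L, 14L), -1L, 1L)),
    # directed cycle, 6 genes, one repression -> negative feedback loop
    CY = e(paste0("g", c(1:6)), paste0("g", c(2:6, 1)),
           c(1L, 1L, 1L, 1L, 1L, -1L)),
    # bifurcating: root activates two mutually repressing branch masters,
    # each master drives its own arm and represses the other's
    BF = dplyr::bind_rows(
      e("g1", c("g2", "g3"), 1L),
      e(c("g2", "g3"), c("g3", "g2"), -1L),
      e(c("g2", "g4"), c("g4", "g5"), 1L),
      e(c("g3", "g6"), c("g6", "g7"), 1L),
      e(c("g2", "g3", "g2", "g3"), c("g6", "g4", "g7", "g5"), -1L),
      e("g5", "g8", 1L)),
    # bifurcating converging: two repressing branches that reconverge on a
    # shared downstream cascade
    BFC = dplyr::bind_rows(
      e("g1", c("g2", "g3"), 1L),
      e(c("g2", "g3"), c("g3", "g2"), -1L),
      e(c("g2", "g4"), c("g4", "g6"), 1L),
      e(c("g3", "g5"), c("g5", "g7"), 1L),
      e(c("g2", "g3"), c("g5", "g4"), -1L),
      e(c("g6", "g7", "g8", "g9"), c("g8", "g8", "g9", "g10"), 1L)),
    # trifurcating: three mutually repressing masters under one root, each
    # activating its own target and repressing the others'
    TF = dplyr::bind_rows(
      e("g1", c("g2", "g3", "g4"), 1L),
      e(rep(c("g2", "g3", "g4"), each = 2L),
        c("g3", "g4", "g2", "g4", "g2", "g3"), -1L),
      e(c("g2", "g3", "g4"), c("g5", "g6", "g7"), 1L),
      e(rep(c("g2", "g3", "g4"), each = 2L),
        c("g6", "g7", "g5", "g7", "g5", "g6"), -1L),
      e("g5", "g8", 1L)),
    abort(sprintf("unknown archetype '%s'.", kind))
  )
}

archetype_sizes <- c(LI = 7L, LL = 18L, CY = 6L, BF = 8L, BFC = 10L, TF = 8L)

#' Generate a signed benchmark regulatory network
#'
#' Returns one of the six differentiation-trajectory archetypes — Linear
#' (LI, 7 genes), Linear Long (LL, 18), Cycle (CY, 6), Bifurcating (BF, 8),
#' Bifurcating Converging (BFC, 10), Trifurcating (TF, 8) — or a random
#' `custom` network at a requested density. Archetypes are fixed wirings
#' (deterministic regardless of seed); `custom` networks are seeded draws.
#'
#' @param kind One of `"LI"`, `"LL"`, `"CY"`, `"BF"`, `"BFC"`, `"TF"`,
#'   `"custom"`.
#' @param n_genes Gene count; only honoured for `custom` (archetypes have
#'   fixed sizes). Must be at least 2.
#' @param density Edge density for `custom` networks (default 0.2).
#' @param seed Integer seed (used by `custom`).
#' @return A signed [grn_network()].
#' @export
make_benchmark_network <- function(kind = c("LI", "LL", "CY", "BF", "BFC", "TF",
                                            "custom"),
                                   n_genes = NULL, density = 0.2, seed = 1) {
  kind <- match.arg(kind)
  if (kind != "custom") {
    size <- archetype_sizes[[kind]]
    if (!is.null(n_genes) && n_genes < size) {
      abort(sprintf("archetype %s needs at least %d genes.", kind, size))
    }
    return(grn_network(archetype_edges(kind),
                       gene_universe = paste0("g", seq_len(size))))
  }
  if (is.null(n_genes) || n_genes < 2L) abort("`n_genes` must be >= 2 for custom.")
  n_edges <- max(1L, round(density * n_genes * (n_genes - 1L)))
  withr::with_seed(as.integer(seed), {
    genes <- paste0("g", seq_len(n_genes))
    all_idx <- which(matrix(TRUE, n_genes, n_genes) & !diag(n_genes) > 0)
    off <- setdiff(seq_len(n_genes^2), pair_index(seq_len(n_genes),
                                                  seq_len(n_genes), n_genes))
    pick <- sample(off, n_edges)
    ij <- index_pair(pick, n_genes)
    grn_network(tibble(regulator = genes[ij[, 1L]], target = genes[ij[, 2L]],
                       sign = sample(c(-1L, 1L), n_edges, replace = TRUE)),
                gene_universe = genes)
  })
}

#' Simulation configuration
#'
#' Bundles the knobs of the Hill-kinetics single-cell simulator. Defaults
#' describe the standard study conditions: 2000 cells per dataset, no
#' dropout, Hill coefficient 2, moderate intrinsic noise.
#'
#' @param network_kind Archetype passed to [make_benchmark_network()].
#' @param n_genes Optional gene count (only for `custom` networks).
#' @param n_cells Number of cells to sample (>= 10). Default 2000.
#' @param dropout_q Dropout percentile `q`, typically 0, 50 or 70. Default 0.
#' @param noise_sd Scale of the multiplicative (sqrt-expression) stochastic
#'   term. Default 0.3.
#' @param hill_coefficient Hill exponent of the regulation functions (> 0).
#'   Default 2.
#' @param seed Integer seed. Default 1.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(network_kind = "LI", n_genes = NULL, n_cells = 2000L,
                       dropout_q = 0L, noise_sd = 0.3, hill_coefficient = 2,
                       seed = 1L) {
  if (n_cells < 10L) abort("`n_cells` must be >= 10.")
  if (dropout_q < 0 || dropout_q >= 100) abort("`dropout_q` must be in [0, 100).")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (hill_coefficient <= 0) abort("`hill_coefficient` must be > 0.")
  structure(list(network_kind = network_kind, n_genes = n_genes,
                 n_cells = as.integer(n_cells), dropout_q = as.integer(dropout_q),
                 noise_sd = noise_sd, hill_coefficient = hill_coefficient,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate single-cell expression along network-driven trajectories
#'
#' Integrates, per cell, the stochastic Hill-kinetics system
#' \deqn{dx_g = (\alpha \, H_g(x) - \gamma \, x_g)\,dt + \sigma \sqrt{x_g}\, dW}
#' where `H_g` multiplies Hill activation terms `x_a^n / (K^n + x_a^n)` over
#' activators and repression terms `K^n / (K^n + x_r^n)` over repressors of
#' gene g (genes without regulators have `H = 1`). Root genes start at
#' random levels and regulated genes near zero, so trajectories realize the
#' cascade; at mutually repressing branch points the winning branch is
#' decided by the stochastic initial conditions, standing in for explicit
#' branch labels. Each cell is an independent trajectory snapshotted at a
#' uniformly random time, which yields the asynchronous population a
#' single-cell experiment captures.
#'
#' @param network A signed [grn_network()].
#' @param config A [sim_config()].
#' @param alpha,gamma,K Kinetic constants: maximal production rate (2),
#'   decay rate (1), Hill half-saturation (1), giving an expression scale of
#'   `alpha / gamma = 2`.
#' @param t_max Trajectory length in units of `1 / gamma`; `NULL` (default)
#'   adapts to the network's cascade depth so distal genes have time to
#'   respond.
#' @param dt Euler-Maruyama step (default 0.05).
#' @return An [expression_matrix()] (`raw_counts`-like non-negative values,
#'   genes x cells).
#' @export
simulate_cells <- function(network, config = sim_config(), alpha = 2,
                           gamma = 1, K = 1, t_max = NULL, dt = 0.05) {
  if (!isTRUE(attr(network, "signed"))) abort("`network` must be signed.")
  genes <- gene_universe(network)
  m <- length(genes)
  n_cells <- config$n_cells
  hill_n <- config$hill_coefficient
  reg_idx <- match(network$regulator, genes)
  tgt_idx <- match(network$target, genes)
  acts <- lapply(seq_len(m), function(g) reg_idx[tgt_idx == g & network$sign > 0])
  reps <- lapply(seq_len(m), function(g) reg_idx[tgt_idx == g & network$sign < 0])
  has_reg <- lengths(acts) + lengths(reps) > 0L
  # a network with no root regulator (e.g. a pure cycle) is fine: repressed
  # genes self-start because their Hill repression term is ~1 at low input
  if (is.null(t_max)) {
    depth <- cascade_depth(reg_idx, tgt_idx, m, has_reg)
    t_max <- 2 * (depth + 2) / gamma
  }
  n_steps <- ceiling(t_max / dt)

  withr::with_seed(config$seed, {
    x <- matrix(0, m, n_cells)
    x[!has_reg, ] <- stats::runif(sum(!has_reg) * n_cells, 0, alpha / gamma)
    x[has_reg, ] <- stats::runif(sum(has_reg) * n_cells, 0, 0.1)
    snap_step <- sample.int(n_steps, n_cells, replace = TRUE)
    out <- matrix(0, m, n_cells, dimnames = list(genes, paste0("c", seq_len(n_cells))))
    kn <- K^hill_n
    for (s in seq_len(n_steps)) {
      xn <- x^hill_n
      act_frac <- xn / (kn + xn)
      h <- matrix(1, m, n_cells)
      for (g in which(has_reg)) {
        for (a in acts[[g]]) h[g, ] <- h[g, ] * act_frac[a, ]
        for (r in reps[[g]]) h[g, ] <- h[g, ] * (1 - act_frac[r, ])
      }
      drift <- (alpha * h - gamma * x) * dt
      noise <- if (config$noise_sd > 0) {
        config$noise_sd * sqrt(pmax(x, 0) * dt) *
          matrix(stats::rnorm(m * n_cells), m, n_cells)
      } else 0
      x <- pmax(x + drift + noise, 0)
      if (!all(is.finite(x))) {
        bad <- genes[which(!apply(is.finite(x), 1L, all))[1L]]
        abort(sprintf("non-finite expression for gene '%s'; unstable parameters.", bad))
      }
      hit <- snap_step == s
      if (any(hit)) out[, hit] <- x[, hit]
    }
    expression_matrix(out, transform = "raw_counts")
  })
}

# longest shortest-path distance from any root to any gene (cascade depth)
cascade_depth <- function(reg_idx, tgt_idx, m, has_reg) {
  depth <- ifelse(has_reg, NA_real_, 0)
  for (iter in seq_len(m)) {
    upd <- depth
    for (k in seq_along(reg_idx)) {
      d <- depth[reg_idx[k]] + 1
      if (!is.na(d) && (is.na(upd[tgt_idx[k]]) || d > upd[tgt_idx[k]])) {
        if (d <= m) upd[tgt_idx[k]] <- d
      }
    }
    if (identical(upd, depth)) break
    depth <- upd
  }
  if (all(is.na(depth))) return(m)  # no root (e.g. a pure cycle)
  max(depth, na.rm = TRUE)
}

#' Inject dropout (technical zero-inflation)
#'
#' Emulates scRNA-seq dropout with percentile-based lower-tail zeroing:
#' values
#' below the `q`-th percentile of the nonzero expression distribution are
#' independently set to zero with probability 0.5. `q = 0` leaves the matrix
#' untouched; existing zeros always remain zeros; no entry ever increases.
#'
#' @param expr An [expression_matrix()].
#' @param q Dropout percentile in `[0, 100)`.
#' @param seed Integer seed.
#' @return An [expression_matrix()] with the same dimensions.
#' @export
inject_dropout <- function(expr, q, seed = 1) {
  if (q < 0 || q >= 100) abort("`q` must be in [0, 100).")
  if (q == 0) return(expr)
  vals <- unclass(expr)
  nz <- vals[vals > 0]
  if (!length(nz)) return(expr)
  cutoff <- stats::quantile(nz, q / 100, names = FALSE)
  eligible <- vals > 0 & vals < cutoff
  withr::with_seed(as.integer(seed), {
    zap <- eligible & matrix(stats::runif(length(vals)) < 0.5,
                             nrow(vals), ncol(vals))
    vals[zap] <- 0
  })
  expression_matrix(vals, transform = attr(expr, "transform"))
}

#' Simulate a complete benchmark dataset
#'
#' Convenience wrapper: builds the archetype network, simulates cells,
#' injects dropout, and optionally writes the expression matrix, the signed
#' reference network and a YAML provenance file capturing every parameter.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; when given, writes
#'   `ExpressionData.csv`, `refNetwork.csv` and `simulation-config.yaml`.
#' @return A list with `expr` (an [expression_matrix()]), `network` (the
#'   signed [grn_network()]) and `config`.
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  network <- make_benchmark_network(config$network_kind, n_genes = config$n_genes,
                                    seed = config$seed)
  expr <- simulate_cells(network, config)
  expr <- inject_dropout(expr, config$dropout_q, seed = config$seed + 1L)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_expression(expr, file.path(dir, "ExpressionData.csv"))
    writeLines(c("Gene1,Gene2,Type",
                 sprintf("%s,%s,%s", network$regulator, network$target,
                         ifelse(network$sign > 0, "+", "-"))),
               file.path(dir, "refNetwork.csv"))
    yaml::write_yaml(unclass(config), file.path(dir, "simulation-config.yaml"))
  }
  list(expr = expr, network = network, config = config)
}
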