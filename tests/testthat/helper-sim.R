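# Shared fixtures: all synthetic, generated in code at test time.

# One simulated (Z, x, y) triple under the default confounded design.
sim_triple <- function(n = 1000, alpha = 1, lambda = 0, effect = 0, seed = 1,
                       config = sim_config()) {
  Z <- gen_covariates(n, config, seed = seed)
  x <- gen_grna_indicators(Z, config$tau, seed = seed + 1L)
  y <- gen_zinb_expression(Z, x, config$beta, alpha, lambda, effect = effect,
                           seed = seed + 2L)
  list(Z = Z, x = x, y = y, config = config)
}

# A small multi-gene / multi-gRNA synthetic screen with dimnames, for
# batch-level and IO tests.
sim_screen <- function(n_genes = 6, n_grnas = 3, n_cells = 600, seed = 10) {
  config <- sim_config()
  Z <- gen_covariates(n_cells, config, seed = seed)
  grna <- do.call(rbind, lapply(seq_len(n_grnas), function(g) {
    gen_grna_indicators(Z, config$tau, seed = seed + 100L + g)
  }))
  expr <- do.call(rbind, lapply(seq_len(n_genes), function(g) {
    gen_zinb_expression(Z, grna[1 + (g %% n_grnas), ], config$beta,
                        alpha = 1, lambda = 0, effect = 0,
                        seed = seed + 200L + g)
  }))
  rownames(expr) <- paste0("gene", seq_len(n_genes))
  colnames(expr) <- paste0("cell", seq_len(n_cells))
  rownames(grna) <- paste0("grna", seq_len(n_grnas))
  colnames(grna) <- colnames(expr)
  list(expr = expr, grna = grna, Z = Z, config = config)
}

# Brute-force BH step-up: scan every threshold k, reject the largest k with
# p_(k) <= k * fdr / n, flag all p at or below that order statistic.
bh_bruteforce <- function(p, fdr) {
  n <- length(p)
  ps <- sort(p)
  k <- suppressWarnings(max(which(ps <= seq_len(n) * fdr / n)))
  if (!is.finite(k)) return(rep(FALSE, n))
  p <= ps[k]
}

# Brute-force one-sample KS statistic against Uniform(0,1).
ks_bruteforce <- function(p) {
  n <- length(p)
  ps <- sort(p)
  max(pmax(abs(seq_len(n) / n - ps), abs(ps - (seq_len(n) - 1) / n)))
}
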