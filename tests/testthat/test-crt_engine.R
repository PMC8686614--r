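# A null-distribution object with known skew-t parameters (symmetric,
# effectively normal), bypassing the fit.
known_null <- function(z_samples = rnorm(500), xi = 0, omega = 1, slant = 0,
                       nu = 1e4, fit_ok = TRUE) {
  structure(list(z_samples = z_samples,
                 skew_t = structure(list(xi = xi, omega = omega, slant = slant,
                                         nu = nu, fit_ok = fit_ok,
                                         n_used = length(z_samples)),
                                    class = "skew_t_fit"),
                 B = length(z_samples)),
            class = "null_distribution")
}

test_that("tail probabilities from a fitted null follow the CDF conventions", {
  null <- known_null()
  expect_equal(crt_pvalue(0, null, "left")$p_value, 0.5, tolerance = 1e-3)
  expect_equal(crt_pvalue(qnorm(0.975), null, "two")$p_value, 0.05,
               tolerance = 1e-3)
  expect_equal(crt_pvalue(-2, null, "left")$p_value, pnorm(-2),
               tolerance = 1e-3)
  expect_identical(crt_pvalue(0, null, "left")$method, "skew_t")
})

test_that("empirical fallback uses the add-one rule", {
  set.seed(22)
  null <- known_null(z_samples = rnorm(500), fit_ok = FALSE)
  z_lo <- min(null$z_samples) - 1
  res <- crt_pvalue(z_lo, null, "left")
  expect_identical(res$method, "empirical")
  expect_equal(res$p_value, 1 / 501)
  # add-one keeps p at or above 1/(B+1) and at or below 1
  expect_equal(crt_pvalue(max(null$z_samples) + 1, null, "left")$p_value, 1)
})

test_that("p-values are monotone in the observed z for a fixed null", {
  null <- known_null(slant = 1.5, nu = 8)
  zs <- seq(-5, 5, length.out = 31)
  p_left <- vapply(zs, function(z) crt_pvalue(z, null, "left")$p_value,
                   numeric(1))
  expect_true(all(diff(p_left) >= -1e-9))
})

test_that("skew-t and empirical p-values agree within a factor of two", {
  set.seed(23)
  sim <- sim_triple(n = 1000, seed = 301)
  red <- fit_reduced_nb(sim$y, sim$Z, 1)
  prop <- fit_grna_propensity(sim$x, sim$Z)
  null <- build_null_distribution(sim$y, red$offsets, 1, prop$probabilities,
                                  B = 500, seed = 7)
  expect_true(null$skew_t$fit_ok)
  for (z in quantile(null$z_samples, c(0.05, 0.25, 0.5), na.rm = TRUE)) {
    p_st <- crt_pvalue(z, null, "left")$p_value
    null_emp <- null; null_emp$skew_t$fit_ok <- FALSE
    p_emp <- crt_pvalue(z, null_emp, "left")$p_value
    if (p_st > 0.02) {
      expect_lt(max(p_st / p_emp, p_emp / p_st), 2)
    }
  }
})

test_that("a pair with no or too few treated cells is flagged, not tested", {
  sim <- sim_triple(n = 200, seed = 41)
  res0 <- run_crt_pair(sim$y, rep(0, 200), sim$Z, 1, B = 50, seed = 1)
  expect_identical(res0$error_code, "no_treated_cells")
  expect_true(is.na(res0$p_value))
  x3 <- c(rep(1, 3), rep(0, 197))
  res3 <- run_crt_pair(sim$y, x3, sim$Z, 1, B = 50, seed = 1,
                           min_treated = 10)
  expect_identical(res3$error_code, "too_few_treated_cells")
})

test_that("strong repression yields a tiny left-tail p-value", {
  sim <- sim_triple(n = 1500, effect = -3, seed = 51)
  res <- run_crt_pair(sim$y, sim$x, sim$Z, 1, B = 500, tail = "left",
                          seed = 2)
  expect_true(is.na(res$error_code))
  expect_lt(res$p_value, 0.01)
  expect_lt(res$observed_z, 0)
})

test_that("null pairs produce uniform p-values across repetitions", {
  ps <- vapply(1:200, function(i) {
    sim <- sim_triple(n = 800, seed = 9000 + i)
    if (sum(sim$x) < 5) return(NA_real_)
    res <- run_crt_pair(sim$y, sim$x, sim$Z, 1, B = 300, tail = "two",
                            seed = 9000 + i, min_treated = 5)
    res$p_value
  }, numeric(1))
  ps <- ps[is.finite(ps)]
  expect_gt(length(ps), 150)
  expect_gt(ks_uniformity(ps)$p_value, 0.01)
})

test_that("batch results are identical across worker counts and pair order", {
  scr <- sim_screen(n_genes = 4, n_grnas = 2, n_cells = 600, seed = 61)
  pairs <- expand.grid(gene_id = rownames(scr$expr),
                       grna_id = rownames(scr$grna),
                       stringsAsFactors = FALSE)
  r1 <- run_crt_many(scr$expr, scr$grna, scr$Z, pairs, B = 100,
                         tail = "two", seed = 42, workers = 1, min_treated = 5)
  r2 <- run_crt_many(scr$expr, scr$grna, scr$Z, pairs, B = 100,
                         tail = "two", seed = 42, workers = 2, min_treated = 5)
  expect_identical(r1, r2)
  perm <- sample(nrow(pairs))
  r3 <- run_crt_many(scr$expr, scr$grna, scr$Z, pairs[perm, ], B = 100,
                         tail = "two", seed = 42, workers = 1, min_treated = 5)
  r3 <- r3[order(match(paste(r3$gene_id, r3$grna_id),
                       paste(r1$gene_id, r1$grna_id))), ]
  rownames(r3) <- NULL
  expect_identical(r1, r3)
})

test_that("per-pair failures are collected without aborting the batch", {
  scr <- sim_screen(n_genes = 3, n_grnas = 2, n_cells = 400, seed = 71)
  scr$expr["gene2", ] <- 0  # unfittable gene
  pairs <- expand.grid(gene_id = rownames(scr$expr),
                       grna_id = rownames(scr$grna),
                       stringsAsFactors = FALSE)
  disp <- setNames(rep(1, 3), rownames(scr$expr))
  res <- run_crt_many(scr$expr, scr$grna, scr$Z, pairs, dispersions = disp,
                          B = 50, seed = 1, min_treated = 5)
  expect_equal(nrow(res), 6)
  bad <- res[res$gene_id == "gene2", ]
  expect_true(all(!is.na(bad$error_code)))
  expect_true(all(is.na(bad$p_value)))
  good <- res[res$gene_id != "gene2", ]
  expect_true(any(is.finite(good$p_value)))
})
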