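test_that("moment dispersion matches the closed-form moment oracle", {
  # mean 4, variance 20 -> (20 - 4) / 16 = 1; built from an explicit vector
  y1 <- c(0, 2, 4, 6, 8)
  stopifnot(mean(y1) == 4, var(y1) == 10)
  expect_equal(moment_dispersion(y1), (10 - 4) / 16)
  set.seed(5)
  for (i in 1:20) {
    y <- rnbinom(200, mu = 5, size = 0.5)
    m <- mean(y); s2 <- var(y)
    expect_equal(moment_dispersion(y), max(0.01, (s2 - m) / m^2))
  }
})

test_that("equidispersed counts hit the dispersion floor and zero-mean genes error", {
  y <- rep(c(3, 3, 3, 3), 5)  # variance 0 <= mean
  expect_equal(moment_dispersion(y), 0.01)
  expect_equal(moment_dispersion(y, floor = 1e-4), 1e-4)
  expect_error(moment_dispersion(rep(0, 10)), "zero mean")
})

test_that("dispersion trend is exact for constant input and degenerate for one gene", {
  means <- c(0.5, 2, 8, 30)
  fit <- estimate_dispersions(means, rep(0.7, 4))
  expect_equal(fit$final_dispersion, rep(0.7, 4))
  one <- estimate_dispersions(3, 1.3)
  expect_equal(one$final_dispersion, 1.3)
  expect_equal(fit$final_dispersion, fit$fitted_trend)
})

test_that("pooled trend recovers a flat true dispersion for most genes", {
  set.seed(21)
  n_genes <- 200
  mus <- exp(runif(n_genes, log(0.5), log(20)))
  raw <- vapply(mus, function(mu) {
    moment_dispersion(rnbinom(1000, mu = mu, size = 1 / 0.5))
  }, numeric(1))
  fit <- estimate_dispersions(mus, raw)
  frac_close <- mean(abs(fit$final_dispersion - 0.5) / 0.5 <= 0.2)
  expect_gte(frac_close, 0.9)
})

test_that("reduced NB fit: intercept-only MLE is log sample mean; zero gene errors", {
  y <- c(2, 4, 4, 6)  # mean 4
  Z0 <- matrix(numeric(0), nrow = 4, ncol = 0)
  fit <- fit_reduced_nb(y, Z0, alpha = 1)
  expect_equal(fit$intercept, log(4), tolerance = 1e-6)
  expect_equal(fit$offsets, rep(log(4), 4), tolerance = 1e-6)
  expect_error(fit_reduced_nb(rep(0, 10), matrix(rnorm(10), 10, 1), 1),
               "all-zero")
})

test_that("reduced NB fit recovers generative coefficients within 3 SE", {
  cfg <- sim_config()
  Z <- gen_covariates(5000, cfg, seed = 31)
  y <- gen_zinb_expression(Z, rep(0, 5000), cfg$beta, alpha = 1, seed = 32)
  fit <- fit_reduced_nb(y, Z, alpha = 1)
  # independent SE oracle: glm with the same fixed-theta family
  g <- glm(y ~ Z, family = MASS::negative.binomial(theta = 1))
  se <- sqrt(diag(summary(g, dispersion = 1)$cov.unscaled))
  est <- c(fit$intercept, fit$covariate_coefficients)
  expect_true(all(abs(est - cfg$beta) <= 3 * se))
  expect_true(fit$converged)
})

test_that("treated-cells-only statistic equals the all-cells statistic (distillation)", {
  set.seed(77)
  for (i in 1:25) {
    sim <- sim_triple(n = 600, alpha = runif(1, 0.3, 2), seed = 1000 + i)
    if (sum(sim$x) < 5) next
    alpha_fit <- runif(1, 0.3, 2)
    red <- fit_reduced_nb(sim$y, sim$Z, alpha_fit)
    a <- distilled_z(sim$y, sim$x, red$offsets, alpha_fit)
    b <- crtscreen:::distilled_z_all_cells(sim$y, sim$x, red$offsets, alpha_fit)
    expect_equal(a$z_value, b$z_value, tolerance = 1e-6)
    expect_equal(a$beta_hat, b$beta_hat, tolerance = 1e-6)
  }
})

test_that("distilled coefficient matches the glm offset-fit oracle", {
  sim <- sim_triple(n = 800, seed = 55)
  red <- fit_reduced_nb(sim$y, sim$Z, 1)
  d <- distilled_z(sim$y, sim$x, red$offsets, 1)
  g <- glm(sim$y ~ sim$x - 1 + offset(red$offsets),
           family = MASS::negative.binomial(theta = 1))
  expect_equal(d$beta_hat, unname(coef(g)), tolerance = 1e-4)
  expect_equal(d$n_treated, sum(sim$x))
})

test_that("distilled statistic errors without treated cells", {
  sim <- sim_triple(n = 100, seed = 3)
  red <- fit_reduced_nb(sim$y, sim$Z, 1)
  expect_error(distilled_z(sim$y, rep(0, 100), red$offsets, 1), "carrying")
})

test_that("distilled z is centered under the null", {
  zs <- vapply(1:300, function(i) {
    sim <- sim_triple(n = 500, seed = 5000 + i)
    if (sum(sim$x) < 2) return(NA_real_)
    red <- fit_reduced_nb(sim$y, sim$Z, 1)
    distilled_z(sim$y, sim$x, red$offsets, 1)$z_value
  }, numeric(1))
  zs <- zs[is.finite(zs)]
  expect_lt(abs(mean(zs)), 3 * sd(zs) / sqrt(length(zs)))
})

test_that("distilled and full NB z agree closely; strong repression drives z negative", {
  devs <- vapply(1:10, function(i) {
    sim <- sim_triple(n = 1000, seed = 7000 + i)
    if (sum(sim$x) < 10) return(NA_real_)
    red <- fit_reduced_nb(sim$y, sim$Z, 1)
    d <- distilled_z(sim$y, sim$x, red$offsets, 1)
    abs(full_nb_z(sim$y, sim$x, sim$Z, 1) - d$z_value)
  }, numeric(1))
  expect_true(all(devs[is.finite(devs)] < 0.1))
  sim <- sim_triple(n = 2000, effect = -2, seed = 81)
  expect_lt(full_nb_z(sim$y, sim$x, sim$Z, 1), -4)
})

test_that("fitted NB mean is invariant to the batch reference level", {
  sim <- sim_triple(n = 500, seed = 91)
  Z1 <- sim$Z
  Z2 <- sim$Z; Z2[, "batch"] <- 1 - Z2[, "batch"]  # swap reference level
  f1 <- fit_reduced_nb(sim$y, Z1, 1)
  f2 <- fit_reduced_nb(sim$y, Z2, 1)
  expect_equal(f1$offsets, f2$offsets, tolerance = 1e-6)
})

test_that("normal-theory p-values follow the stated tail conventions", {
  expect_equal(parametric_pvalue(0, "two"), 1)
  expect_equal(parametric_pvalue(1.959964, "right"), 0.025, tolerance = 1e-4)
  expect_equal(parametric_pvalue(-1.644854, "left"), 0.05, tolerance = 1e-4)
  expect_equal(parametric_pvalue(1.2, "two"),
               2 * (1 - pnorm(1.2)), tolerance = 1e-12)
})

test_that("dispersion tables round-trip through TSV", {
  fit <- estimate_dispersions(c(1, 5, 20), c(0.4, 0.6, 0.5))
  fit$gene_id <- paste0("g", 1:3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dispersions(fit, path)
  back <- read_dispersions(path)
  expect_equal(back$final_dispersion, fit$final_dispersion)
  expect_identical(back$gene_id, fit$gene_id)
})
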