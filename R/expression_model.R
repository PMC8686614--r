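#' Method-of-moments raw dispersion estimate
#'
#' Estimates the NB dispersion alpha under the convention
#' `Var(Y) = mu + alpha * mu^2`, i.e. `alpha = (s^2 - m) / m^2` with sample
#' mean `m` and variance `s^2`, floored at `floor` for equidispersed or
#' underdispersed genes.
#'
#' @param y Non-negative integer count vector (one gene across cells),
#'   length >= 2.
#' @param floor Lower bound on the returned dispersion.
#' @return Positive scalar dispersion.
#' @export
moment_dispersion <- function(y, floor = 0.01) {
  stopifnot(length(y) >= 2)
  m <- mean(y)
  if (m == 0) stop("gene has zero mean expression; filter unexpressed genes")
  max(floor, (var(y) - m) / m^2)
}

#' Pool per-gene dispersions through a mean-dispersion trend
#'
#' Regresses raw dispersion estimates on mean expression by Nadaraya-Watson
#' kernel regression (Gaussian kernel, log-log scale) and projects each gene
#' onto the fitted curve: the final dispersion of a gene is the trend value
#' at its mean. Pooling stabilizes the noisy per-gene moment estimates.
#'
#' @param means Per-gene mean expression, > 0.
#' @param raw Per-gene raw dispersions (see [moment_dispersion()]), > 0.
#' @param bandwidth Kernel bandwidth on the log-mean axis; `NULL` uses
#'   Silverman's rule of thumb.
#' @return Data.frame with columns `mean_expression`, `raw_dispersion`,
#'   `fitted_trend`, `final_dispersion` (`final_dispersion` equals the trend,
#'   by construction).
#' @export
estimate_dispersions <- function(means, raw, bandwidth = NULL) {
  stopifnot(length(means) == length(raw), length(means) >= 1,
            all(means > 0), all(raw > 0))
  lx <- log(means)
  ly <- log(raw)
  n <- length(lx)
  if (n == 1 || sd(lx) == 0) {
    # degenerate trend: no mean axis to regress along
    trend <- if (n == 1) raw else rep(exp(mean(ly)), n)
  } else {
    if (is.null(bandwidth)) {
      bandwidth <- 0.9 * min(sd(lx), IQR(lx) / 1.34) * n^(-1 / 5)
      if (bandwidth <= 0) bandwidth <- sd(lx) * n^(-1 / 5)
    }
    trend <- exp(nw_smooth(lx, ly, lx, bandwidth))
  }
  data.frame(mean_expression = means, raw_dispersion = raw,
             fitted_trend = trend, final_dispersion = trend)
}

# Nadaraya-Watson estimate of y on x evaluated at x0 (Gaussian kernel).
nw_smooth <- function(x, y, x0, h) {
  vapply(x0, function(xq) {
    w <- exp(-0.5 * ((x - xq) / h)^2)
    sum(w * y) / sum(w)
  }, numeric(1))
}

#' @importFrom stats IQR
NULL

#' Fit the reduced (covariates-only) negative-binomial model
#'
#' Fits `Y ~ NB(mu, alpha)` with `log(mu) = beta0 + Z' gamma` — the gRNA-free
#' regression whose fitted linear predictor becomes the fixed per-cell offset
#' of the distilled statistic. The dispersion is held fixed
#' (`size = 1/alpha`); only the regression coefficients are estimated, by
#' IRLS via [stats::glm()].
#'
#' @param y Count vector.
#' @param Z Numeric covariate matrix, one row per cell (no intercept column).
#' @param alpha Fixed NB dispersion, `Var = mu + alpha mu^2`.
#' @return List of class `reduced_nb_fit`: `intercept`,
#'   `covariate_coefficients`, `offsets` (per-cell fitted linear predictor),
#'   `alpha`, `converged`.
#' @export
fit_reduced_nb <- function(y, Z, alpha) {
  stopifnot(alpha > 0, nrow(Z) == length(y) || ncol(Z) == 0)
  if (all(y == 0)) stop("all-zero gene: cannot fit expression model")
  fam <- MASS::negative.binomial(theta = 1 / alpha)
  df <- data.frame(y = y)
  if (ncol(Z) > 0) {
    Zm <- as.matrix(Z)
    colnames(Zm) <- paste0("z", seq_len(ncol(Zm)))
    df <- cbind(df, Zm)
    fit <- suppressWarnings(glm(y ~ ., data = df, family = fam))
  } else {
    fit <- suppressWarnings(glm(y ~ 1, data = df, family = fam))
  }
  cf <- coef(fit)
  if (any(!is.finite(cf))) stop("reduced NB fit produced non-finite coefficients")
  structure(list(
    intercept = unname(cf[1]),
    covariate_coefficients = unname(cf[-1]),
    offsets = unname(predict(fit, type = "link")),
    alpha = alpha,
    converged = fit$converged
  ), class = "reduced_nb_fit")
}

#' Distilled negative-binomial z-statistic
#'
#' Fits the single gRNA coefficient beta with the reduced-model linear
#' predictor held fixed as an offset, using only the cells that carry the
#' gRNA. Dropping the non-carrier cells changes the log-likelihood by a
#' constant only, so the estimate and its curvature match the all-cells fit
#' while the cost scales with the (small) number of carrier cells — this is
#' what makes rescoring hundreds of resamples cheap.
#'
#' @param y Count vector over all cells.
#' @param x Binary gRNA indicator over all cells; at least one 1.
#' @param offsets Per-cell offsets from [fit_reduced_nb()] on the same
#'   `(y, Z, alpha)`.
#' @param alpha Fixed NB dispersion (same value as the reduced fit).
#' @return List of class `distilled_stat`: `beta_hat`, `z_value`
#'   (Wald, observed-information SE), `n_treated`, `converged`.
#' @export
distilled_z <- function(y, x, offsets, alpha) {
  stopifnot(length(x) == length(y), length(offsets) == length(y), alpha > 0)
  idx <- which(x == 1)
  if (length(idx) == 0) stop("x has no gRNA-carrying cells")
  res <- distill_fit_cpp(y[idx], offsets[idx], 1 / alpha)
  structure(list(beta_hat = res$beta, z_value = res$z,
                 n_treated = length(idx), converged = res$converged),
            class = "distilled_stat")
}

# All-cells formulation of the distilled statistic: same likelihood up to a
# constant, implemented independently of the treated-cells C++ path (plain-R
# Newton over every cell with x*beta in the linear predictor). Used as an
# internal equivalence oracle.
distilled_z_all_cells <- function(y, x, offsets, alpha) {
  stopifnot(any(x == 1))
  theta <- 1 / alpha
  beta <- log(sum(y[x == 1]) / sum(exp(offsets[x == 1])))
  for (iter in 1:100) {
    mu <- exp(x * beta + offsets)
    score <- sum(x * theta * (y - mu) / (mu + theta))
    info <- sum(x^2 * theta * mu * (y + theta) / (mu + theta)^2)
    step <- score / info
    beta <- beta + step
    if (abs(step) < 1e-12) break
  }
  mu <- exp(x * beta + offsets)
  info <- sum(x^2 * theta * mu * (y + theta) / (mu + theta)^2)
  list(beta_hat = beta, z_value = beta * sqrt(info))
}

#' Full (non-distilled) negative-binomial z-statistic
#'
#' Joint NB GLM of `y` on the gRNA indicator and all covariates with fixed
#' dispersion; returns the Wald z for the gRNA coefficient. Used as the
#' comparison ("improved NB") method and as a cross-check on the distilled
#' statistic.
#'
#' @inheritParams distilled_z
#' @param Z Covariate matrix.
#' @return Scalar z-value.
#' @export
full_nb_z <- function(y, x, Z, alpha) {
  stopifnot(any(x == 1), alpha > 0)
  fam <- MASS::negative.binomial(theta = 1 / alpha)
  df <- data.frame(y = y, x = x)
  if (ncol(Z) > 0) {
    Zm <- as.matrix(Z)
    colnames(Zm) <- paste0("z", seq_len(ncol(Zm)))
    df <- cbind(df, Zm)
  }
  fit <- suppressWarnings(glm(y ~ ., data = df, family = fam))
  # dispersion = 1: the NB variance function already carries the fixed alpha,
  # so the Wald z must not be rescaled by an estimated dispersion factor
  unname(coef(summary(fit, dispersion = 1))["x", "z value"])
}

#' Parametric normal-theory p-value for a z-statistic
#'
#' The tail probability the z-value would be assigned under the standard
#' normal reference of the parametric NB model (the quantity the conditional
#' randomization test replaces).
#'
#' @param z Finite z-value.
#' @param tail `"left"`, `"right"`, or `"two"` (two-sided,
#'   `2 * min(left, right)` capped at 1).
#' @return p-value in (0, 1].
#' @export
parametric_pvalue <- function(z, tail = c("two", "left", "right")) {
  tail <- match.arg(tail)
  stopifnot(is.finite(z))
  left <- pnorm(z)
  switch(tail,
    left = left,
    right = 1 - left,
    two = min(1, 2 * min(left, 1 - left))
  )
}

#' Read / write a cached dispersion table
#'
#' @param disp Data.frame as returned by [estimate_dispersions()], plus an
#'   optional `gene_id` column.
#' @param path TSV path.
#' @export
write_dispersions <- function(disp, path) {
  write.table(disp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dispersions
#' @export
read_dispersions <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
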