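#' Simulation configuration for synthetic screens
#'
#' Defaults emulate a high-MOI CRISPRi screen with confounded gRNA presence:
#' two technical covariates (binary batch, natural-log sequencing depth), a
#' logistic gRNA propensity with `tau = (-7, -2, 0.5)`, and zero-inflated NB
#' expression with `beta = (-2.5, -2, 0.5)`. The depth generator (normal on
#' the log scale, mean 8.9, sd 0.3, i.e. a median depth of ~7300 UMIs) was
#' calibrated by Monte Carlo so that under these coefficients the mean gRNA
#' presence probability is about 0.04 and the mean expression about 4 — the
#' design properties the simulation is built around.
#'
#' @param n_cells Cells per simulated dataset.
#' @param tau Propensity coefficients `(tau0, tau_batch, tau_depth)`.
#' @param beta Expression coefficients `(beta0, beta_batch, beta_depth)`.
#' @param alpha True NB dispersion (`Var = mu + alpha mu^2`).
#' @param lambda Zero-inflation rate in `[0, 1]`.
#' @param depth_log_mean,depth_log_sd Log-scale depth distribution.
#' @param n_sim Repetitions for calibration studies.
#' @param B Resamples per conditional randomization test.
#' @param seed Master seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_cells = 1000, tau = c(-7, -2, 0.5),
                       beta = c(-2.5, -2, 0.5), alpha = 1, lambda = 0,
                       depth_log_mean = 8.9, depth_log_sd = 0.3,
                       n_sim = 500, B = 500, seed = 1) {
  stopifnot(lambda >= 0, lambda <= 1, alpha > 0, n_cells >= 1)
  structure(list(n_cells = n_cells, tau = tau, beta = beta, alpha = alpha,
                 lambda = lambda, depth_log_mean = depth_log_mean,
                 depth_log_sd = depth_log_sd, n_sim = n_sim, B = B,
                 seed = seed), class = "sim_config")
}

#' Generate synthetic per-cell covariates
#'
#' `Z1` is a binary batch indicator (Bernoulli(0.5)); `Z2` is the natural log
#' of a lognormal sequencing depth, i.e. normal on the log scale.
#'
#' @param n Number of cells.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Numeric matrix with columns `batch`, `log_depth`.
#' @export
gen_covariates <- function(n, config = sim_config(), seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cbind(batch = rbinom(n, 1, 0.5),
        log_depth = rnorm(n, config$depth_log_mean, config$depth_log_sd))
}

#' Generate gRNA indicators from the logistic propensity model
#'
#' `X_i ~ Bernoulli(pi_i)` with `logit(pi_i) = tau0 + Z_i' tau`.
#'
#' @param Z Covariate matrix.
#' @param tau Coefficients `(tau0, tau_1, ..., tau_d)`.
#' @param seed Integer seed.
#' @return Integer 0/1 vector.
#' @export
gen_grna_indicators <- function(Z, tau, seed = 1) {
  stopifnot(length(tau) == 1 + ncol(Z))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pi <- 1 / (1 + exp(-(tau[1] + drop(as.matrix(Z) %*% tau[-1]))))
  rbinom(nrow(Z), 1, pi)
}

#' Generate zero-inflated negative-binomial expression
#'
#' With probability `lambda` a cell's count is an exact zero; otherwise
#' `Y_i ~ NB(mu_i, alpha)` with
#' `log(mu_i) = beta0 + Z_i' beta + x_i * effect`. `effect = 0` gives the
#' global null (gRNA presence does not affect expression); a negative
#' `effect` emulates CRISPRi repression.
#'
#' @param Z Covariate matrix.
#' @param x Binary gRNA indicator (ignored when `effect = 0`).
#' @param beta Coefficients `(beta0, beta_1, ..., beta_d)`.
#' @param alpha NB dispersion, `Var = mu + alpha mu^2`.
#' @param lambda Zero-inflation rate.
#' @param effect Log-scale gRNA effect.
#' @param seed Integer seed.
#' @return Integer count vector.
#' @export
gen_zinb_expression <- function(Z, x, beta, alpha, lambda = 0, effect = 0,
                                seed = 1) {
  stopifnot(length(beta) == 1 + ncol(Z), alpha > 0, lambda >= 0, lambda <= 1)
  n <- nrow(Z)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mu <- exp(beta[1] + drop(as.matrix(Z) %*% beta[-1]) + x * effect)
  y <- rnbinom(n, size = 1 / alpha, mu = mu)
  if (lambda > 0) y[runif(n) < lambda] <- 0L
  y
}

#' Four-setting calibration settings
#'
#' The dispersion / zero-inflation combinations of the calibration study:
#' setting 1 `(lambda, alpha) = (0, 1)` (analysis model correctly specified),
#' setting 2 `(0, 5)`, setting 3 `(0, 0.2)`, setting 4 `(0.25, 1)`.
#'
#' @return Data.frame with columns `setting`, `lambda`, `alpha`.
#' @export
calibration_settings <- function() {
  data.frame(setting = 1:4, lambda = c(0, 0, 0, 0.25), alpha = c(1, 5, 0.2, 1))
}

#' Run the null calibration study
#'
#' For each setting and repetition: draw covariates, gRNA indicators, and
#' null expression (no gRNA effect); compute a two-sided p-value from the
#' parametric NB method (distilled z vs standard normal) and from the
#' conditional randomization test (same z vs the skew-t-smoothed resampling
#' null). Both analyses fix the dispersion at `analysis_alpha` (default 1),
#' so settings 2-4 probe robustness to a misspecified expression model.
#'
#' @param settings Data.frame as from [calibration_settings()] (subset to run
#'   fewer settings).
#' @param n_sim Repetitions per setting.
#' @param methods Character subset of `c("crt", "nb_parametric")`.
#' @param config Base [sim_config()] (cells, coefficients, B).
#' @param analysis_alpha Dispersion assumed by the analysis models.
#' @param seed Master seed; repetition r of setting s uses the derived seed
#'   `pair_seed(seed, s, r)`.
#' @return List of class `calibration_study`: `p_values` (named list of
#'   `n_sim` x nrow(settings) matrices), `n_failed` (fit failures per
#'   setting), `summary` data.frame with per method/setting KS statistics and
#'   empirical type-I error at nominal 0.01 / 0.05 / 0.1.
#' @export
run_calibration_study <- function(settings = calibration_settings(),
                                  n_sim = 500,
                                  methods = c("crt", "nb_parametric"),
                                  config = sim_config(),
                                  analysis_alpha = 1, seed = 1) {
  methods <- match.arg(methods, c("crt", "nb_parametric"), several.ok = TRUE)
  S <- nrow(settings)
  pmats <- lapply(setNames(methods, methods),
                  function(m) matrix(NA_real_, n_sim, S))
  n_failed <- integer(S)
  for (s in seq_len(S)) {
    for (r in seq_len(n_sim)) {
      sr_seed <- pair_seed(seed, paste0("setting", settings$setting[s]),
                           paste0("rep", r))
      Z <- gen_covariates(config$n_cells, config, seed = sr_seed)
      x <- gen_grna_indicators(Z, config$tau, seed = sr_seed + 1L)
      y <- gen_zinb_expression(Z, x, config$beta, settings$alpha[s],
                               settings$lambda[s], effect = 0,
                               seed = sr_seed + 2L)
      if (sum(x) < 2 || sum(y) == 0) { n_failed[s] <- n_failed[s] + 1L; next }
      res <- tryCatch({
        reduced <- fit_reduced_nb(y, Z, analysis_alpha)
        obs <- distilled_z(y, x, reduced$offsets, analysis_alpha)
        if (!is.finite(obs$z_value)) stop("statistic did not converge")
        out <- list()
        if ("nb_parametric" %in% methods) {
          out$nb_parametric <- parametric_pvalue(obs$z_value, "two")
        }
        if ("crt" %in% methods) {
          prop <- fit_grna_propensity(x, Z)
          null <- build_null_distribution(y, reduced$offsets, analysis_alpha,
                                          prop$probabilities, config$B,
                                          seed = sr_seed + 3L)
          out$crt <- crt_pvalue(obs$z_value, null, "two")$p_value
        }
        out
      }, error = function(e) NULL)
      if (is.null(res)) { n_failed[s] <- n_failed[s] + 1L; next }
      for (m in names(res)) pmats[[m]][r, s] <- res[[m]]
    }
  }
  rows <- list()
  for (m in methods) for (s in seq_len(S)) {
    p <- pmats[[m]][, s]
    p <- p[!is.na(p)]
    ks <- ks_uniformity(p)
    rows[[length(rows) + 1]] <- data.frame(
      method = m, setting = settings$setting[s], lambda = settings$lambda[s],
      alpha = settings$alpha[s], n_used = length(p),
      ks_statistic = ks$statistic, ks_p_value = ks$p_value,
      type1_at_01 = mean(p <= 0.01), type1_at_05 = mean(p <= 0.05),
      type1_at_10 = mean(p <= 0.1))
  }
  structure(list(p_values = pmats, n_failed = n_failed,
                 summary = do.call(rbind, rows), settings = settings),
            class = "calibration_study")
}
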