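#' Fit the gRNA propensity model
#'
#' Logistic regression of gRNA presence on per-cell technical factors:
#' `logit(pi_i) = tau0 + Z_i' tau`. The fitted probabilities `pi_i` drive the
#' conditional resampling of the gRNA indicator. When the MLE is unstable
#' (complete or quasi-complete separation, detected via boundary fitted
#' probabilities or diverging coefficients), the fit is redone with a small
#' ridge penalty on standardized covariates so that coefficients stay finite.
#'
#' @param x Binary gRNA indicator vector with at least one 0 and one 1.
#' @param Z Numeric covariate matrix, one row per cell.
#' @param ridge Ridge penalty used on fallback (glmnet `lambda`, alpha = 0,
#'   standardized covariates).
#' @param clip Fitted probabilities are clipped to `[clip, 1 - clip]` so that
#'   log-scale diagnostics stay finite.
#' @return List of class `grna_propensity_fit`: `intercept`, `coefficients`,
#'   `probabilities` (per cell, strictly inside (0,1)), `regularization_used`.
#' @export
fit_grna_propensity <- function(x, Z, ridge = 1e-4, clip = 1e-8) {
  stopifnot(nrow(Z) == length(x) || ncol(Z) == 0)
  if (all(x == x[1])) stop("gRNA indicator is constant; propensity model undefined")
  if (ncol(Z) == 0) {
    p <- mean(x)
    return(structure(list(intercept = log(p / (1 - p)), coefficients = numeric(0),
                          probabilities = rep(p, length(x)),
                          regularization_used = FALSE),
                     class = "grna_propensity_fit"))
  }
  Zm <- as.matrix(Z)
  fit <- suppressWarnings(glm(x ~ Zm, family = binomial()))
  pr <- fit$fitted.values
  separated <- !fit$converged || any(!is.finite(coef(fit))) ||
    max(abs(coef(fit))) > 50 || any(pr < 1e-10) || any(pr > 1 - 1e-10)
  if (separated) {
    # glmnet needs >= 2 columns; pad with an all-zero dummy when necessary
    Zp <- if (ncol(Zm) < 2) cbind(Zm, 0) else Zm
    gfit <- glmnet::glmnet(Zp, x, family = "binomial", alpha = 0,
                           lambda = ridge, standardize = TRUE)
    b0 <- as.numeric(gfit$a0)
    b <- as.numeric(gfit$beta)[seq_len(ncol(Zm))]
    eta <- b0 + drop(Zm %*% b)
    pr <- 1 / (1 + exp(-eta))
    cf <- c(b0, b)
  } else {
    cf <- unname(coef(fit))
  }
  pr <- pmin(pmax(pr, clip), 1 - clip)
  structure(list(intercept = cf[1], coefficients = cf[-1],
                 probabilities = unname(pr),
                 regularization_used = separated),
            class = "grna_propensity_fit")
}

#' Conditionally resample gRNA indicators
#'
#' Draws `B` independent resamples of the gRNA indicator,
#' `X~_i ~ Bernoulli(pi_i)` independently per cell, holding expression and
#' covariates fixed. Deterministic given `seed`.
#'
#' @param probabilities Per-cell presence probabilities in `[0, 1]`.
#' @param B Number of resamples.
#' @param seed Integer seed.
#' @return Integer matrix, `B` rows (resamples) by `n` cells.
#' @export
resample_grna <- function(probabilities, B, seed) {
  stopifnot(B >= 1, all(probabilities >= 0 & probabilities <= 1))
  n <- length(probabilities)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  u <- matrix(runif(B * n), nrow = B)
  m <- matrix(0L, nrow = B, ncol = n)
  m[u < rep(probabilities, each = B)] <- 1L
  m
}

# save/restore the caller's RNG state so pair-level seeding does not perturb
# surrounding code
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
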