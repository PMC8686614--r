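#' Conditional-randomization p-value for an observed z-score
#'
#' Compares the observed distilled z-value to the resampling null. When the
#' skew-t fit succeeded, tail probabilities come from the fitted CDF; on
#' failure the empirical add-one rule is used, which guarantees a positive,
#' super-uniform p-value: left tail `(1 + #{b : z_b <= z}) / (B + 1)`,
#' analogously right, two-sided `2 * min` capped at 1.
#'
#' @param observed_z Observed z-value.
#' @param null Null distribution as returned by [build_null_distribution()]
#'   (list with `z_samples` and a `skew_t` fit).
#' @param tail `"left"`, `"right"`, or `"two"`.
#' @return List: `p_value` in (0, 1], `method` (`"skew_t"` or `"empirical"`).
#' @export
crt_pvalue <- function(observed_z, null, tail = c("left", "right", "two")) {
  tail <- match.arg(tail)
  if (isTRUE(null$skew_t$fit_ok)) {
    st <- null$skew_t
    left <- pskt(observed_z, st$xi, st$omega, st$slant, st$nu)
    right <- 1 - left
    method <- "skew_t"
  } else {
    zb <- null$z_samples[is.finite(null$z_samples)]
    B <- length(zb)
    left <- (1 + sum(zb <= observed_z)) / (B + 1)
    right <- (1 + sum(zb >= observed_z)) / (B + 1)
    method <- "empirical"
  }
  p <- switch(tail, left = left, right = right,
              two = min(1, 2 * min(left, right)))
  p <- min(max(p, .Machine$double.xmin), 1)
  list(p_value = p, method = method)
}

#' Build the resampling null distribution of the distilled statistic
#'
#' Draws `B` conditional resamples of the gRNA indicator from the fitted
#' propensities, rescores each with the sparsity-accelerated distilled fit
#' (carrier cells only), and fits a skew-t to the resulting z-scores.
#'
#' @param y Count vector.
#' @param offsets Per-cell offsets from [fit_reduced_nb()].
#' @param alpha NB dispersion used by the statistic.
#' @param probabilities Per-cell gRNA propensities.
#' @param B Number of resamples.
#' @param seed Integer seed for the resampling stream.
#' @return List of class `null_distribution`: `z_samples` (length `B`, may
#'   contain NA for degenerate resamples), `skew_t` (a [fit_skew_t()]
#'   result), `B`.
#' @export
build_null_distribution <- function(y, offsets, alpha, probabilities, B = 500,
                                    seed = 1) {
  xs <- resample_grna(probabilities, B, seed)
  idx <- lapply(seq_len(B), function(b) which(xs[b, ] == 1L))
  keep <- lengths(idx) > 0
  z <- rep(NA_real_, B)
  if (any(keep)) {
    z[keep] <- distill_scores_cpp(y, offsets, 1 / alpha, idx[keep])
  }
  structure(list(z_samples = z, skew_t = fit_skew_t(z), B = B),
            class = "null_distribution")
}

#' Test one gene-gRNA pair by conditional resampling
#'
#' Runs the full per-pair procedure: reduced NB fit of expression on the
#' technical factors, observed distilled z, logistic propensity fit of gRNA
#' presence on the same factors, `B` conditional resamples rescored through
#' the distilled statistic, skew-t smoothing, and the tail p-value.
#'
#' @param y Gene UMI counts over cells.
#' @param x Binary gRNA indicator over cells.
#' @param Z Covariate matrix (see [covariate_matrix()]).
#' @param alpha NB dispersion for the statistic (typically the pooled trend
#'   value for this gene, see [estimate_dispersions()]).
#' @param B Number of resamples (default 500).
#' @param tail Tail for the p-value. The default is left-tailed: with a
#'   CRISPRi repressor, true regulatory effects reduce expression.
#' @param seed Integer seed for this pair's resampling stream.
#' @param min_treated Minimum number of gRNA-carrying cells required to test.
#' @param reduced Optional precomputed [fit_reduced_nb()] result (cache).
#' @param propensity Optional precomputed [fit_grna_propensity()] result
#'   (cache); propensities depend only on `(x, Z)`, so one fit serves every
#'   gene paired with the same gRNA.
#' @return List of class `pair_result`: `observed_z`, `p_value`, `tail`,
#'   `method`, `B`, `n_treated`, `error_code` (NA when the test ran), plus
#'   the `null` distribution.
#' @export
run_crt_pair <- function(y, x, Z, alpha, B = 500,
                             tail = c("left", "right", "two"), seed = 1,
                             min_treated = 10, reduced = NULL,
                             propensity = NULL) {
  tail <- match.arg(tail)
  out <- list(observed_z = NA_real_, p_value = NA_real_, tail = tail,
              method = NA_character_, B = B, n_treated = sum(x == 1),
              error_code = NA_character_, null = NULL)
  class(out) <- "pair_result"
  if (out$n_treated == 0) { out$error_code <- "no_treated_cells"; return(out) }
  if (out$n_treated < min_treated) { out$error_code <- "too_few_treated_cells"; return(out) }
  res <- tryCatch({
    if (is.null(reduced)) reduced <- fit_reduced_nb(y, Z, alpha)
    obs <- distilled_z(y, x, reduced$offsets, alpha)
    if (!is.finite(obs$z_value)) stop("observed statistic did not converge")
    if (is.null(propensity)) propensity <- fit_grna_propensity(x, Z)
    null <- build_null_distribution(y, reduced$offsets, alpha,
                                    propensity$probabilities, B, seed)
    pv <- crt_pvalue(obs$z_value, null, tail)
    list(obs = obs, null = null, pv = pv)
  }, error = function(e) e)
  if (inherits(res, "error")) {
    out$error_code <- conditionMessage(res)
    return(out)
  }
  out$observed_z <- res$obs$z_value
  out$p_value <- res$pv$p_value
  out$method <- res$pv$method
  out$null <- res$null
  out
}

# Deterministic per-pair seed: polynomial string hash of
# "<master>:<gene>:<grna>". Kept below 2e9 so small additive stream offsets
# stay inside the 32-bit integer range. Independent of pair order and worker
# count by construction.
pair_seed <- function(master_seed, gene_id, grna_id) {
  s <- paste(master_seed, gene_id, grna_id, sep = ":")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2000000000
  as.integer(h)
}

#' Test many gene-gRNA pairs
#'
#' Runs [run_crt_pair()] over a pair table with per-gene reduced-fit and
#' per-gRNA propensity caching. Each pair draws its randomness from a seed
#' derived from the master seed and the pair's IDs, so results are identical
#' regardless of worker count, chunking, or pair order. Per-pair failures are
#' recorded in `error_code`, never abort the batch.
#'
#' @param expr Gene-by-cell count matrix with rownames.
#' @param grna_assignments Binary gRNA-by-cell matrix with rownames.
#' @param Z Covariate matrix, one row per cell.
#' @param pairs Data.frame with columns `gene_id`, `grna_id` (extra columns
#'   such as `pair_type` are carried through).
#' @param dispersions Named per-gene dispersion vector; `NULL` estimates the
#'   pooled trend from `expr` (see [estimate_dispersions()]).
#' @param B,tail,min_treated Passed to [run_crt_pair()].
#' @param seed Master seed.
#' @param workers Number of forked workers (`parallel::mclapply`); 1 runs
#'   serially. Results do not depend on this value.
#' @return Data.frame, one row per pair: `gene_id`, `grna_id`, `n_treated`,
#'   `z_observed`, `p_value`, `tail`, `method`, `error_code`, plus carried
#'   columns.
#' @export
run_crt_many <- function(expr, grna_assignments, Z, pairs,
                             dispersions = NULL, B = 500,
                             tail = c("left", "right", "two"), seed = 1,
                             workers = 1, min_treated = 10) {
  tail <- match.arg(tail)
  stopifnot(all(pairs$gene_id %in% rownames(expr)),
            all(pairs$grna_id %in% rownames(grna_assignments)))
  genes <- unique(as.character(pairs$gene_id))
  grnas <- unique(as.character(pairs$grna_id))
  if (is.null(dispersions)) {
    means <- Matrix::rowMeans(expr[genes, , drop = FALSE])
    raw <- vapply(genes, function(g) moment_dispersion(as.numeric(expr[g, ])),
                  numeric(1))
    disp <- estimate_dispersions(means, raw)
    dispersions <- setNames(disp$final_dispersion, genes)
  }
  reduced_cache <- lapply(setNames(genes, genes), function(g) {
    tryCatch(fit_reduced_nb(as.numeric(expr[g, ]), Z, dispersions[[g]]),
             error = function(e) e)
  })
  prop_cache <- lapply(setNames(grnas, grnas), function(r) {
    tryCatch(fit_grna_propensity(as.numeric(grna_assignments[r, ]), Z),
             error = function(e) e)
  })
  one <- function(k) {
    g <- as.character(pairs$gene_id[k])
    r <- as.character(pairs$grna_id[k])
    x <- as.numeric(grna_assignments[r, ])
    red <- reduced_cache[[g]]
    prop <- prop_cache[[r]]
    if (inherits(red, "error")) {
      return(data.frame(gene_id = g, grna_id = r, n_treated = sum(x),
                        z_observed = NA_real_, p_value = NA_real_, tail = tail,
                        method = NA_character_,
                        error_code = conditionMessage(red)))
    }
    if (inherits(prop, "error")) {
      return(data.frame(gene_id = g, grna_id = r, n_treated = sum(x),
                        z_observed = NA_real_, p_value = NA_real_, tail = tail,
                        method = NA_character_,
                        error_code = conditionMessage(prop)))
    }
    res <- run_crt_pair(as.numeric(expr[g, ]), x, Z, dispersions[[g]],
                            B = B, tail = tail,
                            seed = pair_seed(seed, g, r),
                            min_treated = min_treated,
                            reduced = red, propensity = prop)
    data.frame(gene_id = g, grna_id = r, n_treated = res$n_treated,
               z_observed = res$observed_z, p_value = res$p_value,
               tail = tail, method = res$method, error_code = res$error_code)
  }
  ks <- seq_len(nrow(pairs))
  rows <- if (workers > 1) {
    parallel::mclapply(ks, one, mc.cores = workers)
  } else {
    lapply(ks, one)
  }
  out <- do.call(rbind, rows)
  extra <- setdiff(names(pairs), names(out))
  if (length(extra)) out <- cbind(out, pairs[, extra, drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Write a pair-result table
#'
#' @param results Data.frame from [run_crt_many()].
#' @param path TSV path.
#' @export
write_results <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
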