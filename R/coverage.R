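#' Empirical coverage of the percentile bootstrap interval
#'
#' Simulation experiment validating the bootstrap confidence interval of the
#' control-coefficient estimator under the lognormal measurement model at the
#' study's pooled per-line sample sizes. Each replicate draws HET and WT
#' concentrations lognormally around fixed medians, forms the
#' `level`-percentile bootstrap CI for lambda with [bootstrap_ci()], and
#' records whether it covers the finite-change target lambda defined by the
#' median ratio and the expression ratio `r`.
#'
#' @param n_rep Number of replicate datasets (default 500).
#' @param n_het,n_wt Plants per arm (defaults 240 and 128: 15 and 8
#'   replicates across 16 conditions).
#' @param r Expression ratio defining the target (default 0.5).
#' @param sigma_log Lognormal noise SD (default 0.35).
#' @param medians Length-2 numeric `c(het, wt)` of true medians; default is
#'   the kinetic model's 3MSOP steady state for a CYP79F1 knockdown at `r`
#'   against wild type.
#' @param n_boot,level Bootstrap settings (defaults 1000 resamples, 0.95).
#' @param seed Integer master seed; replicate `i` uses child seeds derived
#'   from `seed + i`.
#' @return A one-row tibble: `coverage` (proportion), `se` (binomial Monte
#'   Carlo standard error), `n_rep`, `target_lambda`, `n_het`, `n_wt`,
#'   `n_boot`, `level`.
#' @export
coverage_simulation <- function(n_rep = 500, n_het = 240, n_wt = 128,
                                r = 0.5, sigma_log = 0.35, medians = NULL,
                                n_boot = 1000, level = 0.95, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (is.null(medians)) {
    model <- build_pathway_model()
    wt_med <- product_concentrations(model)[["3MSOP"]]
    het_med <- product_concentrations(
      apply_knockdown(model, "CYP79F1", r))[["3MSOP"]]
    medians <- c(het = het_med, wt = wt_med)
  }
  stopifnot(length(medians) == 2, all(medians > 0))
  target <- log(medians[[1]] / medians[[2]]) / log(r)
  hits <- vapply(seq_len(n_rep), function(i) {
    draws <- withr::with_seed(seed + 2L * i, list(
      het = medians[[1]] * exp(stats::rnorm(n_het, sd = sigma_log)),
      wt = medians[[2]] * exp(stats::rnorm(n_wt, sd = sigma_log))
    ))
    ci <- bootstrap_ci(draws$het, draws$wt, r = r, n_boot = n_boot,
                       level = level, seed = seed + 2L * i + 1L)
    ci$ci_low <= target && target <= ci$ci_high
  }, logical(1))
  cov <- mean(hits)
  tibble::tibble(
    coverage = cov,
    se = sqrt(cov * (1 - cov) / n_rep),
    n_rep = n_rep, target_lambda = target,
    n_het = n_het, n_wt = n_wt, n_boot = n_boot, level = level
  )
}
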