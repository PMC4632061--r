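#' Genotype summary mean of positive concentrations
#'
#' Summarises one genotype arm's concentrations. The geometric mean
#' (`exp(mean(log(x)))`) is the default because concentrations are
#' log-transformed throughout the analysis battery; an arithmetic option is
#' provided for comparison.
#'
#' @param values Positive numeric vector.
#' @param scale `"geometric"` (default) or `"arithmetic"`.
#' @return A single summary mean.
#' @examples
#' genotype_summary(c(2, 8)) # 4
#' @export
genotype_summary <- function(values, scale = c("geometric", "arithmetic")) {
  scale <- match.arg(scale)
  if (length(values) == 0) stop("`values` must be nonempty", call. = FALSE)
  if (any(!is.finite(values) | values <= 0)) {
    stop("all concentrations must be positive and finite", call. = FALSE)
  }
  if (scale == "geometric") exp(mean(log(values))) else mean(values)
}

#' Flux control coefficient from a HET/WT contrast
#'
#' Estimates the control coefficient lambda of an enzyme on a glucosinolate
#' pool from the concentrations measured in heterozygous-knockdown (HET) and
#' wild-type (WT) plants, given the enzyme's HET/WT relative expression ratio
#' `r`. Two finite-change estimators are provided:
#'
#' * `log_ratio` (default): `lambda = ln(G_HET / G_WT) / ln(r)`, the
#'   log-deviation form — exact when the response is locally a power law in
#'   enzyme level, and symmetric in the labelling of the two arms.
#' * `fractional`: `lambda = ((G_WT - G_HET) / G_WT) / (1 - r)`, the
#'   deviation-index form.
#'
#' Here `G` is the genotype summary of [genotype_summary()] (geometric mean
#' by default). Both forms converge to the metabolic-control-analysis
#' coefficient `d ln X / d ln E` as `r -> 1`.
#'
#' @param het,wt Positive concentration vectors for the two genotype arms.
#' @param r HET/WT relative expression ratio (> 0 and != 1).
#' @param estimator `"log_ratio"` or `"fractional"`.
#' @param scale Summary scale passed to [genotype_summary()].
#' @return The scalar estimate of lambda.
#' @examples
#' estimate_lambda(het = c(2, 4), wt = c(4, 8), r = 0.25) # 0.5
#' @export
estimate_lambda <- function(het, wt, r,
                            estimator = c("log_ratio", "fractional"),
                            scale = "geometric") {
  estimator <- match.arg(estimator)
  if (!is.numeric(r) || length(r) != 1 || r <= 0) {
    stop("`r` must be a single positive value", call. = FALSE)
  }
  if (r == 1) stop("zero enzyme perturbation: r = 1", call. = FALSE)
  g_het <- genotype_summary(het, scale)
  g_wt <- genotype_summary(wt, scale)
  lambda_from_summaries(g_het, g_wt, r, estimator)
}

lambda_from_summaries <- function(g_het, g_wt, r, estimator) {
  switch(estimator,
    log_ratio = log(g_het / g_wt) / log(r),
    fractional = ((g_wt - g_het) / g_wt) / (1 - r)
  )
}

#' Percentile bootstrap confidence interval for lambda
#'
#' Resamples plants with replacement independently within each genotype arm,
#' recomputes the control-coefficient estimate on every resample with the
#' expression ratio `r` held fixed, and returns the percentile interval of
#' the resampled estimates (empirical quantiles with linear interpolation,
#' R's default type 7). A confidence interval for the raw HET/WT
#' concentration ratio is reported alongside the one for lambda.
#'
#' @inheritParams estimate_lambda
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed; required, and sufficient for reproducibility.
#' @param strata Optional pair of list columns for stratified resampling:
#'   a list with elements `het` and `wt` giving a stratum label per plant;
#'   when supplied, resampling is with replacement within each stratum of
#'   each arm. Default (`NULL`) resamples each whole arm, matching the
#'   pooled-environment analysis.
#' @return A one-row tibble: `lambda`, `ci_low`, `ci_high`, `ratio`,
#'   `ratio_low`, `ratio_high`, `n_het`, `n_wt`, `n_boot`, `level`,
#'   `estimator`.
#' @export
bootstrap_ci <- function(het, wt, r, estimator = c("log_ratio", "fractional"),
                         n_boot = 1000, level = 0.95, seed, strata = NULL,
                         scale = "geometric") {
  estimator <- match.arg(estimator)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (length(het) < 2 || length(wt) < 2) {
    stop("both arms need >= 2 plants to bootstrap", call. = FALSE)
  }
  point <- estimate_lambda(het, wt, r, estimator, scale)
  lx_het <- if (scale == "geometric") log(het) else het
  lx_wt <- if (scale == "geometric") log(wt) else wt
  idx <- withr::with_seed(seed, list(
    het = draw_indices(length(het), n_boot, strata$het),
    wt = draw_indices(length(wt), n_boot, strata$wt)
  ))
  m_het <- colMeans(matrix(lx_het[idx$het], nrow = length(het)))
  m_wt <- colMeans(matrix(lx_wt[idx$wt], nrow = length(wt)))
  g_het <- if (scale == "geometric") exp(m_het) else m_het
  g_wt <- if (scale == "geometric") exp(m_wt) else m_wt
  lam <- lambda_from_summaries(g_het, g_wt, r, estimator)
  ratio <- g_het / g_wt

  alpha <- (1 - level) / 2
  q <- stats::quantile(lam, c(alpha, 1 - alpha), names = FALSE, type = 7)
  qr <- stats::quantile(ratio, c(alpha, 1 - alpha), names = FALSE, type = 7)
  tibble::tibble(
    lambda = point, ci_low = q[1], ci_high = q[2],
    ratio = genotype_summary(het, scale) / genotype_summary(wt, scale),
    ratio_low = qr[1], ratio_high = qr[2],
    n_het = length(het), n_wt = length(wt),
    n_boot = n_boot, level = level, estimator = estimator
  )
}

# n_boot resample index columns, optionally stratified by a label vector
draw_indices <- function(n, n_boot, labels = NULL) {
  if (is.null(labels)) {
    return(matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n))
  }
  stopifnot(length(labels) == n)
  idx <- matrix(0L, nrow = n, ncol = n_boot)
  for (lv in unique(labels)) {
    pos <- which(labels == lv)
    idx[pos, ] <- matrix(pos[sample.int(length(pos), length(pos) * n_boot,
                                        replace = TRUE)],
                         nrow = length(pos))
  }
  idx
}

#' Estimate the full enzyme x compound control-coefficient table
#'
#' The headline computation: for each insertion line (enzyme) and each of the
#' seven glucosinolate compounds, estimates the control coefficient from the
#' line's HET plants against either the WT plants of all lines pooled
#' (`pooled_wt`, the reported analysis) or the same line's WT plants
#' (`per_line`), pooling across all environmental conditions, with a
#' percentile bootstrap confidence interval per cell.
#'
#' @param dataset Wide-format plant records (columns `line`, `genotype`, the
#'   seven compound columns; e.g. from [simulate_concentrations()]).
#' @param ratios Named numeric vector of HET/WT expression ratios per line.
#' @param pooling `"pooled_wt"` (default) or `"per_line"`.
#' @inheritParams bootstrap_ci
#' @param stratify_by_condition If `TRUE`, bootstrap resampling is stratified
#'   by environmental condition within each arm (default `FALSE`: the
#'   analysis pools environments).
#' @return A tibble of class `gsl_lambda_table`, one row per enzyme x
#'   compound, with estimate, CI bounds, sample sizes, and a formatted
#'   `label` column rendering each cell as e.g. `"1.118 (1.006-1.247)"`.
#'   Cells whose HET or WT arm is missing are flagged in `missing_arm` and
#'   carry `NA` estimates.
#' @export
estimate_table <- function(dataset, ratios = NULL,
                           pooling = c("pooled_wt", "per_line"),
                           estimator = c("log_ratio", "fractional"),
                           n_boot = 1000, level = 0.95, seed,
                           stratify_by_condition = FALSE) {
  pooling <- match.arg(pooling)
  estimator <- match.arg(estimator)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  lines <- intersect(names(gsl_lines()), unique(dataset$line))
  if (length(lines) == 0) stop("no known insertion lines in `dataset`",
                               call. = FALSE)
  if (is.null(ratios)) {
    ratios <- stats::setNames(rep(0.5, length(lines)), lines)
  }
  factors <- intersect(c("W", "C", "S", "J"), names(dataset))
  cond_label <- function(d) {
    if (length(factors) == 0 || !stratify_by_condition) return(NULL)
    do.call(paste, c(as.list(d[factors]), sep = ""))
  }

  cells <- tidyr::expand_grid(line = lines, compound = compound_names())
  cells$cell_seed <- seed + seq_len(nrow(cells))
  res <- purrr::pmap_dfr(cells, function(line, compound, cell_seed) {
    het_rows <- dataset[dataset$line == line & dataset$genotype == "HET", ]
    wt_rows <- if (pooling == "pooled_wt") {
      dataset[dataset$genotype == "WT", ]
    } else {
      dataset[dataset$line == line & dataset$genotype == "WT", ]
    }
    base <- tibble::tibble(
      enzyme = gsl_lines()[[line]], line = line, compound = compound,
      pooling = pooling
    )
    if (nrow(het_rows) < 2 || nrow(wt_rows) < 2) {
      return(dplyr::mutate(base, lambda = NA_real_, ci_low = NA_real_,
                           ci_high = NA_real_, ratio = NA_real_,
                           ratio_low = NA_real_, ratio_high = NA_real_,
                           n_het = nrow(het_rows), n_wt = nrow(wt_rows),
                           n_boot = n_boot, level = level,
                           estimator = estimator, missing_arm = TRUE,
                           label = NA_character_))
    }
    strata <- if (stratify_by_condition) {
      list(het = cond_label(het_rows), wt = cond_label(wt_rows))
    } else NULL
    ci <- bootstrap_ci(het_rows[[compound]], wt_rows[[compound]],
                       r = ratios[[line]], estimator = estimator,
                       n_boot = n_boot, level = level, seed = cell_seed,
                       strata = strata)
    dplyr::bind_cols(base, ci) |>
      dplyr::mutate(missing_arm = FALSE,
                    label = format_estimate(.data$lambda, .data$ci_low,
                                            .data$ci_high))
  })
  class(res) <- c("gsl_lambda_table", class(res))
  res
}

#' Render a control-coefficient estimate as "point (low-high)"
#'
#' @param lambda,ci_low,ci_high Estimate and percentile bounds.
#' @param digits Decimal places (default 3).
#' @return Character vector like `"1.118 (1.006-1.247)"`.
#' @export
format_estimate <- function(lambda, ci_low, ci_high, digits = 3) {
  sprintf("%.*f (%.*f−%.*f)", digits, lambda, digits, ci_low,
          digits, ci_high)
}

#' Reshape a lambda table to compound rows x enzyme columns
#'
#' @param table A `gsl_lambda_table` from [estimate_table()].
#' @param what Column to spread (default the formatted `label`).
#' @return A tibble with one row per compound and one column per enzyme.
#' @export
lambda_table_wide <- function(table, what = "label") {
  tidyr::pivot_wider(
    dplyr::select(table, "compound", "enzyme", dplyr::all_of(what)),
    names_from = "enzyme", values_from = dplyr::all_of(what)
  )
}
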