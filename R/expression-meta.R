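#' Median-based proportional change in expression
#'
#' The meta-analysis statistic for the MeJA expression response:
#' `(treated_median - control_median) / control_median`. Negative values mean
#' expression decreased after treatment. The statistic is scale-invariant:
#' multiplying both arms' medians by the same positive constant leaves it
#' unchanged.
#'
#' @param treated_median,control_median Per-gene median expression of the
#'   treated and control arms (vectorised; `control_median` must be > 0).
#' @return Numeric vector of proportional changes.
#' @examples
#' proportional_expression_change(200, 100) # 1
#' proportional_expression_change(50, 100)  # -0.5
#' @export
proportional_expression_change <- function(treated_median, control_median) {
  if (any(!is.finite(control_median) | control_median <= 0)) {
    stop("`control_median` must be positive and finite", call. = FALSE)
  }
  (treated_median - control_median) / control_median
}

#' Aggregate per-experiment expression changes across experiments
#'
#' Computes the per-gene proportional expression change within each
#' experiment and averages across experiments, reporting the mean, its
#' standard error, and the number of contributing experiments. Genes missing
#' from some experiments are averaged over the experiments that measured
#' them, never imputed; genes with no experiments at all are dropped with a
#' warning. With a single contributing experiment the standard error is
#' reported as `NA`.
#'
#' @param data Long tibble with columns `experiment`, `gene`, `arm`
#'   (`"treated"` / `"control"`), `median` (e.g. from
#'   [generate_expression_fixtures()] or read from CSV).
#' @return A tibble with one row per gene: `gene`, `mean_change`, `se`,
#'   `n_experiments`, plus a list column `changes` of per-experiment values.
#' @export
aggregate_expression <- function(data) {
  stopifnot(all(c("experiment", "gene", "arm", "median") %in% names(data)))
  wide <- tidyr::pivot_wider(data, id_cols = c("experiment", "gene"),
                             names_from = "arm", values_from = "median")
  if (!all(c("treated", "control") %in% names(wide))) {
    stop("`arm` must contain both 'treated' and 'control'", call. = FALSE)
  }
  complete <- !is.na(wide$treated) & !is.na(wide$control)
  dropped <- setdiff(unique(wide$gene), unique(wide$gene[complete]))
  if (length(dropped)) {
    warning("gene(s) with no complete experiment dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  wide <- wide[complete, , drop = FALSE]
  wide$change <- proportional_expression_change(wide$treated, wide$control)
  wide |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      mean_change = mean(.data$change),
      se = if (dplyr::n() > 1) {
        stats::sd(.data$change) / sqrt(dplyr::n())
      } else NA_real_,
      n_experiments = dplyr::n(),
      changes = list(.data$change)
    ) |>
    dplyr::ungroup()
}
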