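#' Reproduce the whole study in silico
#'
#' End-to-end driver: simulates the factorial experiment from the kinetic
#' model, runs the MANOVA battery and pooling logic, the univariate
#' proportional-change tables, the control-coefficient table with bootstrap
#' CIs, the herbivory experiment and its two-way ANOVA, and the expression
#' meta-analysis, writing every result as CSV into `out_dir`. The run is
#' deterministic given `seed`: each stage uses a child seed derived as
#' `seed + stage offset` (simulation +1, herbivory +2, expression +3,
#' bootstrap +4), and the fully resolved configuration is written next to
#' the outputs.
#'
#' @param seed Integer master seed.
#' @param out_dir Output directory (created if needed).
#' @param config Named list of overrides: any of `lines`,
#'   `n_wt_per_condition`, `n_het_per_condition`, `sigma_log`, `ratios`,
#'   `n_boot`, `level`, `pooling`, `estimator`, `herbivory` (list of
#'   arguments to [simulate_herbivory()]), `n_herbivory_wt`,
#'   `n_herbivory_het`, `model_config` (passed to [build_pathway_model()]).
#' @param skip Character vector of stages to skip: any of `"herbivory"`,
#'   `"expression"`.
#' @return Invisibly, a named list of the result tibbles and `out_dir`.
#' @export
run_gsl_study <- function(seed, out_dir, config = list(), skip = character()) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cfg <- utils::modifyList(list(
    lines = names(gsl_lines()),
    n_wt_per_condition = 8,
    n_het_per_condition = 15,
    sigma_log = 0.35,
    ratios = stats::setNames(rep(0.5, 3), names(gsl_lines())),
    n_boot = 1000,
    level = 0.95,
    pooling = "pooled_wt",
    estimator = "log_ratio",
    n_herbivory_wt = 40,
    n_herbivory_het = 40,
    model_config = NULL
  ), config)

  model <- build_pathway_model(cfg$model_config)
  results <- list(out_dir = out_dir)
  write_out <- function(x, name) {
    readr::write_csv(x, file.path(out_dir, name))
    x
  }

  # resolved configuration, flattened to key/value
  flat_cfg <- c(
    list(seed = seed),
    cfg[c("n_wt_per_condition", "n_het_per_condition", "sigma_log",
          "n_boot", "level", "pooling", "estimator",
          "n_herbivory_wt", "n_herbivory_het")],
    stats::setNames(as.list(cfg$ratios), paste0("ratio_", names(cfg$ratios))),
    list(lines = paste(cfg$lines, collapse = ";"),
         skip = paste(skip, collapse = ";"))
  )
  write_out(tibble::tibble(key = names(flat_cfg),
                           value = vapply(flat_cfg, as.character,
                                          character(1))),
            "run_config.csv")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  design <- stage("design", generate_design(
    lines = cfg$lines,
    n_wt_per_condition = cfg$n_wt_per_condition,
    n_het_per_condition = cfg$n_het_per_condition
  ))
  write_out(design, "design.csv")
  results$design <- design

  plants <- stage("simulate", simulate_concentrations(
    design, model = model, ratios = cfg$ratios,
    sigma_log = cfg$sigma_log, seed = seed + 1
  ))
  write_out(plants, "plants.csv")
  write_out(pivot_concentrations_long(plants), "plants_long.csv")
  results$plants <- plants

  table1 <- stage("manova", manova_by_line(plants, pooling = cfg$pooling))
  write_out(table1, "table1.csv")
  results$table1 <- table1

  pooling <- stage("pooling", pooling_policy(
    gsl_manova(dplyr::bind_rows(
      plants[plants$genotype == "HET" & plants$line == cfg$lines[1], ],
      plants[plants$genotype == "WT", ]
    ))
  ))
  results$pooling <- pooling

  heat <- stage("heatmap-table", proportional_change_table(plants))
  write_out(heat, "fig2_fig3.csv")
  results$prop_change <- heat

  table2 <- stage("estimate", estimate_table(
    plants, ratios = cfg$ratios, pooling = cfg$pooling,
    estimator = cfg$estimator, n_boot = cfg$n_boot, level = cfg$level,
    seed = seed + 4
  ))
  write_out(table2, "table2.csv")
  write_out(lambda_table_wide(table2), "table2_wide.csv")
  results$table2 <- table2

  if (!"herbivory" %in% skip) {
    herb_design <- stage("herbivory", generate_design(
      lines = "Cyp79f1", n_wt_per_condition = cfg$n_herbivory_wt,
      n_het_per_condition = cfg$n_herbivory_het, factors = character(0)
    ))
    herb_plants <- stage("herbivory", simulate_concentrations(
      herb_design, model = model,
      ratios = cfg$ratios["Cyp79f1"], sigma_log = cfg$sigma_log,
      seed = seed + 2
    ))
    herb <- stage("herbivory", simulate_herbivory(herb_plants,
                                                  seed = seed + 2))
    write_out(herb, "herbivory.csv")
    herb_anova <- stage("herbivory", herbivory_anova(herb))
    write_out(herb_anova, "herbivory_anova.csv")
    results$herbivory <- herb
    results$herbivory_anova <- herb_anova
  }

  if (!"expression" %in% skip) {
    expr <- stage("meta", generate_expression_fixtures(seed = seed + 3))
    write_out(expr, "expression.csv")
    meta <- stage("meta", aggregate_expression(expr))
    write_out(dplyr::select(meta, -"changes"), "fig5.csv")
    results$expression <- expr
    results$meta <- meta
  }

  invisible(results)
}
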