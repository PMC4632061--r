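#' Default environmental treatment effects
#'
#' Multiplicative modifiers applied to pathway steps under each of the four
#' environmental treatments of the factorial design: reduced water (`W`),
#' mechanical leaf crushing (`C`), reduced soil nutrients (`S`), and methyl
#' jasmonate application (`J`). Factors act on catalytic levels and influx
#' pseudo-steps and combine multiplicatively when treatments overlap.
#'
#' The magnitudes are repo-frozen simulator constants chosen once so that the
#' qualitative response pattern of the real pathway is reproduced; only their
#' signs carry meaning. In particular the `J` modifier raises every
#' glucosinolate enzyme and both influxes except CYP81F2, which it lowers —
#' the MeJA expression signature that makes 4OHI3M drop while I3M and 1MOI3M
#' rise.
#'
#' @return A named list mapping treatment -> named numeric vector of positive
#'   factors (step id -> factor).
#' @export
default_environment_effects <- function() {
  enz <- gsl_enzymes()
  real_enzymes <- enz$enzyme[!enz$pseudo]
  up <- function(f) stats::setNames(rep(f, length(real_enzymes)), real_enzymes)
  j <- up(1.5)
  j[["CYP81F2"]] <- 0.5
  list(
    W = c(INFLUX_ALI = 1.25, INFLUX_IND = 1.25),
    C = c(up(1.2), INFLUX_ALI = 1.3, INFLUX_IND = 1.3),
    S = c(INFLUX_ALI = 0.75, INFLUX_IND = 0.85),
    J = c(j, INFLUX_ALI = 1.5, INFLUX_IND = 1.5)
  )
}

# combine the modifiers of the active treatments of one condition
condition_modifiers <- function(condition, effects) {
  mods <- numeric(0)
  for (trt in names(effects)) {
    if (isTRUE(condition[[trt]] == 1L) || isTRUE(condition[[trt]])) {
      m <- effects[[trt]]
      for (id in names(m)) {
        mods[[id]] <- if (id %in% names(mods)) mods[[id]] * m[[id]] else m[[id]]
      }
    }
  }
  mods
}

#' Generate the factorial experimental design
#'
#' Builds the plant-level skeleton of the study: for each insertion line, a
#' full factorial over all on/off combinations of the environmental
#' treatments, crossed with genotype (WT / HET) at fixed replicate counts per
#' condition. With the default four treatments and 8 WT + 15 HET replicates,
#' each line contributes 16 x 23 = 368 plants. Flats (block labels) are
#' assigned round-robin.
#'
#' @param lines Character vector of insertion line names (default the three
#'   study lines `Cyp79f1`, `Cyp83a1`, `Sur1`).
#' @param n_wt_per_condition,n_het_per_condition Replicates per genotype per
#'   condition (defaults 8 and 15).
#' @param factors Treatment flags to cross (default `c("W","C","S","J")`; a
#'   subset gives a reduced factorial for debugging).
#' @param n_flats Number of blocks for round-robin flat assignment.
#' @return A tibble with columns `plant_id`, `line`, `genotype`, one 0/1
#'   column per treatment flag, and `flat`.
#' @examples
#' nrow(generate_design(lines = "Cyp79f1")) # 368
#' @export
generate_design <- function(lines = names(gsl_lines()),
                            n_wt_per_condition = 8,
                            n_het_per_condition = 15,
                            factors = c("W", "C", "S", "J"),
                            n_flats = 4) {
  if (length(lines) == 0) stop("`lines` must be nonempty", call. = FALSE)
  if (n_wt_per_condition < 1 || n_het_per_condition < 1) {
    stop("replicate counts must be >= 1", call. = FALSE)
  }
  if (length(factors) > 0) {
    conds <- do.call(tidyr::expand_grid,
                     stats::setNames(rep(list(c(0L, 1L)), length(factors)),
                                     factors))
  } else {
    conds <- tibble::tibble(.rows = 1)
  }
  conds$condition_id <- seq_len(nrow(conds))
  design <- tidyr::expand_grid(
    line = lines,
    condition_id = conds$condition_id,
    genotype = c("WT", "HET")
  )
  design$n <- ifelse(design$genotype == "WT",
                     n_wt_per_condition, n_het_per_condition)
  design <- tidyr::uncount(design, weights = .data$n)
  design <- dplyr::left_join(design, conds, by = "condition_id")
  design <- dplyr::select(design, "line", "genotype",
                          dplyr::all_of(factors), "condition_id")
  design$flat <- paste0("F", (seq_len(nrow(design)) - 1L) %% n_flats + 1L)
  design$plant_id <- seq_len(nrow(design))
  dplyr::relocate(design, "plant_id")
}

#' Simulate glucosinolate concentration measurements
#'
#' Completes a [generate_design()] skeleton with noisy concentrations of the
#' seven glucosinolate products. For each plant, the condition's
#' environmental modifiers and — for HET plants — the line's knockdown ratio
#' are applied to the kinetic model; the steady-state product concentrations
#' serve as lognormal medians, and each compound is drawn independently with
#' log-scale standard deviation `sigma_log`. Plants whose steady state fails
#' to converge are dropped with a warning.
#'
#' @param design Tibble from [generate_design()].
#' @param model Baseline (wild-type) `pathway_model`.
#' @param effects Environmental effects list as from
#'   [default_environment_effects()].
#' @param ratios Named numeric vector: HET/WT relative expression ratio per
#'   line (default 0.5 for each line in the design).
#' @param sigma_log Lognormal measurement noise SD on the log scale
#'   (default 0.35).
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return The design tibble with seven added compound columns (wide format,
#'   one row per plant). See [pivot_concentrations_long()] for the long form.
#' @export
simulate_concentrations <- function(design, model = build_pathway_model(),
                                    effects = default_environment_effects(),
                                    ratios = NULL, sigma_log = 0.35, seed) {
  stopifnot(is.data.frame(design), inherits(model, "pathway_model"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (!is.numeric(sigma_log) || sigma_log < 0) {
    stop("`sigma_log` must be >= 0", call. = FALSE)
  }
  lines <- unique(design$line)
  if (is.null(ratios)) {
    ratios <- stats::setNames(rep(0.5, length(lines)), lines)
  }
  missing_r <- setdiff(design$line[design$genotype == "HET"], names(ratios))
  if (length(missing_r)) {
    stop("no expression ratio given for line(s): ",
         paste(unique(missing_r), collapse = ", "), call. = FALSE)
  }
  factors <- intersect(c("W", "C", "S", "J"), names(design))
  effects <- effects[intersect(names(effects), factors)]

  # steady-state medians per distinct (genotype-line, condition) cell;
  # WT cells are shared across lines because the baseline model is identical
  key_of <- function(i) {
    cond <- as.list(design[i, factors, drop = FALSE])
    geno <- design$genotype[i]
    ln <- if (geno == "HET") design$line[i] else "WT"
    paste(ln, paste(unlist(cond), collapse = ""), sep = "|")
  }
  keys <- vapply(seq_len(nrow(design)), key_of, character(1))
  medians <- list()
  failed <- character(0)
  for (key in unique(keys)) {
    i <- which(keys == key)[1]
    mod <- model
    if (design$genotype[i] == "HET") {
      ln <- design$line[i]
      mod <- apply_knockdown(mod, gsl_lines()[[ln]], ratios[[ln]])
    }
    cond <- as.list(design[i, factors, drop = FALSE])
    mods <- condition_modifiers(cond, effects)
    if (length(mods)) mod <- scale_model(mod, mods)
    ss <- steady_state(mod)
    if (!ss$converged) {
      failed <- c(failed, key)
      medians[[key]] <- rep(NA_real_, 7)
    } else {
      medians[[key]] <- unname(ss$concentrations[compound_names()])
    }
  }
  if (length(failed)) {
    warning(length(failed), " design cell(s) dropped: steady state did not ",
            "converge", call. = FALSE)
  }
  med_mat <- do.call(rbind, medians[keys])
  noise <- withr::with_seed(seed, {
    matrix(stats::rnorm(nrow(design) * 7, sd = sigma_log), ncol = 7)
  })
  conc <- med_mat * exp(noise)
  colnames(conc) <- compound_names()
  out <- dplyr::bind_cols(design, tibble::as_tibble(conc))
  out[stats::complete.cases(conc), , drop = FALSE]
}

#' Reshape simulated plants between wide and long formats
#'
#' The wide format has one row per plant with seven compound columns; the
#' long format has one row per plant x compound with `compound` and
#' `concentration` columns.
#'
#' @param plants Wide-format tibble from [simulate_concentrations()].
#' @return A tibble in the other format.
#' @export
pivot_concentrations_long <- function(plants) {
  tidyr::pivot_longer(plants, cols = dplyr::all_of(compound_names()),
                      names_to = "compound", values_to = "concentration")
}

#' @rdname pivot_concentrations_long
#' @param plants_long Long-format tibble.
#' @export
pivot_concentrations_wide <- function(plants_long) {
  tidyr::pivot_wider(plants_long, names_from = "compound",
                     values_from = "concentration")
}

#' Simulate herbivory leaf-area outcomes
#'
#' Generates percent leaf area removed (`LR`) after 3 hr of exposure to a
#' generalist herbivore, for plants of the `Cyp79f1` line. Feeding is
#' deterred by short-chain aliphatic glucosinolates:
#' `LR = baseline * exp(-beta * (3MSOP + 4MSOB)) * exp(flat effect + noise)`.
#' With `beta > 0`, HET plants (lower short-chain aliphatics) lose
#' stochastically more leaf area than WT.
#'
#' @param records Wide-format plant records of the `Cyp79f1` line with
#'   concentration columns (e.g. from [simulate_concentrations()]).
#' @param beta Sensitivity of feeding to short-chain aliphatic concentration
#'   (per concentration unit, default 1.0, frozen after a power simulation at
#'   the default design size; 0 makes genotypes exchangeable).
#' @param baseline Percent leaf area removed at zero deterrent (default 25).
#' @param sigma Lognormal plant-to-plant noise SD (default 0.4).
#' @param flat_sd SD of the multiplicative flat (block) effect on the log
#'   scale (default 0.15).
#' @param seed Integer seed.
#' @return A tibble with columns `genotype`, `flat`, `LR` (percent, >= 0).
#' @export
simulate_herbivory <- function(records, beta = 1.0, baseline = 25,
                               sigma = 0.4, flat_sd = 0.15, seed) {
  stopifnot(is.data.frame(records))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (!is.numeric(beta) || beta < 0) stop("`beta` must be >= 0", call. = FALSE)
  if (any(records$line != "Cyp79f1")) {
    stop("herbivory is simulated for the Cyp79f1 line only", call. = FALSE)
  }
  short_chain <- records[["3MSOP"]] + records[["4MSOB"]]
  flats <- sort(unique(records$flat))
  withr::with_seed(seed, {
    flat_eff <- stats::setNames(stats::rnorm(length(flats), sd = flat_sd),
                                flats)
    noise <- stats::rnorm(nrow(records), sd = sigma)
    lr <- baseline * exp(-beta * short_chain) *
      exp(flat_eff[records$flat] + noise)
  })
  tibble::tibble(
    genotype = records$genotype,
    flat = records$flat,
    LR = pmax(unname(lr), 0)
  )
}

#' Generate synthetic expression meta-analysis fixtures
#'
#' Emulates a set of public microarray experiments measuring glucosinolate
#' pathway gene expression after MeJA treatment, each summarised as per-gene
#' treated and control medians. The default effect profile doubles every
#' pathway gene's expression except CYP81F2, which it halves — the response
#' pattern the meta-analysis statistic is meant to recover.
#'
#' @param n_experiments Number of experiments (default 3).
#' @param effect_profile Named numeric vector of true treated/control fold
#'   changes per gene; default 2 for every non-pseudo pathway enzyme and 0.5
#'   for CYP81F2.
#' @param baseline Control-arm median expression level (arbitrary units).
#' @param sigma_log Log-scale noise SD applied independently to each arm's
#'   median (default 0.15).
#' @param seed Integer seed.
#' @return A long tibble with columns `experiment`, `gene`, `arm`
#'   (`treated` / `control`), `median`.
#' @export
generate_expression_fixtures <- function(n_experiments = 3,
                                         effect_profile = NULL,
                                         baseline = 100, sigma_log = 0.15,
                                         seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (is.null(effect_profile)) {
    enz <- gsl_enzymes()
    genes <- enz$enzyme[!enz$pseudo]
    effect_profile <- stats::setNames(rep(2, length(genes)), genes)
    effect_profile[["CYP81F2"]] <- 0.5
  }
  genes <- names(effect_profile)
  grid <- tidyr::expand_grid(
    experiment = paste0("expt_", seq_len(n_experiments)),
    gene = genes
  )
  withr::with_seed(seed, {
    ctrl <- baseline * exp(stats::rnorm(nrow(grid), sd = sigma_log))
    trt <- ctrl * effect_profile[grid$gene] *
      exp(stats::rnorm(nrow(grid), sd = sigma_log))
  })
  dplyr::bind_rows(
    dplyr::mutate(grid, arm = "control", median = unname(ctrl)),
    dplyr::mutate(grid, arm = "treated", median = unname(trt))
  ) |>
    dplyr::arrange(.data$experiment, .data$gene, .data$arm)
}
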