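#' Default kinetic parameters of the glucosinolate pathway model
#'
#' Rate constants and influx rates for [build_pathway_model()]. All units are
#' arbitrary: the study this pipeline emulates reports no absolute
#' glucosinolate concentrations, so the simulator is calibrated only so that
#' wild-type steady-state product pools are of comparable magnitude and the
#' qualitative knockdown/treatment responses of the real pathway are
#' reproduced. Values are frozen; overriding them is supported through the
#' `config` argument of [build_pathway_model()].
#'
#' Keys:
#' * `influx_ali`, `influx_ind` — constant source rates for the
#'   methionine-derived (chain-elongation) and tryptophan-derived entry pools.
#' * `k_elong` — chain-elongation rate constant (L2 -> L3 -> L4 -> L5).
#' * `k_cyp79f1`, `k_cyp79f2` — entry (oxime-forming) rate constants;
#'   CYP79F1 accepts all chain lengths, CYP79F2 only the long-chain pools.
#' * `k_cyp83a1`, `k_cyp79b`, `k_cyp83b1` — downstream oxidation steps.
#' * `kcat_sur1`, `km_sur1_ali`, `km_sur1_ind` — the shared SUR1 step,
#'   modelled with competitive Michaelis-Menten kinetics so the aliphatic and
#'   indolic branches compete for one enzyme.
#' * `k_late_ali`, `k_late_ind` — lumped late steps (glucosylation +
#'   sulfation) finishing each branch.
#' * `k_cyp81f2`, `k_mod1m` — parallel modifications of I3M to 4OHI3M and
#'   1MOI3M.
#' * `d_product` — first-order non-enzymatic turnover of the seven products.
#' * `d_precursor`, `d_intermediate`, `d_committed` — first-order losses of
#'   the elongation pools, the other intermediates, and the SUR1 substrate
#'   pools respectively. Precursor turnover competing with entry gives the
#'   entry enzymes control over total branch flux; turnover of the SUR1
#'   substrate pools (`d_committed`) lets SUR1 competition redistribute flux
#'   between branches.
#'
#' @return Named numeric vector of parameters.
#' @export
default_pathway_params <- function() {
  c(
    influx_ali   = 1.00,
    influx_ind   = 0.60,
    k_elong      = 1.00,
    k_cyp79f1    = 0.60,
    k_cyp79f2    = 1.20,
    k_cyp83a1    = 2.00,
    k_cyp79b     = 1.50,
    k_cyp83b1    = 2.00,
    kcat_sur1    = 0.90,
    km_sur1_ali  = 0.10,
    km_sur1_ind  = 0.50,
    k_late_ali   = 3.00,
    k_late_ind   = 3.00,
    k_cyp81f2    = 0.80,
    k_mod1m      = 0.80,
    d_product    = 0.25,
    d_precursor  = 0.50,
    d_intermediate = 0.05,
    d_committed  = 0.40
  )
}

resolve_config <- function(config) {
  default_levels <- stats::setNames(rep(1, length(gsl_steps())), gsl_steps())
  if (is.null(config)) {
    return(list(params = default_pathway_params(), levels = default_levels))
  }
  if (is.character(config) && length(config) == 1) {
    tab <- utils::read.csv(config, stringsAsFactors = FALSE)
    config <- stats::setNames(tab$value, tab$key)
  }
  if (is.data.frame(config)) {
    config <- stats::setNames(config$value, config$key)
  }
  if (!is.numeric(config) || is.null(names(config))) {
    stop("`config` must be a named numeric vector, a key/value data frame, ",
         "or a path to a key,value CSV file", call. = FALSE)
  }
  params <- default_pathway_params()
  levels <- default_levels
  lev_keys <- grepl("^enzyme_", names(config))
  for (key in names(config)[lev_keys]) {
    id <- sub("^enzyme_", "", key)
    if (!id %in% names(levels)) {
      stop("unknown enzyme in config: ", id, call. = FALSE)
    }
    levels[[id]] <- config[[key]]
  }
  unknown <- setdiff(names(config)[!lev_keys], names(params))
  if (length(unknown)) {
    stop("unknown parameter(s) in config: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  params[names(config)[!lev_keys]] <- config[!lev_keys]
  list(params = params, levels = levels)
}

#' Build the branched glucosinolate pathway model
#'
#' Constructs the canonical kinetic model of the aliphatic + indolic
#' glucosinolate network: a chain-elongation ladder L2 -> L3 -> L4 -> L5
#' (`ELONG`) fed by a constant methionine-derived influx, with an entry step
#' at every pool (CYP79F1 on all four pools, CYP79F2 on the long-chain pools
#' L4 and L5 only), then per chain length CYP83A1, the shared SUR1 step, and
#' a lumped late step (`LATE_ALI`) yielding the products 3MSOP / 4MSOB /
#' 5MSOP / 6MSOH; and the indolic branch tryptophan-source -> CYP79B ->
#' CYP83B1 -> SUR1 -> `LATE_IND` -> I3M, with I3M modified in parallel to
#' 4OHI3M (CYP81F2) and 1MOI3M (MOD1M). All products and intermediates are
#' subject to first-order non-enzymatic turnover attributed to the `DEG`
#' pseudo-step. The two SUR1 reactions use competitive Michaelis-Menten
#' kinetics sharing one competition group; every other step is linear in its
#' substrate. Every rate is proportional to its step's catalytic level
#' (degree-1 homogeneity), which is what makes the classical
#' summation theorems hold over the full step set (see [summation_check()]).
#'
#' @param config Optional parameter overrides: a named numeric vector, a
#'   key/value data frame, or a path to a two-column `key,value` CSV.
#'   Parameter keys are documented in [default_pathway_params()]; enzyme
#'   levels are set with keys of the form `enzyme_CYP79F1`.
#' @param sur1_kinetics `"competitive_mm"` (default) or `"linear"`; the
#'   linear variant makes the whole network linear, enabling the direct
#'   steady-state solve (at the price of losing branch crosstalk).
#' @return An object of class `pathway_model`: a list with `species`,
#'   `reactions` (a tibble), `enzyme_levels`, and `params`.
#' @examples
#' model <- build_pathway_model()
#' model
#' @export
build_pathway_model <- function(config = NULL,
                                sur1_kinetics = c("competitive_mm",
                                                  "linear")) {
  sur1_kinetics <- match.arg(sur1_kinetics)
  resolved <- resolve_config(config)
  p <- resolved$params
  levels <- resolved$levels
  bad <- names(p)[!is.finite(p) | p <= 0]
  if (length(bad)) {
    stop("nonpositive or non-finite parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- names(levels)[!is.finite(levels) | levels < 0]
  if (length(bad)) {
    stop("negative or non-finite enzyme level(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  chains <- c(2L, 3L, 4L, 5L)
  ali_products <- c("3MSOP", "4MSOB", "5MSOP", "6MSOH")
  species <- c(
    paste0("L", chains),
    paste0("ald", chains), paste0("aci", chains), paste0("thio", chains),
    "IND", "iald", "iaci", "ithio",
    compound_names()
  )

  rx <- list()
  add <- function(id, substrate, product, enzyme, kinetics, k, Km = NA_real_,
                  group = NA_character_) {
    rx[[length(rx) + 1L]] <<- tibble::tibble(
      id = id, substrate = substrate, product = product, enzyme = enzyme,
      kinetics = kinetics, k = k, Km = Km, group = group
    )
  }

  add("influx_ali", NA_character_, "L2", "INFLUX_ALI", "influx", p[["influx_ali"]])
  add("influx_ind", NA_character_, "IND", "INFLUX_IND", "influx", p[["influx_ind"]])
  for (i in 1:3) {
    add(paste0("elong_", chains[i]), paste0("L", chains[i]),
        paste0("L", chains[i + 1]), "ELONG", "linear", p[["k_elong"]])
  }
  for (i in seq_along(chains)) {
    n <- chains[i]
    add(paste0("entry_f1_", n), paste0("L", n), paste0("ald", n),
        "CYP79F1", "linear", p[["k_cyp79f1"]])
    if (n >= 4) {
      add(paste0("entry_f2_", n), paste0("L", n), paste0("ald", n),
          "CYP79F2", "linear", p[["k_cyp79f2"]])
    }
    add(paste0("ox83a_", n), paste0("ald", n), paste0("aci", n),
        "CYP83A1", "linear", p[["k_cyp83a1"]])
    if (sur1_kinetics == "competitive_mm") {
      add(paste0("sur1_ali_", n), paste0("aci", n), paste0("thio", n),
          "SUR1", "competitive_mm", p[["kcat_sur1"]], p[["km_sur1_ali"]],
          "SUR1")
    } else {
      add(paste0("sur1_ali_", n), paste0("aci", n), paste0("thio", n),
          "SUR1", "linear", p[["kcat_sur1"]] / p[["km_sur1_ali"]])
    }
    add(paste0("late_ali_", n), paste0("thio", n), ali_products[i],
        "LATE_ALI", "linear", p[["k_late_ali"]])
  }
  add("cyp79b", "IND", "iald", "CYP79B", "linear", p[["k_cyp79b"]])
  add("cyp83b1", "iald", "iaci", "CYP83B1", "linear", p[["k_cyp83b1"]])
  if (sur1_kinetics == "competitive_mm") {
    add("sur1_ind", "iaci", "ithio", "SUR1", "competitive_mm",
        p[["kcat_sur1"]], p[["km_sur1_ind"]], "SUR1")
  } else {
    add("sur1_ind", "iaci", "ithio", "SUR1", "linear",
        p[["kcat_sur1"]] / p[["km_sur1_ind"]])
  }
  add("late_ind", "ithio", "I3M", "LATE_IND", "linear", p[["k_late_ind"]])
  add("cyp81f2", "I3M", "4OHI3M", "CYP81F2", "linear", p[["k_cyp81f2"]])
  add("mod1m", "I3M", "1MOI3M", "MOD1M", "linear", p[["k_mod1m"]])
  for (cmp in compound_names()) {
    add(paste0("deg_", cmp), cmp, NA_character_, "DEG", "linear",
        p[["d_product"]])
  }
  # non-enzymatic turnover of precursor pools, also attributed to DEG;
  # turnover of the SUR1 substrate pools (aci*, iaci) is what allows the
  # shared saturable step to shift flux between branches
  for (n in chains) {
    add(paste0("deg_L", n), paste0("L", n), NA_character_, "DEG", "linear",
        p[["d_precursor"]])
    add(paste0("deg_ald", n), paste0("ald", n), NA_character_, "DEG", "linear",
        p[["d_intermediate"]])
    add(paste0("deg_aci", n), paste0("aci", n), NA_character_, "DEG", "linear",
        p[["d_committed"]])
    add(paste0("deg_thio", n), paste0("thio", n), NA_character_, "DEG", "linear",
        p[["d_intermediate"]])
  }
  add("deg_IND", "IND", NA_character_, "DEG", "linear", p[["d_intermediate"]])
  add("deg_iald", "iald", NA_character_, "DEG", "linear", p[["d_intermediate"]])
  add("deg_iaci", "iaci", NA_character_, "DEG", "linear", p[["d_committed"]])
  add("deg_ithio", "ithio", NA_character_, "DEG", "linear", p[["d_intermediate"]])

  structure(
    list(
      species = species,
      reactions = dplyr::bind_rows(rx),
      enzyme_levels = levels,
      params = p
    ),
    class = "pathway_model"
  )
}

#' @export
print.pathway_model <- function(x, ...) {
  cat("<pathway_model>\n")
  cat("  species:  ", length(x$species), "\n")
  cat("  reactions:", nrow(x$reactions), "\n")
  nondefault <- x$enzyme_levels[x$enzyme_levels != 1]
  if (length(nondefault)) {
    cat("  non-unit levels:",
        paste(names(nondefault), signif(nondefault, 4), sep = "=",
              collapse = ", "), "\n")
  } else {
    cat("  all catalytic levels at wild-type default 1.0\n")
  }
  invisible(x)
}

#' Set an enzyme's catalytic level
#'
#' `apply_knockdown()` scales one manipulable enzyme's level by a relative
#' expression ratio `r` (HET/WT), the in-silico analogue of a heterozygous
#' T-DNA insertion line. `set_enzyme_level()` assigns an absolute level for
#' any step, which the MCA oracle uses for perturbations.
#'
#' @param model A `pathway_model`.
#' @param enzyme Enzyme id; for `apply_knockdown()` one of the three
#'   manipulable enzymes (CYP79F1, CYP83A1, SUR1).
#' @param r Relative expression ratio in (0, 1].
#' @return A modified copy of the model.
#' @examples
#' het <- apply_knockdown(build_pathway_model(), "CYP79F1", 0.5)
#' het$enzyme_levels[["CYP79F1"]]
#' @export
apply_knockdown <- function(model, enzyme, r) {
  stopifnot(inherits(model, "pathway_model"))
  if (!enzyme %in% manipulable_enzymes()) {
    stop("`enzyme` must be one of the manipulable enzymes: ",
         paste(manipulable_enzymes(), collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(r) || length(r) != 1 || !is.finite(r) || r <= 0 || r > 1) {
    stop("`r` must be a single value in (0, 1]", call. = FALSE)
  }
  model$enzyme_levels[[enzyme]] <- model$enzyme_levels[[enzyme]] * r
  model
}

#' @rdname apply_knockdown
#' @param level New nonnegative catalytic level.
#' @export
set_enzyme_level <- function(model, enzyme, level) {
  stopifnot(inherits(model, "pathway_model"))
  if (!enzyme %in% names(model$enzyme_levels)) {
    stop("unknown step id: ", enzyme, call. = FALSE)
  }
  if (!is.numeric(level) || length(level) != 1 || !is.finite(level) ||
      level < 0) {
    stop("`level` must be a single nonnegative value", call. = FALSE)
  }
  model$enzyme_levels[[enzyme]] <- level
  model
}

#' Apply multiplicative modifiers to model parameters
#'
#' Scales catalytic levels and/or influx steps by the factors in `modifiers`,
#' the mechanism by which environmental treatments act on the simulator.
#'
#' @param model A `pathway_model`.
#' @param modifiers Named numeric vector of positive factors; names are step
#'   ids (`CYP79F1`, ..., `INFLUX_ALI`, `INFLUX_IND`).
#' @return A modified copy of the model.
#' @export
scale_model <- function(model, modifiers) {
  stopifnot(inherits(model, "pathway_model"))
  if (length(modifiers) == 0) return(model)
  if (is.null(names(modifiers)) || !is.numeric(modifiers)) {
    stop("`modifiers` must be a named numeric vector", call. = FALSE)
  }
  if (any(!is.finite(modifiers) | modifiers <= 0)) {
    stop("modifier factors must be positive and finite", call. = FALSE)
  }
  unknown <- setdiff(names(modifiers), names(model$enzyme_levels))
  if (length(unknown)) {
    stop("unknown step id(s) in modifiers: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  model$enzyme_levels[names(modifiers)] <-
    model$enzyme_levels[names(modifiers)] * modifiers
  model
}
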