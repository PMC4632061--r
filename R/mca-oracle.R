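target_value <- function(ss, target, is_species) {
  if (is_species) ss$concentrations[[target]] else ss$fluxes[[target]]
}

#' Ground-truth control coefficient by finite differences
#'
#' Computes the metabolic-control-analysis control coefficient
#' `C = d ln(target) / d ln(level)` of a catalytic step on a steady-state
#' concentration or flux, by central differencing on the log scale:
#' `[ln X(E e^delta) - ln X(E e^-delta)] / (2 delta)`. This is the quantity
#' the finite-change knockdown estimator ([estimate_lambda()]) approximates,
#' and serves as its oracle on noise-free simulated data.
#'
#' @param model A `pathway_model`.
#' @param enzyme Step id to perturb (any catalytic step or influx
#'   pseudo-step).
#' @param target A species name (concentration control) or reaction id (flux
#'   control). Species take precedence if a name matches both.
#' @param delta Log-perturbation half-width (default 0.01).
#' @param tol Steady-state solver tolerance.
#' @return A one-row tibble with columns `enzyme`, `target`, `target_type`,
#'   and `value`.
#' @examples
#' true_control_coefficient(build_pathway_model(), "CYP79F1", "3MSOP")
#' @export
true_control_coefficient <- function(model, enzyme, target, delta = 0.01,
                                     tol = 1e-9) {
  oracle_table(model, targets = target, steps = enzyme, delta = delta,
               tol = tol)
}

#' Control coefficients of every step on a set of targets
#'
#' Central-difference control coefficients for each requested step on each
#' requested target. The two perturbed steady states of a step are solved
#' once and reused across all its targets.
#'
#' @param model A `pathway_model`.
#' @param targets Character vector of species names and/or reaction ids
#'   (default: the seven product concentrations).
#' @param steps Step ids to perturb (default: every catalytic level of the
#'   model, influx pseudo-steps included).
#' @inheritParams true_control_coefficient
#' @return A tibble with one row per step x target.
#' @export
oracle_table <- function(model, targets = compound_names(),
                         steps = names(model$enzyme_levels), delta = 0.01,
                         tol = 1e-9) {
  stopifnot(inherits(model, "pathway_model"))
  if (!is.numeric(delta) || delta <= 0) {
    stop("`delta` must be positive", call. = FALSE)
  }
  unknown <- setdiff(steps, names(model$enzyme_levels))
  if (length(unknown)) {
    stop("unknown step id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  is_species <- targets %in% model$species
  bad <- targets[!is_species & !targets %in% model$reactions$id]
  if (length(bad)) {
    stop("unknown target(s) (neither species nor reaction id): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  purrr::map_dfr(steps, function(e) {
    level <- model$enzyme_levels[[e]]
    if (level <= 0) {
      stop("level of ", e, " must be positive to perturb", call. = FALSE)
    }
    solve_at <- function(fac) {
      ss <- steady_state(set_enzyme_level(model, e, level * fac), tol = tol)
      if (!ss$converged) {
        stop("steady state did not converge perturbing ", e, " by factor ",
             format(fac, digits = 6), call. = FALSE)
      }
      ss
    }
    up <- solve_at(exp(delta))
    dn <- solve_at(exp(-delta))
    purrr::map_dfr(seq_along(targets), function(i) {
      vu <- target_value(up, targets[i], is_species[i])
      vd <- target_value(dn, targets[i], is_species[i])
      if (vu <= 0 || vd <= 0) {
        stop("target ", targets[i], " vanished at perturbed point; ",
             "cannot take logs", call. = FALSE)
      }
      tibble::tibble(
        enzyme = e, target = targets[i],
        target_type = if (is_species[i]) "concentration" else "flux",
        value = (log(vu) - log(vd)) / (2 * delta)
      )
    })
  })
}

#' Summation-theorem check
#'
#' Sums the control coefficients of *all* steps of the network — every
#' catalytic step plus the influx pseudo-steps — on one target. Because
#' every rate in the model is degree-1 homogeneous in its step's level, the
#' classical summation theorems apply: the sum is 1 for a steady-state flux
#' target and 0 for a concentration target.
#'
#' @inheritParams true_control_coefficient
#' @return A one-row tibble with columns `target`, `target_type`, `sum`, and
#'   `expected` (1 for flux, 0 for concentration).
#' @examples
#' summation_check(build_pathway_model(), "3MSOP")
#' @export
summation_check <- function(model, target, delta = 0.01, tol = 1e-9) {
  tab <- oracle_table(model, targets = target,
                      steps = names(model$enzyme_levels), delta = delta,
                      tol = tol)
  tibble::tibble(
    target = target,
    target_type = tab$target_type[1],
    sum = sum(tab$value),
    expected = if (tab$target_type[1] == "flux") 1 else 0
  )
}
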