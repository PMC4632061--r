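# compile the reaction table into fast index/closure form
compile_model <- function(model) {
  rx <- model$reactions
  n <- length(model$species)
  sub_idx <- match(rx$substrate, model$species)
  prod_idx <- match(rx$product, model$species)
  lev <- unname(model$enzyme_levels[rx$enzyme])
  kin <- rx$kinetics
  k <- rx$k
  Km <- rx$Km
  is_mm <- kin == "competitive_mm"
  groups <- unique(rx$group[is_mm])

  rates <- function(x) {
    v <- numeric(nrow(rx))
    lin <- kin == "linear"
    v[lin] <- k[lin] * lev[lin] * x[sub_idx[lin]]
    infl <- kin == "influx"
    v[infl] <- k[infl] * lev[infl]
    if (any(is_mm)) {
      for (g in groups) {
        idx <- which(is_mm & rx$group == g)
        sat <- x[sub_idx[idx]] / Km[idx]
        denom <- 1 + sum(sat)
        v[idx] <- k[idx] * lev[idx] * sat / denom
      }
    }
    v
  }
  deriv <- function(x) {
    v <- rates(x)
    dx <- numeric(n)
    has_sub <- !is.na(sub_idx)
    has_prod <- !is.na(prod_idx)
    dx_sub <- tapply(v[has_sub], sub_idx[has_sub], sum)
    dx[as.integer(names(dx_sub))] <- dx[as.integer(names(dx_sub))] - dx_sub
    dx_prod <- tapply(v[has_prod], prod_idx[has_prod], sum)
    dx[as.integer(names(dx_prod))] <- dx[as.integer(names(dx_prod))] + dx_prod
    dx
  }
  list(n = n, rates = rates, deriv = deriv,
       all_linear = !any(is_mm))
}

# steady state of an all-linear model by direct solve of A x + b = 0
linear_steady_state <- function(model, compiled) {
  rx <- model$reactions
  n <- length(model$species)
  A <- matrix(0, n, n)
  b <- numeric(n)
  sub_idx <- match(rx$substrate, model$species)
  prod_idx <- match(rx$product, model$species)
  lev <- unname(model$enzyme_levels[rx$enzyme])
  for (i in seq_len(nrow(rx))) {
    ke <- rx$k[i] * lev[i]
    if (rx$kinetics[i] == "influx") {
      b[prod_idx[i]] <- b[prod_idx[i]] + ke
    } else {
      A[sub_idx[i], sub_idx[i]] <- A[sub_idx[i], sub_idx[i]] - ke
      if (!is.na(prod_idx[i])) {
        A[prod_idx[i], sub_idx[i]] <- A[prod_idx[i], sub_idx[i]] + ke
      }
    }
  }
  x <- as.numeric(solve(A, -b))
  x
}

#' Steady state of a pathway model
#'
#' Computes the steady-state concentrations and per-reaction fluxes of a
#' [build_pathway_model()] network. When every reaction is linear the steady
#' state is obtained by a direct linear solve; otherwise stiff ODE
#' integration (deSolve's `lsoda`) from empty pools is followed by damped
#' Newton refinement of the algebraic system, and convergence is declared
#' when the largest relative rate `max |dX/dt| / max(X, floor)` falls below
#' `tol`.
#'
#' @param model A `pathway_model`.
#' @param tol Relative rate threshold for convergence (default `1e-9`).
#' @param t_max Integration horizon; non-convergence within `t_max` is
#'   flagged on the returned object, not raised as an error.
#' @param method `"auto"` (default: direct solve when all kinetics are
#'   linear, integration otherwise), `"linear"` (force the direct solve;
#'   errors on nonlinear models), or `"ode"` (force integration, useful for
#'   cross-checking the direct solve).
#' @return An object of class `steady_state` with elements `concentrations`
#'   (named vector), `fluxes` (named per-reaction rates), `converged`,
#'   `residual`, and `method`.
#' @examples
#' ss <- steady_state(build_pathway_model())
#' ss$concentrations[gsl_compounds()$compound]
#' @export
steady_state <- function(model, tol = 1e-9, t_max = 1e5,
                         method = c("auto", "linear", "ode")) {
  stopifnot(inherits(model, "pathway_model"))
  method <- match.arg(method)
  if (!is.numeric(tol) || tol <= 0) stop("`tol` must be positive", call. = FALSE)
  cm <- compile_model(model)
  n <- cm$n
  if (method == "linear" && !cm$all_linear) {
    stop("model has nonlinear kinetics; direct linear solve not applicable",
         call. = FALSE)
  }

  rel_residual <- function(x) {
    dx <- cm$deriv(x)
    max(abs(dx)) / max(max(x), 1e-8)
  }

  if (cm$all_linear && method != "ode") {
    x <- linear_steady_state(model, cm)
    res <- rel_residual(x)
    method <- "linear_solve"
    converged <- res <= max(tol, 1e-10)
  } else {
    ode_fun <- function(t, x, parms) list(cm$deriv(x))
    x <- rep(0, n)
    t_total <- 0
    chunk <- 50
    converged <- FALSE
    # integrate in growing chunks until near steady state (loose check),
    # then polish with Newton
    while (t_total < t_max) {
      sol <- deSolve::lsoda(y = x, times = c(0, chunk), func = ode_fun,
                            rtol = 1e-8, atol = 1e-10)
      x <- pmax(as.numeric(sol[nrow(sol), -1]), 0)
      t_total <- t_total + chunk
      chunk <- min(chunk * 2, t_max - t_total + 1)
      if (rel_residual(x) < 1e-4) break
    }
    # damped Newton on f(x) = 0 with finite-difference Jacobian
    for (iter in 1:50) {
      fx <- cm$deriv(x)
      if (max(abs(fx)) / max(max(x), 1e-8) <= tol * 1e-3) break
      J <- matrix(0, n, n)
      h <- pmax(abs(x), 1e-6) * 1e-7
      for (j in seq_len(n)) {
        xj <- x
        xj[j] <- xj[j] + h[j]
        J[, j] <- (cm$deriv(xj) - fx) / h[j]
      }
      step <- tryCatch(solve(J, -fx), error = function(e) NULL)
      if (is.null(step)) break
      alpha <- 1
      repeat {
        xn <- x + alpha * step
        if (all(xn >= 0) || alpha < 1e-6) break
        alpha <- alpha / 2
      }
      x <- pmax(xn, 0)
    }
    res <- rel_residual(x)
    method <- "ode_newton"
    converged <- res <= tol
  }

  fluxes <- cm$rates(x)
  structure(
    list(
      concentrations = stats::setNames(x, model$species),
      fluxes = stats::setNames(fluxes, model$reactions$id),
      converged = converged,
      residual = res,
      method = method
    ),
    class = "steady_state"
  )
}

#' @export
print.steady_state <- function(x, ...) {
  cat("<steady_state>", x$method,
      if (x$converged) "(converged)" else "(NOT converged)",
      " residual:", format(x$residual, digits = 3), "\n")
  prods <- x$concentrations[compound_names()]
  print(round(prods, 4))
  invisible(x)
}

#' Tidy a steady state into a tibble
#'
#' @param x A `steady_state` object.
#' @param ... Unused.
#' @return A tibble with columns `species` and `value`.
#' @export
tidy.steady_state <- function(x, ...) {
  tibble::tibble(species = names(x$concentrations),
                 value = unname(x$concentrations))
}

#' Steady-state product concentrations
#'
#' Convenience accessor returning the seven glucosinolate product pools of a
#' steady state, in canonical compound order.
#'
#' @param ss A `steady_state` object (or a `pathway_model`, which is solved
#'   first).
#' @param ... Passed on to [steady_state()] when `ss` is a model.
#' @return Named numeric vector of seven concentrations.
#' @export
product_concentrations <- function(ss, ...) {
  if (inherits(ss, "pathway_model")) ss <- steady_state(ss, ...)
  stopifnot(inherits(ss, "steady_state"))
  if (!ss$converged) {
    stop("steady state did not converge (residual ",
         format(ss$residual, digits = 3), ")", call. = FALSE)
  }
  ss$concentrations[compound_names()]
}

#' Write / read a steady state as a two-column CSV
#'
#' @param ss A `steady_state` object.
#' @param path Output file path.
#' @return `write_steady_state()` returns `path` invisibly;
#'   `read_steady_state()` returns a tibble with columns `species`, `value`.
#' @export
write_steady_state <- function(ss, path) {
  readr::write_csv(tidy.steady_state(ss), path)
  invisible(path)
}

#' @rdname write_steady_state
#' @export
read_steady_state <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    species = readr::col_character(), value = readr::col_double()
  ))
}
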