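# Rao's F approximation for Wilks' Lambda (the standard conversion, exact
# for p <= 2 responses or hypothesis df <= 2)
wilks_to_f <- function(lambda, p, q, v) {
  s <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  df1 <- p * q
  df2 <- s * (v - (p - q + 1) / 2) - (p * q - 2) / 2
  lam_s <- lambda^(1 / s)
  f <- (1 - lam_s) / lam_s * df2 / df1
  tibble::tibble(
    wilks_lambda = lambda, f_stat = f, df1 = df1, df2 = df2,
    p_value = stats::pf(f, df1, df2, lower.tail = FALSE)
  )
}

#' Factorial MANOVA of genotype and environment on glucosinolate profiles
#'
#' Fits the study's full multivariate linear model to the log-transformed
#' concentrations of the seven glucosinolate compounds:
#' genotype + W + C + S + J, the four genotype-by-environment interactions,
#' and all six pairwise environment-by-environment interactions (15
#' non-intercept terms). Per-term hypothesis matrices use Type III sums of
#' squares with sum-to-zero contrasts (via `car::Manova`); each term is
#' tested with Wilks' Lambda `det(E) / det(H + E)` and Rao's F
#' approximation.
#'
#' @param data Wide-format plant records with `genotype`, the treatment flag
#'   columns, and the compound columns. Typically one line's HET plants plus
#'   WT plants (pooled or per line).
#' @param responses Response columns (default the seven compounds).
#' @param log_transform Log-transform responses first (default `TRUE`).
#' @param terms Model terms; the default is the full study model restricted
#'   to the treatment flags present in `data`.
#' @return An object of class `gsl_manova`: list with `fit` (the `mlm`),
#'   `results` (a tibble of per-term Wilks' Lambda, F, dfs, p), `n`, and
#'   `responses`. Use [tidy()] / [glance()] to extract.
#' @examples
#' \donttest{
#' plants <- simulate_concentrations(
#'   generate_design(lines = "Cyp79f1", n_wt_per_condition = 2,
#'                   n_het_per_condition = 2),
#'   seed = 1)
#' tidy(gsl_manova(plants))
#' }
#' @export
gsl_manova <- function(data, responses = compound_names(),
                       log_transform = TRUE, terms = NULL) {
  stopifnot(is.data.frame(data))
  missing_resp <- setdiff(responses, names(data))
  if (length(missing_resp)) {
    stop("missing response column(s): ", paste(missing_resp, collapse = ", "),
         call. = FALSE)
  }
  factors <- intersect(c("W", "C", "S", "J"), names(data))
  if (is.null(terms)) {
    terms <- c("genotype", factors,
               if (length(factors)) paste0("genotype:", factors),
               if (length(factors) > 1) utils::combn(factors, 2, paste,
                                                     collapse = ":"))
  }
  Y <- as.matrix(data[responses])
  if (log_transform) {
    if (any(Y <= 0)) stop("log transform requires positive concentrations",
                          call. = FALSE)
    Y <- log(Y)
  }
  df <- data
  df$genotype <- factor(df$genotype)
  for (f in factors) df[[f]] <- factor(df[[f]])
  p <- length(responses)
  n <- nrow(df)
  form <- stats::as.formula(paste("Y ~", paste(terms, collapse = " + ")))
  preds <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  contr <- stats::setNames(rep(list("contr.sum"), length(preds)), preds)
  fit <- stats::lm(form, data = df, contrasts = contr)
  if (any(is.na(stats::coef(fit)))) {
    aliased <- rownames(stats::coef(fit))[apply(is.na(stats::coef(fit)), 1,
                                                any)]
    stop("design is rank deficient; aliased coefficients: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  if (stats::df.residual(fit) < p) {
    stop("too few residual degrees of freedom (", stats::df.residual(fit),
         ") for ", p, " responses", call. = FALSE)
  }
  if (p > 1) {
    mv <- car::Manova(fit, type = 3)
    E <- mv$SSPE
    v <- mv$error.df
    results <- purrr::map_dfr(mv$terms, function(tm) {
      H <- mv$SSP[[tm]]
      q <- mv$df[[tm]]
      lambda <- det(E) / det(H + E)
      dplyr::bind_cols(tibble::tibble(term = tm),
                       wilks_to_f(lambda, p, q, v))
    })
    v_out <- v
  } else {
    # single response: Wilks' Lambda degenerates to SSE / (SSH + SSE) and
    # the test to the univariate Type III F
    a3 <- car::Anova(fit, type = 3)
    keep <- !rownames(a3) %in% c("(Intercept)", "Residuals")
    sse <- a3[["Sum Sq"]][rownames(a3) == "Residuals"]
    v_out <- a3[["Df"]][rownames(a3) == "Residuals"]
    results <- tibble::tibble(
      term = rownames(a3)[keep],
      wilks_lambda = sse / (a3[["Sum Sq"]][keep] + sse),
      f_stat = a3[["F value"]][keep],
      df1 = a3[["Df"]][keep],
      df2 = v_out,
      p_value = a3[["Pr(>F)"]][keep]
    )
  }
  results <- results[results$term != "(Intercept)", , drop = FALSE]
  structure(
    list(fit = fit, results = results, n = n, responses = responses,
         error_df = v_out),
    class = "gsl_manova"
  )
}

#' @export
print.gsl_manova <- function(x, ...) {
  cat("Factorial MANOVA (Wilks' Lambda, Type III), n =", x$n, ",",
      length(x$responses), "responses\n")
  print(x$results, n = Inf)
  invisible(x)
}

#' Tidy / glance methods for gsl_manova
#'
#' @param x A `gsl_manova` object.
#' @param ... Unused.
#' @return `tidy()` returns the per-term tibble (term, Wilks' Lambda,
#'   approximate F, df1, df2, p-value); `glance()` a one-row model summary.
#' @export
tidy.gsl_manova <- function(x, ...) x$results

#' @rdname tidy.gsl_manova
#' @export
glance.gsl_manova <- function(x, ...) {
  tibble::tibble(n = x$n, n_responses = length(x$responses),
                 error_df = x$error_df, n_terms = nrow(x$results))
}

#' Per-line MANOVA summary table
#'
#' Runs [gsl_manova()] once per insertion line — each line's HET plants
#' against the WT plants (pooled across lines by default, as in the reported
#' analysis) — and assembles the term x line p-value table with significance
#' codes (`*` p < 0.05, `**` p < 0.01, `***` p < 0.001).
#'
#' @param data Wide-format plant records for all lines.
#' @param pooling `"pooled_wt"` or `"per_line"` WT arm.
#' @return A tibble with one row per model term and, per line, `p_<line>`
#'   and `sig_<line>` columns.
#' @export
manova_by_line <- function(data, pooling = c("pooled_wt", "per_line")) {
  pooling <- match.arg(pooling)
  lines <- intersect(names(gsl_lines()), unique(data$line))
  tabs <- purrr::map(lines, function(ln) {
    wt <- if (pooling == "pooled_wt") {
      data[data$genotype == "WT", ]
    } else {
      data[data$genotype == "WT" & data$line == ln, ]
    }
    sub <- dplyr::bind_rows(data[data$genotype == "HET" & data$line == ln, ],
                            wt)
    res <- tidy.gsl_manova(gsl_manova(sub))
    out <- res[, c("term", "p_value")]
    out$sig <- sig_codes(out$p_value)
    names(out)[2:3] <- paste0(c("p_", "sig_"), ln)
    out
  })
  purrr::reduce(tabs, dplyr::left_join, by = "term")
}

sig_codes <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Pooling directives from the MANOVA interaction terms
#'
#' Implements the study's gatekeeping rule: WT and HET plants are pooled when
#' testing environmental main effects — and environments are pooled when
#' testing the genotype effect — only if none of the four
#' genotype-by-environment interaction terms is significant at `alpha`.
#'
#' @param manova A `gsl_manova` object or its [tidy()] tibble.
#' @param alpha Significance threshold (default 0.05).
#' @return A list with logical flags `pool_genotypes_for_env_effects` and
#'   `pool_environments_for_genotype_effects`, plus the inspected interaction
#'   terms.
#' @export
pooling_policy <- function(manova, alpha = 0.05) {
  res <- if (inherits(manova, "gsl_manova")) tidy.gsl_manova(manova) else manova
  gxe <- res[grepl("^genotype:", res$term), , drop = FALSE]
  if (nrow(gxe) == 0) {
    stop("no genotype-by-environment interaction terms in the MANOVA; ",
         "fit the full model first", call. = FALSE)
  }
  ok <- all(gxe$p_value >= alpha)
  list(
    pool_genotypes_for_env_effects = ok,
    pool_environments_for_genotype_effects = ok,
    interaction_terms = gxe[, c("term", "p_value")]
  )
}

#' Univariate follow-up contrasts with proportional change
#'
#' For one model term (genotype or an environmental treatment), tests each
#' glucosinolate compound with a univariate linear model on log
#' concentration and reports the proportional change
#' `(T_C - U_C) / U_C` computed on back-transformed geometric means, where
#' `T_C` is the treated (or HET) and `U_C` the untreated (or WT) mean
#' concentration. Intended to be called only when the corresponding MANOVA
#' term is significant (the caller enforces the gatekeeping; see
#' [pooling_policy()]).
#'
#' @param data Wide-format plant records.
#' @param term `"genotype"` or one of the treatment flags (`"W"`, `"C"`,
#'   `"S"`, `"J"`).
#' @param alpha Univariate significance threshold (default 0.05).
#' @return A tibble with one row per compound: `compound`, `treatment`,
#'   `T_C`, `U_C`, `prop_change`, `p_value`, `significant`.
#' @export
univariate_followups <- function(data, term, alpha = 0.05) {
  stopifnot(is.data.frame(data))
  if (!term %in% names(data)) stop("unknown term: ", term, call. = FALSE)
  grp <- data[[term]]
  treated <- if (term == "genotype") grp == "HET" else grp == 1
  if (!any(treated) || !any(!treated)) {
    stop("empty stratum for term ", term, call. = FALSE)
  }
  purrr::map_dfr(compound_names(), function(cmp) {
    y <- data[[cmp]]
    if (any(y <= 0)) stop("concentrations must be positive", call. = FALSE)
    fit <- stats::lm(log(y) ~ treated)
    p <- stats::anova(fit)[["Pr(>F)"]][1]
    t_c <- exp(mean(log(y[treated])))
    u_c <- exp(mean(log(y[!treated])))
    tibble::tibble(
      compound = cmp, treatment = term, T_C = t_c, U_C = u_c,
      prop_change = (t_c - u_c) / u_c, p_value = p,
      significant = p < alpha
    )
  })
}

#' Proportional-change matrix across genotype and all treatments
#'
#' Assembles the univariate follow-up contrasts of every term — genotype (per
#' line, HET vs pooled WT) and the four environmental treatments (genotypes
#' pooled) — into the long table behind the study's heat maps.
#'
#' @param data Wide-format plant records for all lines.
#' @param alpha Univariate significance threshold.
#' @return A long tibble with columns `contrast`, `compound`, `T_C`, `U_C`,
#'   `prop_change`, `p_value`, `significant`.
#' @export
proportional_change_table <- function(data, alpha = 0.05) {
  lines <- intersect(names(gsl_lines()), unique(data$line))
  geno <- purrr::map_dfr(lines, function(ln) {
    sub <- dplyr::bind_rows(data[data$genotype == "HET" & data$line == ln, ],
                            data[data$genotype == "WT", ])
    out <- univariate_followups(sub, "genotype", alpha)
    out$treatment <- paste0("genotype_", ln)
    out
  })
  factors <- intersect(c("W", "C", "S", "J"), names(data))
  env <- purrr::map_dfr(factors, function(f) {
    univariate_followups(data, f, alpha)
  })
  out <- dplyr::bind_rows(geno, env)
  dplyr::rename(out, contrast = "treatment")
}

#' Two-way herbivory ANOVA
#'
#' Tests whether genotype and flat (block) predict the leaf area removed by
#' the herbivore: `LR = genotype + flat + genotype:flat`, fitted by least
#' squares with Type III sums of squares and sum-to-zero contrasts. Flat is
#' fitted as a fixed blocking factor even though it is a randomisation unit;
#' the returned table carries a `note` attribute flagging this
#' interpretation.
#'
#' @param records Tibble with columns `genotype`, `flat`, `LR` (e.g. from
#'   [simulate_herbivory()]).
#' @return A tibble with one row per term: `term`, `ss`, `df`, `f_stat`,
#'   `p_value`.
#' @export
herbivory_anova <- function(records) {
  stopifnot(all(c("genotype", "flat", "LR") %in% names(records)))
  if (length(unique(records$genotype)) < 2 ||
      length(unique(records$flat)) < 2) {
    stop("need >= 2 genotypes and >= 2 flats", call. = FALSE)
  }
  cells <- table(records$genotype, records$flat)
  if (any(cells == 0)) {
    stop("empty genotype x flat cell; interaction not estimable",
         call. = FALSE)
  }
  df <- data.frame(
    genotype = factor(records$genotype),
    flat = factor(records$flat),
    LR = records$LR
  )
  fit <- stats::lm(LR ~ genotype * flat, data = df,
                   contrasts = list(genotype = "contr.sum",
                                    flat = "contr.sum"))
  if (stats::var(df$LR) == 0) {
    # degenerate constant response: all effect sums of squares are zero
    trm <- c("genotype", "flat", "genotype:flat")
    dfs <- c(nlevels(df$genotype) - 1L, nlevels(df$flat) - 1L,
             (nlevels(df$genotype) - 1L) * (nlevels(df$flat) - 1L))
    out <- tibble::tibble(term = trm, ss = 0, df = dfs,
                          f_stat = NaN, p_value = NA_real_)
    attr(out, "note") <-
      "flat fitted as a fixed blocking factor (two-way fixed-effects ANOVA)"
    return(out)
  }
  a3 <- car::Anova(fit, type = 3)
  keep <- !rownames(a3) %in% c("(Intercept)", "Residuals")
  out <- tibble::tibble(
    term = rownames(a3)[keep],
    ss = a3[["Sum Sq"]][keep],
    df = a3[["Df"]][keep],
    f_stat = a3[["F value"]][keep],
    p_value = a3[["Pr(>F)"]][keep]
  )
  attr(out, "note") <-
    "flat fitted as a fixed blocking factor (two-way fixed-effects ANOVA)"
  out
}
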