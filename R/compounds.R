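#' Glucosinolate compounds and pathway enzymes
#'
#' `gsl_compounds()` returns the seven glucosinolate end products tracked by
#' the pipeline, in canonical order: four methylsulfinyl-alkyl aliphatic
#' compounds of increasing chain length (3MSOP, 4MSOB, 5MSOP, 6MSOH) followed
#' by the three indolic compounds (I3M, 4OHI3M, 1MOI3M).
#' `gsl_enzymes()` returns the twelve catalytic steps of the kinetic model,
#' including the chain-elongation step (`ELONG`) and the non-enzymatic
#' product-turnover pseudo-step (`DEG`).
#'
#' @return A tibble with one row per compound (resp. enzyme) and a logical
#'   class column.
#' @examples
#' gsl_compounds()
#' gsl_enzymes()
#' @export
gsl_compounds <- function() {
  tibble::tibble(
    compound = c("3MSOP", "4MSOB", "5MSOP", "6MSOH", "I3M", "4OHI3M", "1MOI3M"),
    class = c(rep("aliphatic", 4), rep("indolic", 3)),
    chain_length = c(3L, 4L, 5L, 6L, NA, NA, NA)
  )
}

#' @rdname gsl_compounds
#' @export
gsl_enzymes <- function() {
  tibble::tibble(
    enzyme = c("CYP79F1", "CYP79F2", "CYP83A1", "SUR1", "LATE_ALI",
               "CYP79B", "CYP83B1", "LATE_IND", "CYP81F2", "MOD1M",
               "ELONG", "DEG"),
    manipulable = c(TRUE, FALSE, TRUE, TRUE, rep(FALSE, 8)),
    pseudo = c(rep(FALSE, 11), TRUE)
  )
}

# step ids used by summation-theorem checks: the 12 catalytic steps plus the
# two influx pseudo-steps
gsl_steps <- function() {
  c(gsl_enzymes()$enzyme, "INFLUX_ALI", "INFLUX_IND")
}

compound_names <- function() gsl_compounds()$compound

enzyme_names <- function() gsl_enzymes()$enzyme

manipulable_enzymes <- function() {
  e <- gsl_enzymes()
  e$enzyme[e$manipulable]
}

# the three T-DNA insertion lines and the enzyme each knocks down
gsl_lines <- function() {
  c(Cyp79f1 = "CYP79F1", Cyp83a1 = "CYP83A1", Sur1 = "SUR1")
}
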