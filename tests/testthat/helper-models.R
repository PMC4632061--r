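# hand-built toy networks for closed-form checks; same structure as
# build_pathway_model() output so every solver/oracle function applies

toy_model <- function(species, reactions, levels) {
  structure(
    list(species = species, reactions = reactions, enzyme_levels = levels,
         params = numeric(0)),
    class = "pathway_model"
  )
}

# influx (step E0, rate v0) -> S --E1--> P --DEG--> loss
toy_chain <- function(v0 = 1, k1 = 2, d = 0.5,
                      levels = c(E0 = 1, E1 = 1, DEG = 1)) {
  toy_model(
    species = c("S", "P"),
    reactions = tibble::tibble(
      id = c("influx", "conv", "deg"),
      substrate = c(NA, "S", "P"),
      product = c("S", "P", NA),
      enzyme = c("E0", "E1", "DEG"),
      kinetics = c("influx", "linear", "linear"),
      k = c(v0, k1, d),
      Km = NA_real_,
      group = NA_character_
    ),
    levels = levels
  )
}

# entry from a fixed source (rate prop. to E1) -> S --E2--> P --DEG--> loss
toy_two_step <- function(v0 = 1, k2 = 2, d = 0.5) {
  toy_model(
    species = c("S", "P"),
    reactions = tibble::tibble(
      id = c("entry", "conv", "deg"),
      substrate = c(NA, "S", "P"),
      product = c("S", "P", NA),
      enzyme = c("E1", "E2", "DEG"),
      kinetics = c("influx", "linear", "linear"),
      k = c(v0, k2, d),
      Km = NA_real_,
      group = NA_character_
    ),
    levels = c(E1 = 1, E2 = 1, DEG = 1)
  )
}

# noise-free simulated dataset at given design size (shared by several tests)
noise_free_plants <- function(lines = names(gsl_lines()), n_wt = 1, n_het = 1,
                              factors = character(0), ratios = NULL,
                              seed = 1) {
  design <- generate_design(lines = lines, n_wt_per_condition = max(n_wt, 1),
                            n_het_per_condition = max(n_het, 1),
                            factors = factors)
  simulate_concentrations(design, ratios = ratios, sigma_log = 0, seed = seed)
}
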