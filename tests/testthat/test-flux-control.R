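test_that("genotype summaries match hand values", {
  expect_equal(genotype_summary(c(4, 4, 4)), 4)
  expect_equal(genotype_summary(c(2, 8)), 4)
  expect_equal(genotype_summary(c(2, 8), scale = "arithmetic"), 5)
  expect_error(genotype_summary(c(1, 0)), "positive")
  expect_error(genotype_summary(numeric(0)), "nonempty")
})

test_that("lambda point estimates match hand computation", {
  expect_equal(estimate_lambda(c(3, 3), c(3, 3), r = 0.5), 0)
  expect_equal(estimate_lambda(1, 2, r = 0.5), 1)
  # geometric means sqrt(8) and sqrt(32): ratio 0.5, ln(0.5)/ln(0.25) = 0.5
  expect_equal(estimate_lambda(c(2, 4), c(4, 8), r = 0.25), 0.5)
  # fractional (deviation-index) form: ((G_WT - G_HET)/G_WT) / (1 - r)
  expect_equal(estimate_lambda(c(2, 4), c(4, 8), r = 0.25,
                               estimator = "fractional"), (0.5) / 0.75)
  expect_error(estimate_lambda(1, 2, r = 1), "zero enzyme perturbation")
  expect_error(estimate_lambda(1, 2, r = -1), "positive")
})

test_that("bootstrap CI collapses to the point estimate on constant arms", {
  ci <- bootstrap_ci(c(2, 2, 2), c(4, 4, 4), r = 0.5, seed = 1)
  expect_equal(ci$ci_low, ci$lambda)
  expect_equal(ci$ci_high, ci$lambda)
  expect_equal(ci$lambda, 1)
})

test_that("bootstrap is reproducible given the seed", {
  het <- exp(rnorm(20)); wt <- exp(rnorm(20))
  a <- bootstrap_ci(het, wt, r = 0.5, seed = 99)
  b <- bootstrap_ci(het, wt, r = 0.5, seed = 99)
  expect_identical(a, b)
  cc <- bootstrap_ci(het, wt, r = 0.5, seed = 100)
  expect_false(isTRUE(all.equal(a$ci_low, cc$ci_low)))
})

test_that("n = 2 bootstrap quantiles match the exhaustive enumeration", {
  het <- c(1.2, 3.1); wt <- c(2.5, 6.4); r <- 0.5
  g <- function(x) c(x[1], sqrt(prod(x)), sqrt(prod(x)), x[2])
  lam_atoms <- as.vector(outer(g(het), g(wt),
                               function(h, w) log(h / w) / log(r)))
  expect_length(lam_atoms, 16)
  # each atom has probability 1/16 > 0.025, so the percentile bounds of a
  # large resample converge to the extreme atoms
  ci <- bootstrap_ci(het, wt, r = r, n_boot = 4000, seed = 11)
  expect_equal(ci$ci_low, min(lam_atoms), tolerance = 1e-10)
  expect_equal(ci$ci_high, max(lam_atoms), tolerance = 1e-10)
  expect_true(ci$lambda >= min(lam_atoms) && ci$lambda <= max(lam_atoms))
})

test_that("estimates render in the reported table format", {
  expect_equal(format_estimate(1.118, 1.006, 1.247),
               "1.118 (1.006−1.247)")
  expect_equal(format_estimate(-0.0062, -0.014, 0.031),
               "-0.006 (-0.014−0.031)")
})

test_that("estimate_table reduces to single-pair estimates on noise-free data", {
  plants <- noise_free_plants(n_wt = 2, n_het = 2)
  tab <- estimate_table(plants, n_boot = 50, seed = 3)
  expect_s3_class(tab, "gsl_lambda_table")
  expect_equal(nrow(tab), 21)
  expect_false(any(tab$missing_arm))

  # all WT rows carry the identical medians, so pooling policy is irrelevant
  per_line <- estimate_table(plants, pooling = "per_line", n_boot = 50,
                             seed = 3)
  expect_equal(tab$lambda, per_line$lambda, tolerance = 1e-12)

  # each cell equals the direct two-sample estimate
  m <- build_pathway_model()
  wt <- product_concentrations(m)
  het <- product_concentrations(apply_knockdown(m, "CYP79F1", 0.5))
  cell <- tab[tab$line == "Cyp79f1" & tab$compound == "3MSOP", ]
  expect_equal(cell$lambda, log(het[["3MSOP"]] / wt[["3MSOP"]]) / log(0.5),
               tolerance = 1e-8)

  # zero noise also collapses the CIs onto the point estimates
  expect_equal(tab$ci_low, tab$lambda, tolerance = 1e-10)
})

test_that("the table ranks CYP79F1 first when it holds dominant control", {
  # parameterisation with a fast (unsaturated) SUR1 step, so that true
  # short-chain control sits in the entry enzyme; verified against the oracle
  cfg <- c(kcat_sur1 = 4, km_sur1_ali = 1, km_sur1_ind = 1)
  model <- build_pathway_model(cfg)
  design <- generate_design(n_wt_per_condition = 1, n_het_per_condition = 1,
                            factors = character(0))
  design <- dplyr::bind_rows(design, design) # 2 per arm for bootstrap
  plants <- simulate_concentrations(design, model = model, sigma_log = 0,
                                    seed = 1)
  tab <- estimate_table(plants, n_boot = 50, seed = 3)
  oracle <- oracle_table(model, targets = c("3MSOP", "4MSOB"),
                         steps = c("CYP79F1", "CYP83A1", "SUR1"))
  for (cmp in c("3MSOP", "4MSOB")) {
    orc <- oracle[oracle$target == cmp, ]
    expect_equal(orc$enzyme[which.max(abs(orc$value))], "CYP79F1")
    sub <- tab[tab$compound == cmp, ]
    expect_equal(sub$enzyme[which.max(abs(sub$lambda))], "CYP79F1")
  }
})

test_that("lambda is centred at zero when there is no knockdown effect", {
  plants <- noise_free_plants(lines = "Cyp79f1", n_wt = 2, n_het = 2,
                              ratios = c(Cyp79f1 = 1))
  lam <- estimate_lambda(plants[plants$genotype == "HET", ][["3MSOP"]],
                         plants[plants$genotype == "WT", ][["3MSOP"]],
                         r = 0.95)
  expect_equal(lam, 0, tolerance = 1e-10)
})

test_that("lambda tables reshape to compound x enzyme layout", {
  plants <- noise_free_plants(n_wt = 2, n_het = 2)
  tab <- estimate_table(plants, n_boot = 50, seed = 3)
  wide <- lambda_table_wide(tab)
  expect_equal(nrow(wide), 7)
  expect_setequal(setdiff(names(wide), "compound"),
                  c("CYP79F1", "CYP83A1", "SUR1"))
})
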