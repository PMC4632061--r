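test_that("default model has the canonical topology", {
  m <- build_pathway_model()
  expect_true(all(compound_names() %in% m$species))
  expect_length(compound_names(), 7)
  expect_setequal(names(m$enzyme_levels),
                  c(gsl_enzymes()$enzyme, "INFLUX_ALI", "INFLUX_IND"))
  expect_length(gsl_enzymes()$enzyme, 12)
  # SUR1 serves four aliphatic chain lengths plus the indolic branch
  expect_gte(sum(m$reactions$enzyme == "SUR1"), 5)
  # CYP79F1 enters at all four pools, CYP79F2 only at the long-chain pools
  expect_equal(sum(m$reactions$enzyme == "CYP79F1"), 4)
  expect_equal(m$reactions$substrate[m$reactions$enzyme == "CYP79F2"],
               c("L4", "L5"))
})

test_that("config overrides change levels/parameters but not topology", {
  m0 <- build_pathway_model()
  m1 <- build_pathway_model(c(enzyme_CYP79F1 = 0.5))
  expect_equal(m1$enzyme_levels[["CYP79F1"]], 0.5)
  expect_equal(m1$reactions, m0$reactions)
  lev <- m1$enzyme_levels
  lev[["CYP79F1"]] <- 1
  expect_equal(lev, m0$enzyme_levels)

  # round trip through the key,value CSV reader
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(key = c("k_elong", "enzyme_SUR1"),
                              value = c(0.7, 0.25)),
                   path, row.names = FALSE)
  m2 <- build_pathway_model(path)
  expect_equal(m2$params[["k_elong"]], 0.7)
  expect_equal(m2$enzyme_levels[["SUR1"]], 0.25)
})

test_that("invalid parameters are rejected by name", {
  expect_error(build_pathway_model(c(k_elong = -1)), "k_elong")
  expect_error(build_pathway_model(c(enzyme_SUR1 = -0.1)), "SUR1")
  expect_error(build_pathway_model(c(nonsense = 1)), "nonsense")
})

test_that("steady state of a single linear chain matches the closed form", {
  v0 <- 1.3; k1 <- 2.2; d <- 0.4
  ss <- steady_state(toy_chain(v0, k1, d))
  expect_true(ss$converged)
  expect_equal(ss$concentrations[["P"]], v0 / d, tolerance = 1e-9)
  expect_equal(ss$concentrations[["S"]], v0 / k1, tolerance = 1e-9)
  expect_equal(unname(ss$fluxes["conv"]), v0, tolerance = 1e-9)
})

test_that("direct linear solve agrees with ODE integration", {
  m <- build_pathway_model(sur1_kinetics = "linear")
  direct <- steady_state(m)
  expect_equal(direct$method, "linear_solve")
  ode <- steady_state(m, method = "ode")
  expect_equal(ode$method, "ode_newton")
  expect_equal(ode$concentrations, direct$concentrations, tolerance = 1e-6)
  expect_error(steady_state(build_pathway_model(), method = "linear"),
               "nonlinear")
})

test_that("flux balance holds: total influx equals total loss", {
  for (m in list(build_pathway_model(),
                 apply_knockdown(build_pathway_model(), "SUR1", 0.5))) {
    ss <- steady_state(m)
    expect_true(ss$converged)
    expect_lte(ss$residual, 1e-9)
    influx <- sum(ss$fluxes[c("influx_ali", "influx_ind")])
    loss <- sum(ss$fluxes[grepl("^deg_", names(ss$fluxes))])
    expect_equal(loss, influx, tolerance = 1e-8)
    expect_true(all(ss$concentrations > 0))
  }
})

test_that("linear kinetics are degree-1 homogeneous in catalytic levels", {
  m <- build_pathway_model(sur1_kinetics = "linear")
  ss1 <- steady_state(m)
  m2 <- m
  m2$enzyme_levels[] <- m2$enzyme_levels * 2
  ss2 <- steady_state(m2)
  expect_equal(ss2$fluxes, ss1$fluxes * 2, tolerance = 1e-9)
  expect_equal(ss2$fluxes / sum(ss2$fluxes), ss1$fluxes / sum(ss1$fluxes),
               tolerance = 1e-9)
})

test_that("knockdown semantics: identity at r = 1, scaling below", {
  m <- build_pathway_model()
  expect_equal(apply_knockdown(m, "CYP79F1", 1), m)
  expect_equal(apply_knockdown(m, "CYP79F1", 0.5)$enzyme_levels[["CYP79F1"]],
               0.5)
  expect_error(apply_knockdown(m, "CYP79F1", 0), "0, 1")
  expect_error(apply_knockdown(m, "ELONG", 0.5), "manipulable")
})

test_that("SUR1 knockdown shifts products of both branches", {
  wt <- product_concentrations(build_pathway_model())
  het <- product_concentrations(
    apply_knockdown(build_pathway_model(), "SUR1", 0.5))
  ali <- compound_names()[1:4]
  ind <- compound_names()[5:7]
  expect_true(all(abs(het[ali] / wt[ali] - 1) > 0.01))
  expect_true(all(abs(het[ind] / wt[ind] - 1) > 0.01))
})

test_that("CYP79F1 knockdown reproduces the elongation-overflow signature", {
  wt <- product_concentrations(build_pathway_model())
  het <- product_concentrations(
    apply_knockdown(build_pathway_model(), "CYP79F1", 0.5))
  expect_lt(het[["3MSOP"]], wt[["3MSOP"]])
  expect_lt(het[["4MSOB"]], wt[["4MSOB"]])
  expect_gt(het[["6MSOH"]], wt[["6MSOH"]])
  expect_gt(het[["I3M"]], wt[["I3M"]])
})

test_that("steady state writes and reads back as two-column CSV", {
  ss <- steady_state(toy_chain())
  path <- withr::local_tempfile(fileext = ".csv")
  write_steady_state(ss, path)
  back <- read_steady_state(path)
  expect_equal(back$species, names(ss$concentrations))
  expect_equal(back$value, unname(ss$concentrations))
})
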