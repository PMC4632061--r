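test_that("Wilks' Lambda matches the hand-computed two-group toy", {
  toy <- tibble::tibble(
    genotype = rep(c("A", "B"), each = 3),
    y1 = c(1, 0, 1, 3, 2, 3),
    y2 = c(0, 1, 1, 2, 3, 3)
  )
  fit <- gsl_manova(toy, responses = c("y1", "y2"), log_transform = FALSE)
  res <- tidy(fit)
  expect_equal(res$term, "genotype")
  # H = [[6,6],[6,6]], E = [[4/3,-2/3],[-2/3,4/3]]:
  # Lambda = det(E)/det(H+E) = (4/3)/(76/3) = 1/19
  expect_equal(res$wilks_lambda, 1 / 19, tolerance = 1e-12)
  expect_lt(res$p_value, 0.05)
})

test_that("fitted Lambda equals det(E)/det(H+E) computed from scratch", {
  set.seed(21)
  for (rep in 1:5) {
    g <- factor(rep(1:3, each = 6))
    Y <- matrix(rnorm(18 * 3), 18, 3)
    df <- tibble::tibble(genotype = g, a = Y[, 1], b = Y[, 2], cc = Y[, 3])
    fit <- gsl_manova(df, responses = c("a", "b", "cc"),
                      log_transform = FALSE)
    # independent determinant oracle from group means
    centered_within <- Y - apply(Y, 2, function(col) ave(col, g))
    E <- crossprod(centered_within)
    grand <- colMeans(Y)
    H <- Reduce(`+`, lapply(levels(g), function(lv) {
      d <- colMeans(Y[g == lv, , drop = FALSE]) - grand
      sum(g == lv) * tcrossprod(d)
    }))
    expect_equal(tidy(fit)$wilks_lambda, det(E) / det(H + E),
                 tolerance = 1e-10)
  }
})

test_that("single-response MANOVA reduces to the univariate ANOVA F", {
  set.seed(4)
  df <- tibble::tibble(
    genotype = rep(c("WT", "HET"), each = 10),
    y = exp(rnorm(20, mean = rep(c(0, 0.5), each = 10)))
  )
  fit <- gsl_manova(df, responses = "y")
  uni <- anova(lm(log(y) ~ genotype, data = df))
  expect_equal(tidy(fit)$f_stat, uni[["F value"]][1], tolerance = 1e-10)
  expect_equal(tidy(fit)$p_value, uni[["Pr(>F)"]][1], tolerance = 1e-10)
})

test_that("Lambda is invariant under nonsingular response transforms", {
  set.seed(8)
  df <- tidyr::expand_grid(genotype = c("WT", "HET"), W = 0:1, J = 0:1,
                           rep = 1:4)
  Y <- matrix(rnorm(nrow(df) * 3), ncol = 3)
  d1 <- dplyr::bind_cols(df, tibble::as_tibble(stats::setNames(
    as.data.frame(Y), c("r1", "r2", "r3"))))
  A <- matrix(c(2, 0.5, -1, 0.3, 1.5, 0.2, 0, -0.7, 1.1), 3, 3)
  YT <- Y %*% A
  d2 <- dplyr::bind_cols(df, tibble::as_tibble(stats::setNames(
    as.data.frame(YT), c("r1", "r2", "r3"))))
  f1 <- gsl_manova(d1, responses = c("r1", "r2", "r3"),
                   log_transform = FALSE)
  f2 <- gsl_manova(d2, responses = c("r1", "r2", "r3"),
                   log_transform = FALSE)
  expect_equal(tidy(f1)$wilks_lambda, tidy(f2)$wilks_lambda,
               tolerance = 1e-10)
})

test_that("null p-values of the genotype term are uniform", {
  set.seed(31)
  ps <- replicate(200, {
    df <- tidyr::expand_grid(genotype = c("WT", "HET"), W = 0:1, rep = 1:8)
    df$r1 <- rnorm(nrow(df))
    df$r2 <- rnorm(nrow(df))
    fit <- gsl_manova(df, responses = c("r1", "r2"), log_transform = FALSE)
    res <- tidy(fit)
    res$p_value[res$term == "genotype"]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the full factorial model exposes all 15 terms", {
  plants <- noise_free_plants(lines = "Cyp79f1", n_wt = 1, n_het = 1,
                              factors = c("W", "C", "S", "J"))
  # add noise so the error matrix is full rank
  set.seed(2)
  for (cmp in compound_names()) {
    plants[[cmp]] <- plants[[cmp]] * exp(rnorm(nrow(plants), sd = 0.3))
  }
  fit <- gsl_manova(plants)
  expect_equal(nrow(tidy(fit)), 15)
  expect_setequal(
    tidy(fit)$term,
    c("genotype", "W", "C", "S", "J",
      paste0("genotype:", c("W", "C", "S", "J")),
      utils::combn(c("W", "C", "S", "J"), 2, paste, collapse = ":"))
  )
  g <- glance(fit)
  expect_equal(g$n, nrow(plants))
  expect_equal(g$n_responses, 7)
})

test_that("pooling policy follows the interaction gatekeeping rule", {
  mk <- function(p) tibble::tibble(
    term = c("genotype", paste0("genotype:", c("W", "C", "S", "J")), "W:C"),
    p_value = c(0.001, p, 0.2)
  )
  all_ns <- pooling_policy(mk(c(0.9, 0.3, 0.8, 0.83)))
  expect_true(all_ns$pool_genotypes_for_env_effects)
  expect_true(all_ns$pool_environments_for_genotype_effects)

  one_sig <- pooling_policy(mk(c(0.9, 0.01, 0.8, 0.83)))
  expect_false(one_sig$pool_genotypes_for_env_effects)

  expect_error(pooling_policy(tibble::tibble(term = "genotype",
                                             p_value = 0.001)),
               "interaction")
})

test_that("proportional changes follow the (T - U)/U definition", {
  base <- tibble::tibble(
    genotype = "WT", line = "Cyp79f1",
    J = rep(0:1, each = 4)
  )
  k <- 3
  for (cmp in compound_names()) {
    base[[cmp]] <- c(2 * k, 2 / k, 2 * k, 2 / k,   # untreated geo mean 2
                     1.5 * k, 1.5 / k, 1.5 * k, 1.5 / k) # treated geo mean 1.5
  }
  out <- univariate_followups(base, "J")
  expect_equal(out$T_C, rep(1.5, 7))
  expect_equal(out$U_C, rep(2, 7))
  expect_equal(out$prop_change, rep(-0.25, 7))

  # doubling: prop change exactly 1
  for (cmp in compound_names()) {
    base[[cmp]] <- c(1 * k, 1 / k, 1 * k, 1 / k,
                     2 * k, 2 / k, 2 * k, 2 / k)
  }
  out2 <- univariate_followups(base, "J")
  expect_equal(out2$prop_change, rep(1, 7))

  # identical arms: zero change, F = 0, p = 1
  for (cmp in compound_names()) {
    base[[cmp]] <- rep(c(1, 2, 4, 8), 2)
  }
  out3 <- univariate_followups(base, "J")
  expect_equal(out3$prop_change, rep(0, 7))
  expect_equal(out3$p_value, rep(1, 7))
  expect_false(any(out3$significant))
})

test_that("herbivory ANOVA recovers the fixed-effects decomposition", {
  # constant response: zero SS beyond the intercept
  const <- tidyr::expand_grid(genotype = c("WT", "HET"),
                              flat = c("F1", "F2"), rep = 1:3)
  const$LR <- 5
  a0 <- herbivory_anova(const)
  expect_equal(a0$ss, rep(0, 3), tolerance = 1e-20)
  expect_setequal(a0$term, c("genotype", "flat", "genotype:flat"))

  expect_error(herbivory_anova(dplyr::filter(const, genotype == "WT")),
               ">= 2 genotypes")
  expect_error(herbivory_anova(dplyr::filter(
    const, !(genotype == "WT" & flat == "F1"))), "empty")
})

test_that("flat p-values are uniform when flats have no effect", {
  set.seed(12)
  ps <- replicate(150, {
    df <- tidyr::expand_grid(genotype = c("WT", "HET"),
                             flat = c("F1", "F2", "F3"), rep = 1:5)
    df$LR <- exp(rnorm(nrow(df)))
    a <- herbivory_anova(df)
    a$p_value[a$term == "flat"]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("simulated herbivory yields a detectable genotype effect", {
  d <- generate_design(lines = "Cyp79f1", n_wt_per_condition = 40,
                       n_het_per_condition = 40, factors = character(0))
  hits <- sapply(1:25, function(s) {
    plants <- simulate_concentrations(d, seed = 500 + s)
    h <- simulate_herbivory(plants, seed = 900 + s)
    a <- herbivory_anova(h)
    mean_diff <- mean(h$LR[h$genotype == "HET"]) -
      mean(h$LR[h$genotype == "WT"])
    c(sig = a$p_value[a$term == "genotype"] < 0.05, up = mean_diff > 0)
  })
  expect_gte(mean(hits["sig", ]), 0.8)
  expect_gte(mean(hits["up", ]), 0.8)
})
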