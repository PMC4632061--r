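---
title: "Models and methods behind gslflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gslflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

gslflux implements, end to end, the estimation of per-enzyme flux control
coefficients for the branched glucosinolate pathway of *Arabidopsis
thaliana* from heterozygous-knockdown (HET) metabolite data, together with
the factorial-environment statistical battery around it and a kinetic
simulator that doubles as synthetic-data generator and as ground-truth
oracle. This vignette is the package's own account of the models, the
defaults, and the numerical conventions — everything a user needs to know to
trust (or challenge) a result.

## 1. The kinetic pathway model

`build_pathway_model()` constructs a deterministic reaction network for the
aliphatic and indolic glucosinolate branches:

* A methionine-derived influx feeds the chain-elongation ladder
  L2 → L3 → L4 → L5 (step `ELONG`). At every pool, *entry* into the core
  pathway (CYP79F1 on all pools; CYP79F2 on the long-chain pools L4 and L5
  only) competes with further elongation and with first-order precursor
  turnover. Each entered chain length passes CYP83A1, the shared SUR1 step,
  and a lumped late step (`LATE_ALI`, standing in for glucosylation and
  sulfation) to yield 3MSOP, 4MSOB, 5MSOP or 6MSOH.
* A tryptophan-derived influx feeds CYP79B → CYP83B1 → SUR1 → `LATE_IND` →
  I3M, which is further modified in parallel to 4OHI3M (CYP81F2) and 1MOI3M
  (`MOD1M`).
* Every product — and, with smaller constants, every intermediate pool — is
  subject to first-order non-enzymatic turnover attributed to the `DEG`
  pseudo-step. Product concentration at steady state is therefore
  proportional to the flux reaching it, which is what makes concentration a
  usable flux readout.

All reactions are linear in their substrate and proportional to their step's
catalytic level, **except** the two SUR1 reactions, which share one
competitive Michaelis–Menten group:
\(v_i = k_\mathrm{cat} E \, (S_i/K_i) / (1 + \sum_j S_j/K_j)\).
This is deliberately the *simplest* mechanism that produces branch
crosstalk: with SUR1 operating near saturation, an aliphatic knockdown
relieves competition and raises indolic output. Degree-1 homogeneity of
every rate in its catalytic level is preserved throughout, so the classical
MCA summation theorems hold exactly over the complete step set (twelve
catalytic steps plus the two influx pseudo-steps), and
`summation_check()` verifies them numerically (flux sums to 1,
concentration sums to 0, both within 10⁻³ at the default solver tolerance).

Two structural choices matter for where control sits:

* **Precursor turnover vs. entry** (`d_precursor`): if the elongation pools
  had no sink other than entry, total branch flux would equal influx no
  matter the enzyme levels, and entry enzymes could only *redistribute*
  flux across chain lengths. Turnover competing with entry is what gives
  CYP79F1 genuine control of total aliphatic output.
* **Turnover of the SUR1 substrate pools** (`d_committed`): a leak at the
  shared step is what allows SUR1 competition to shift flux *between*
  branches rather than only delaying it.

### Units and calibration

No absolute glucosinolate concentrations are available to calibrate
against, so all concentrations, rates and enzyme levels are in arbitrary
units (wild-type catalytic levels are 1.0). The default rate constants in
`default_pathway_params()` (mirrored in
`inst/extdata/pathway_params.csv`) were calibrated once and frozen, with
two goals only: wild-type steady-state product pools of comparable
magnitude across the seven compounds, and the qualitative response
signatures of the real pathway —

* a CYP79F1 knockdown to half expression *lowers* 3MSOP and 4MSOB,
  *raises* 6MSOH (elongation overflow past L3 into CYP79F2's long-chain
  entry), and *raises* I3M (relief of the shared, saturable SUR1 step);
* the methyl jasmonate modifier (all enzymes up, CYP81F2 down) *lowers*
  4OHI3M while *raising* I3M and 1MOI3M.

The kcat of SUR1 (0.9) is intentionally close to the total steady-state
demand of the two branches, i.e. the step runs near saturation. A
consequence worth knowing: in this parameterisation SUR1 carries
substantial control of its own. The magnitudes of no coefficient are
calibrated to any published value — only the signs above are asserted, of
the simulator, by the test suite.

### Steady-state solver

`steady_state()` uses a direct linear solve when every reaction is linear
(`build_pathway_model(sur1_kinetics = "linear")` builds that variant), and
otherwise integrates the stiff ODE system from empty pools with
`deSolve::lsoda` in growing time chunks until the relative rate norm
`max |dX/dt| / max(X, floor)` falls below 10⁻⁴, then polishes the algebraic
root with damped Newton iterations (finite-difference Jacobian,
nonnegativity-preserving step halving) down to a relative residual of
10⁻⁹ or better. When both routes apply the direct solve wins; the test
suite checks that the two agree to 10⁻⁶ relative. Non-convergence is
flagged on the returned object, not thrown, so callers (e.g. the simulator)
can decide what to drop.

## 2. The MCA oracle and the estimator

`true_control_coefficient()` computes
\(C = \partial \ln X / \partial \ln E\) by central differences on the log
scale with half-width `delta = 0.01` — second-order accurate, stable to
halving of delta within 10⁻⁴ — and `oracle_table()` reuses the two
perturbed steady states of a step across all its targets.

`estimate_lambda()` implements the finite-change estimator used on real
knockdown data. The exact published formula behind such estimates is cited
rather than restated in the source study, so the package makes its own
choice explicit and offers both standard forms: the default **log-ratio**
form \(\lambda = \ln(G_{HET}/G_{WT})/\ln r\) (exact under a local power-law
response, symmetric in the arm labels) and the **fractional**
deviation-index form \(((G_{WT}-G_{HET})/G_{WT})/(1-r)\). Genotype
summaries are geometric means, consistent with the log transform used
throughout the inferential battery.

One subtlety: the log-ratio estimator over the interval \([rE, E]\) is
algebraically a central difference *centred at* \(\sqrt r\,E\), not at the
wild-type point. At `r = 0.95` the estimator agrees with the oracle
evaluated at the midpoint to about 10⁻⁴ relative, while against the
wild-type-point oracle the curvature of the near-saturated SUR1 step leaves
a ~3% discrepancy. The acceptance test therefore compares at the midpoint —
that is the quantity a finite change estimates. At the study's actual
`r = 0.5` the estimator is a coarse finite-change approximation; agreement
with the infinitesimal coefficient is documented, not asserted tightly.

### Bootstrap confidence intervals

`bootstrap_ci()` resamples plants with replacement independently within
each genotype arm (1000 resamples by default), recomputes λ on each
resample with `r` held fixed — the interval expresses sampling variability
of the concentration contrast, not of the expression ratio — and takes the
percentile interval from empirical quantiles with linear interpolation
(R's `quantile` type 7). Percentile rather than BCa is the simplest
defensible convention for a plain "bootstrapped 1000 times" description;
it is recorded here so results are reproducible to the convention. The
resampling unit is the plant, unstratified, because the analysis pools
environments before estimation; a condition-stratified mode exists behind
`stratify_by_condition`. With two plants per arm the 16 equiprobable
resample pairs can be enumerated exhaustively, and the test suite checks
the returned bounds against that enumeration.

`coverage_simulation()` is the calibration experiment: 500 replicate
datasets drawn lognormally (σ = 0.35 on the log scale) around the kinetic
model's HET/WT 3MSOP medians at the study's pooled per-line sample sizes
(240 HET, 128 WT), `r = 0.5`. The 95% percentile interval covers the
finite-change target λ at a rate statistically compatible with 0.95
(binomial Monte Carlo error ≈ 1 percentage point at 500 replicates). The
problem sizes here — 500 replicates, 1000 resamples — are the package's
frozen choices for a desk-scale experiment with Monte Carlo error small
enough to detect meaningful miscalibration.

## 3. The synthetic experiment generator

`generate_design()` reproduces the study design exactly: per insertion
line (`Cyp79f1`, `Cyp83a1`, `Sur1`), a full factorial over the four binary
treatments — reduced water (W), leaf crushing (C), reduced soil nutrients
(S), methyl jasmonate (J) — giving 16 conditions, with 8 WT and 15 HET
replicates per condition: 368 plants per line. The reported "approximately
eight" wild types is fixed at exactly 8, because 16 × (8 + 15) reproduces
the printed total of 368 exactly; whether the real counts varied by
condition is unrecoverable. Flats are assigned round-robin as pure block
labels.

`simulate_concentrations()` maps each genotype × condition cell to a
steady state of the kinetic model — applying the line's knockdown ratio
(default `r = 0.5` per line, the single-null-allele expectation; the
actually measured ratios are required inputs wherever real data are
analysed) and the condition's environmental modifiers — and draws each
compound independently lognormal around the cell median with
`sigma_log = 0.35` (a typical metabolite coefficient of variation of about
35%). Treatment modifiers (`default_environment_effects()`) are frozen
multiplicative factors on enzyme levels and influxes; only their direction
pattern carries meaning, most importantly J raising every pathway enzyme
*except* CYP81F2, which it halves. W and C raise influx (stress
induction), S lowers it (nutrient limitation); these magnitudes are
simulator conventions, nothing more.

What the generator deliberately does **not** emulate: cross-compound
measurement covariance (compounds are drawn independently; a real rosette
measured once would correlate errors — a covariance hook exists but is off
because no covariance information is available), condition-varying
replicate counts, germination mortality, leaf-age effects, or measurement
error in the expression ratios. Tests passing on this generator therefore
validate the *statistical machinery* under a clean lognormal world, not
the field behaviour of the assays.

Because the kinetic model is nonlinear on the log scale, environmental
modifiers interact mechanistically with genotype: simulated datasets can
show genotype-by-environment MANOVA interactions even though each acts
multiplicatively on rates. The pooling logic (`pooling_policy()`) treats
that as data, enabling pooling only when no G×E term is significant.

`simulate_herbivory()` models percent leaf area removed after 3 hr as
`LR = baseline · exp(−beta · (3MSOP + 4MSOB)) · exp(flat + noise)`,
deterrence by short-chain aliphatic glucosinolates with a multiplicative
flat effect. Defaults (baseline 25%, σ = 0.4, flat SD 0.15, 40 + 40 plants
of the `Cyp79f1` line) were frozen after a power simulation: at
`beta = 1.0` the genotype term of the two-way ANOVA is significant at
α = 0.01 in ~88% of 200 replicates, so the simulated experiment reliably
detects the HET > WT feeding difference without being a foregone
conclusion.

`generate_expression_fixtures()` emulates three public microarray
experiments as per-gene treated/control medians around a fold-change
profile (default: all pathway genes doubled, CYP81F2 halved, log-noise
SD 0.15).

## 4. The statistical battery

`gsl_manova()` fits the study's full multivariate linear model to the
log-transformed seven-compound response: genotype, the four treatment main
effects, the four genotype×treatment interactions and the six pairwise
treatment×treatment interactions (15 terms). Sums of squares are Type III
with sum-to-zero contrasts (via `car::Manova`) — the convention that
approximates JMP's default, which the original analyses used; the exact
convention in those runs cannot be confirmed, so p-values of that analysis
are matched in kind, not digit for digit. Each term is tested with Wilks'
Λ = det(E)/det(H+E) and Rao's F approximation (exact for ≤ 2 responses or
≤ 2 hypothesis df). The test suite pins Λ to a hand-computed toy
(Λ = 1/19), to an independent determinant oracle on random instances
(10⁻¹⁰), checks invariance under nonsingular response transforms, the
reduction to the univariate F for a single response, and uniformity of
null p-values over seeded simulations.

`univariate_followups()` runs the per-compound log-scale tests at
α = 0.05 with no multiple-testing correction — matching the original
convention, and recorded here precisely because it is a convention.
Proportional changes `(T_C − U_C)/U_C` are computed on back-transformed
geometric means. `herbivory_anova()` fits
`LR = genotype + flat + genotype:flat` as a fixed-effects two-way ANOVA
(Type III, sum-to-zero); flat is a randomisation unit fitted as a fixed
blocking factor — the output carries a note flagging that interpretation,
and no REML/mixed-model treatment is attempted.

`aggregate_expression()` computes the median-based proportional expression
change per gene per experiment and averages across the experiments that
measured the gene — never imputing missing experiments — with the standard
error of that mean (undefined for a single experiment).

## 5. Reproducibility conventions

Every stochastic function takes an explicit `seed` and uses it through
`withr::with_seed`, leaving the caller's RNG state untouched.
`run_gsl_study()` expands its master seed into per-stage child seeds by a
fixed documented offset scheme (simulation +1, herbivory +2, expression
+3, bootstrap +4; `estimate_table()` adds the cell index within the
bootstrap stage, `coverage_simulation()` uses `seed + 2i` / `seed + 2i+1`
for draw and resample of replicate *i*). Runs with the same seed are
byte-identical, which the test suite asserts on the full artifact set.
CSVs are written with UTF-8 encoding, `.` decimals and no locale
dependence; the fully resolved configuration is written next to every
run's outputs.

## 6. Known limitations

* The kinetic model is irreversible and uncompartmentalised, with no
  transcriptional regulation; it is a mechanism for generating plausible
  steady-state response patterns, not a fitted model of the real pathway.
* Magnitudes — concentrations, modifier strengths, control coefficients —
  carry no empirical authority; only the frozen sign structure does.
* The expression ratio `r` is treated as known and fixed; qPCR uncertainty
  in `r` would widen the intervals and is out of scope.
* Wilks' Λ is the only MANOVA statistic provided (as in the analysis this
  battery mirrors); Pillai or Hotelling variants are not implemented.
* The per-experiment significance calls of the expression meta-analysis
  are not reproduced, as the summary they used is not derivable from
  per-arm medians.
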