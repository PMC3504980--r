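---
title: "Two-locus log-linear models for case-parent trios: methods and design"
author: "triolog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-locus log-linear models for case-parent trios: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `triolog`, the
assumptions it makes, the numerical and design choices taken where the
methodology left them open, and what the simulation machinery does and
does not emulate.

## The cell space and the model

The sampling unit is a case-parent trio: an affected child and both
biological parents, genotyped at a biallelic locus ("locus 1"), with the
mother additionally genotyped at a second, unlinked locus in linkage
equilibrium with the first ("locus 2"). Genotypes are coded 0/1/2 as
counts of the risk allele (by convention the minor allele, assumed
risk-increasing, at both loci).

Under mating symmetry — P(mother = i, father = f) = P(mother = f,
father = i) in the source population — the ordered parental pair and the
child genotype define exactly 15 Mendelian-consistent configurations,
which group into 6 mating types. `trio_configurations()` enumerates them;
the configuration with all three members heterozygous arises from two
equally likely transmissions and carries a multiplicity of 2, which
enters the model as a fixed `ln 2` offset. Stratifying the 15
configurations by the mother's locus-2 genotype gives the 45-cell table
on which everything operates. Expected cell counts are, on the log scale,

    ln n(i,f,j,k) = ln mu_m + alpha_i + beta_j + delta_k
                    + phi^MxM_ik + phi^MxO_jk
                    + [ ln p_k + ln 2 * I(i=j=f=1) ]

`expected_cell_proportions()` builds this table on the natural scale and
`trio_design()` linearizes it; an exact-reproduction identity between the
two (to 1e-12, for arbitrary admissible parameters) is part of the test
suite.

Ascertainment makes cell probabilities proportional to population trio
frequency times penetrance, so the Poisson regression of observed cell
counts on this design, with the bracketed offset fixed, gives maximum
likelihood estimates of log relative risks. All effect tests are
likelihood-ratio tests between nested fits on identical counts and
offsets; p-values are upper chi-square tails with degrees of freedom
equal to the number of free parameters removed. No small-sample
correction is applied.

## Model variants

* **`eq1`** specifies the locus-2 genotype frequencies `p = (p0, p1, p2)`
  in the offset and fits a 2-parameter locus-2 main effect `delta`.
  Interaction tests from this variant are *exactly* invariant to the
  specified `p` (the offset perturbation lies in the span of the
  mating-type and `delta` columns); the `delta` test itself is valid only
  when `p` is correct, and `trio_lrt(fit, "locus2")` warns accordingly.
* **`eq2`** estimates the frequencies through free columns
  `lambda_k = ln(p_k/p_0)`; the locus-2 main effect is then absorbed and
  cannot be requested. Interaction LRTs from `eq1` (any strictly positive
  `p`) and `eq2` are identical; the suite asserts this to 1e-6 on random
  tables. Both fits of every LRT re-estimate `lambda` freely.
* **`eq1_hwe`** additionally assumes Hardy–Weinberg equilibrium at
  locus 1: the six `mu_m` are replaced by an intercept plus a column
  `a_m` (the parents' total risk-allele count, 4/3/2/2/1/0), whose
  coefficient is `logit` of the allele frequency. A derivation note: with
  the ordered-row table used here, the HWE mating frequencies are exactly
  `mu_m = q^a (1-q)^(4-a)` — the factor 2 in the heterozygote genotype
  frequency cancels against the 1/2 transmission probability, and the
  double-heterozygote factor 2 is already carried by the configuration-9
  offset — so no additional multiplicity offsets are needed, and a fit to
  exact null proportions recovers `logit(q)` to machine precision (this
  identity is tested).
* **`eq3`** is the single-locus model on the 15 configurations, with the
  same-locus maternal-by-offspring interaction `rho_ij`. Its `rho` LRT is
  equivalent to the conditional multinomial (within-mating-type) test;
  the suite verifies the equivalence to 1e-6 against a directly optimized
  multinomial oracle.

**Mating-type nuisance.** Because the same `mu_m` multiplies all three
locus-2 strata of a configuration, the interaction parameters are
conditionally independent of the mating-type strata once the main effects
are in the model. Consequently the interaction tests are insensitive to
how the strata are modelled and to missing fathers. Note that the
insensitivity to replacing the six `mu` columns by a single intercept
(`mating = "intercept"`) is an *asymptotic* property of the tests'
operating characteristics, not an algebraic identity of the statistic on
a given table; it is therefore tested at the level of rejection rates,
within Monte-Carlo error.

## Genetic codings

`coding` applies per effect (a single string or a named list):
`"dominant"` fits one parameter shared by carriers of 1 or 2 risk alleles
(1-df interaction tests); `"codominant"`/`"unconstrained"` fit one free
parameter per genotype level (2-df main effects, 4-df interactions);
`"multiplicative"` (main effects only) constrains the 2-copy log-risk to
twice the 1-copy value. The locus-2 main effect always keeps its two free
parameters `delta_1, delta_2`, matching how the analyses that motivated
the package were run. Degrees of freedom are always derived from the
actual design columns, never hard-coded.

## Identifiability and degenerate tables

Two failure modes are detected before inference:

* **Zero-support parameters** — an indicator column all of whose
  supporting cells have zero count has its MLE at −∞ (for example, an
  empty `M2 = 2` stratum makes `delta_2` and every interaction parameter
  with second index 2 non-estimable). The likelihood limit is attained by
  excluding those cells and dropping the columns.
* **Linear aliasing** — detected by QR rank on the remaining columns.

By default `trio_model()` raises an error naming the non-estimable
parameters. With `allow_aliased = TRUE` (the replicate engine's setting)
they are dropped and recorded; a test whose parameters were all dropped
returns a *not-estimable* result (`NA` statistic and p-value) rather than
zero, and the power engine counts it as a non-rejection, tallied
separately. Zero counts in otherwise-supported cells are handled by the
Poisson likelihood itself; there is no continuity correction.

## Numerical choices

Fitting is iteratively reweighted least squares (`glm.fit`) on the
Poisson log-likelihood with deviance tolerance 1e-12 and at most 100
iterations, starting from zero (or warm-started inside the EM);
convergence is verified through the score norm
`max |X'(y - mu)|`, and fitted models preserve the sufficient statistics
`X'y`. Log-likelihoods are computed directly (`sum(y*eta - mu)` plus
constants), never through AIC slots, so fractional EM counts are handled
exactly. Likelihood-ratio statistics more negative than −1e-6 raise an
optimization-failure error; tiny negative values are clamped to zero.

## EM for incompletely genotyped trios

Families can miss the father's genotype, or the mother's genotypes at
*both* loci (a mother genotyped at one locus but not the other is not a
design point of the missingness model, though the E-step machinery
handles any pattern). Each incomplete family is compatible with the set
of cells agreeing with its observed entries (`compatible_cells()`); an
empty set flags a Mendelian inconsistency.

The E-step distributes each incomplete family over its compatible cells
proportionally to the current fitted means — offsets included, so locus-2
frequency information enters correctly for families with a missing
mother. The M-step refits the Poisson model to the fractional table to
full convergence (full M-steps are cheap on 45 cells). The observed-data
log-likelihood `sum_fam ln(sum_compatible mu) - sum mu` is monotone
across iterations (asserted at every iteration in tests); the EM stops
when it changes by less than 1e-8, with a cap of 500 iterations. Under
heavy paternal missingness a small fraction of replicates reaches the cap
on a nearly flat ridge of weakly identified mating-type parameters; such
fits are flagged as non-converged, and the replicate engine counts and
excludes them. LRTs after EM compare observed-data log-likelihoods, with
the reduced model run through the same EM on the same families; with no
incomplete families the EM path reduces exactly to the complete-data fit.

Standard errors after EM come from the observed-data information matrix,
computed by central differences on the observed log-likelihood (step
`1e-4 * max(1, |beta|)`); LRTs remain the primary inference. These
convergence and variance choices are design decisions of this package —
the methodology they implement does not prescribe them.

Families with a missing mother (case-father pairs) and case-only records
are excluded by default, with a warning and a count in the fit summary,
because missing mothers remove all locus-2 information and retaining
them can inflate the type-I error; `keep_case_father`/`keep_case_only`
retain them for research use.

## The simulator and what it emulates

`trio_scenario()` presets encode the study conditions under which the
package's operating characteristics are established: baseline disease
incidence 0.1, risk-allele frequency 0.3 at both loci, Hardy–Weinberg
equilibrium, locus-2 genotype frequencies (0.49, 0.42, 0.09), and mating
symmetry. Presets `model1`–`model10` are dominant scenarios (null; M×M
1.5 and 2; M×O 1.5 and 2; main effects 1.5; both interactions 1.5 and 2;
single-locus ρ 1.5 and 2); `model11`–`model14` are codominant with
per-genotype risks 1.3/1.69/2.197 (M×O), 1.4/1.96/2.744 (M×M), or
codominant main effects; the `a` variants draw father genotypes from an
equal mixture of Hardy–Weinberg strata with allele frequencies 0.1 and
0.5 — overall male frequency still 0.3, but the mating pattern is
asymmetric (P(F=1) = 0.34 versus 0.42 for mothers).

Ascertainment is prospective in distribution: a trio enters the study
with probability proportional to
`P(M) P(F) P(C|M,F) P(M2) x baseline x S_i R_j theta_ik phi_jk tau_k`
(`rho_ij` included for single-locus scenarios). Scenarios whose largest
cell risk exceeds 1 are rejected at validation rather than silently
capped, since capping would change the model. Two interchangeable
samplers are provided: the primary multinomial draw over the 45 ordered
cells (exact under the model), and an individual-level rejection sampler
that accepts each simulated family with probability equal to the child's
disease risk. Their distributional equivalence is asserted by two-sample
chi-square across the cell space for every dominant preset; under
symmetric null scenarios the multinomial probabilities equal the
theoretical trio-type table exactly. Missingness is completely at random:
one uniform draw per family against successive (father-rate, mother-rate)
intervals, so the two events are mutually exclusive within a family.

The generator does **not** emulate: linkage or linkage disequilibrium
between the loci, population stratification beyond the stated male
mixture, genotyping error, informative (MNAR) missingness, missing child
genotypes, imprinting, or X-linked inheritance. Passing tests therefore
say nothing about robustness to those features of real data; in
particular, interactions between linked loci require different methods
entirely.

## The replicate engine

`trio_power_study()` runs simulate → fit (EM when missingness is present)
→ LRT across replicates, with replicate `r` seeded deterministically as
`base_seed + r`, one RNG stream per dataset. Rejection requires
`p < alpha` strictly — at exactly `alpha` the replicate counts as a
non-rejection, a measure-zero convention fixed for determinism.
Default replicate count is 1,000, matching the scale at which the
package's reference results are computed (`scripts/acceptance.R`); the
test suite runs 60–600 replicates per study and compares rejection
fractions within 3 Monte-Carlo standard errors,
`sqrt(f(1-f)/n_replicates)`. Problem sizes throughout (300 or 1,000
trios; 45-cell fits) keep a full 1,000-replicate study under a minute.

## Known limitations and open choices

* The `mu_m` are interpreted as ordered-parental-pair frequencies (each
  ordered row of the table carries the same `mu_m`); this affects only
  the interpretation of the fitted `mu`, not any test.
* The restricted ("model reduction") analysis is defined here as the true
  interaction term plus the locus-2 main-effect nuisance parameters on
  top of the mating-type strata. Other compositions (dropping `delta`
  when `p` is correctly specified, or keeping both interactions) change
  the power of the 1-df interaction test materially, so reduced-model
  power figures should always be read together with the exact model
  fitted. Using the same data to select and then test the reduced model
  inflates the type-I error; an independent dataset is preferable.
* Wald intervals are reported in summaries for convenience, but the LRT
  is the canonical test; no robust/sandwich variances are provided.
* More than two alleles per locus, augmentation with unrelated controls,
  and genome-wide scanning are out of scope.
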