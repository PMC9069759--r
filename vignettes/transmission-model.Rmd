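---
title: "Modelling intergenerational transmission of BMI and educational attainment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling intergenerational transmission of BMI and educational attainment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famtrans)
```

## The scientific problem

Body mass index (BMI) and educational attainment (EA) are negatively
correlated within persons, and both are transmitted from parents to
offspring. Observational claims that parental EA (or socioeconomic
status) drives offspring BMI are confounded twice over: spouses resemble
each other in both traits (assortative mating), and EA and BMI are
correlated *within* each parent. A regression of offspring BMI on
maternal EA alone therefore picks up paths through maternal BMI,
paternal EA and paternal BMI. famtrans implements a family-level
structural equation model that estimates all of these paths jointly and
decomposes each parent-offspring association into its direct and
correlation-mediated indirect parts.

## The model

Each nuclear family is mapped to a canonical 16-slot vector: BMI and EA
of father and mother, then BMI and EA of up to three sons and three
daughters (`family_slots()`). Writing $P$ for the parental 4-vector and
$O$ for the offspring 12-vector,

$$ O = a + B\,P + E, \qquad E \perp P, $$

with $P \sim N(\mu_P, \Sigma_P)$ exogenous. The implied moments are

$$ \Sigma = \begin{pmatrix} \Sigma_P & \Sigma_P B' \\ B \Sigma_P & B
\Sigma_P B' + \Sigma_E \end{pmatrix}, \qquad \mu = (\mu_P,\; a + B \mu_P). $$

The free parameters of the **full model** (100 scalars):

* 16 transmission coefficients $b$ (2 parent traits x 2 parent sexes x
  2 offspring traits x 2 offspring sexes), shared across birth order
  within offspring sex;
* the parental covariance block: 4 variances, 2 within-person EA-BMI
  covariances, 4 spousal covariances (2 within-trait, 2 cross-trait);
* 4 offspring residual variances (trait x sex, shared across birth
  order) and 2 within-person residual EA-BMI correlations;
* 60 unconstrained pairwise sibling residual correlations among the 12
  offspring slots (15 same-trait per trait, 30 cross-trait
  cross-person);
* 8 intercepts (parental means plus one offspring intercept per sex and
  trait).

The **parsimonious model** (`model2()`, 90 free scalars) constrains the
transmission block to 6 equality classes: paternal BMI to offspring BMI
(one value for both offspring sexes), maternal BMI to son BMI, maternal
BMI to daughter BMI, parent EA to offspring BMI, parent EA to offspring
EA, and parent BMI to offspring EA. This is the constraint structure
selected by the gender-equality tests on the cohort the package's
calibration mirrors.

```{r}
n_free_parameters(full_model())
n_free_parameters(model2())
```

## Estimation

`fit_fiml()` maximizes the sum over families of the multivariate-normal
log density of each family's *observed* slots (full-information, or
raw-data, maximum likelihood). Families sharing a missingness pattern
are collapsed to sufficient statistics, so an evaluation costs one
Cholesky factorization per pattern regardless of sample size.

Numerical choices:

* **Transforms.** Variances are optimized on the log scale,
  correlations through atanh, so every iterate has valid marginal
  domains. Joint positive definiteness of the assembled residual block
  is checked at evaluation; violations are rejected (treated as
  infeasible), not projected.
* **Optimizer.** BFGS with the analytic FIML score (the per-pattern
  mean/covariance gradient accumulators contracted through the
  structural map in closed form, so one gradient costs one pass over
  the missingness patterns), polished by a final `nlminb` pass;
  convergence at a relative log-likelihood change below 1e-13. On
  failure, a perturbed restart and a neutral start are tried. The
  observed information for standard errors is the central-difference
  Jacobian of that score.
* **Start values.** Transmission from moment regressions on
  pairwise-complete covariances; under missingness the pairwise
  covariance matrix is shrunk 10% toward its diagonal and residual
  correlation starts are damped to keep the start feasible; with
  complete data the start is the exact complete-data ML solution.
* **Identification.** Free-parameter classes with no support in the
  observed patterns (e.g. sibling correlations of birth slots no family
  occupies) are held at their start values and reported as `dropped`,
  with `NA` standard errors. The observed-information matrix is
  additionally checked at the optimum; rank deficiency triggers a
  warning and pseudo-inverse standard errors.
* **Inference.** Standard errors come from the inverse observed
  information (numeric Hessian on the natural scale); confidence
  intervals are Wald, estimate ± 1.96 SE. The published tables the
  calibration mirrors flag significance at p < 0.01 without naming a CI
  method, so Wald is a documented package choice.

`fit_saturated()` fits the unrestricted mean and covariance of every
slot the data observes, by EM over the same pattern statistics; with
complete data it reproduces the sample mean and the 1/n sample
covariance in one step. The model chi-square is twice the log-likelihood
gap to this saturated fit. Degrees of freedom are counted from the
moment/parameter inventory — means plus distinct covariances of the
observed slots, minus identified free scalars — which yields df = 52 for
the full model at full 16-slot coverage. Published df values for this
model family follow a different (unstated) counting convention and are
deliberately not reproduced; chi-square, df and RMSEA are reported for
the data at hand only.

## Effects

Raw coefficients are standardized as $b \cdot \sigma_{parent} /
\sigma_{offspring}$, where $\sigma_{offspring}$ is the **model-implied
total** standard deviation, not the observed one. This choice makes the
decomposition internally consistent: with parental correlation matrix
$R$ and standardized coefficients $\beta$, the indirect effect of
parental variable $j$ on offspring variable $k$ is $\sum_{m \ne j}
R_{jm} \beta_{m \to k}$, and direct + indirect = total holds exactly
(`effect_table()` asserts it to machine precision). Parental
correlations are taken at the estimates, not from observed data —
another documented choice, since the decomposition should be a function
of the fitted model alone. CIs for standardized estimates scale the raw
Wald interval by the same SD ratio, treating the SDs as fixed; no
mediation-style CIs for indirect effects are attempted.

## Gender-equality testing

`gender_equivalence_suite()` runs 8 likelihood-ratio tests against the
full model: for each transmission type (BMI→BMI, EA→EA, BMI→EA, EA→BMI),
equality across offspring gender and equality across parent gender. With
a family-wise alpha of 0.01 the Bonferroni test-wise level is 0.01/8 =
0.00125. Tests are run marginally (each restriction alone against the
full model), and the final model composes the constraints of all
non-rejected tests jointly — the suite does not search sequentially.
Constraints merge transitively through equality classes, so composing
"equal across offspring" and "equal across parents" for one type yields
a single shared coefficient.

## The synthetic-family generator

No public dataset accompanies the design this package implements, so
`simulate_families()` generates family data with the statistical
structure the analysis assumes, calibrated to published summary
statistics of a large Dutch twin-family cohort (Netherlands Twin
Register-like; see `reference_calibration()`):

* parental covariance block and offspring phenotype variances from the
  published age-adjusted covariance table;
* transmission coefficients at the published parsimonious-model
  estimates (paternal BMI→BMI 0.212, maternal BMI→son 0.098,
  maternal BMI→daughter 0.209, EA→BMI −0.066, EA→EA 0.201,
  BMI→EA −0.024);
* residual variances chosen so implied offspring variances match the
  published ones (total minus transmission-explained, floored at 10% of
  the total); within-person residual correlations at the published
  −0.097 (sons) / −0.104 (daughters);
* family composition 18% parents-only, 45% offspring-only, 18% one
  parent, 19% two parents; two offspring per family with independent
  fair genders by default (the cohort's average of 1.4 offspring per
  family and its twin-pair structure are only partially published; a
  fixed-composition override, e.g. three sons and three daughters, is
  available);
* an 18% per-person chance of the short survey form, which lacks EA;
  role-specific normal ages truncated at 16, so the under-25 EA filter
  has realistic bite.

Two defaults are *invented plumbing*, clearly non-published and
overridable: sibling residual correlations (0.3 same-trait, −0.05
cross-trait) exist only so the generator has a full parameterization.
Phenotypes are generated directly on the age-adjusted analysis scale:
ages are attached for the filters but do not enter the phenotype model.
Consequently, passing tests demonstrate correct recovery of the assumed
multivariate-normal family structure — they cannot speak to age
nonlinearity, floor/ceiling effects in the 8-level EA scale, reporting
error in self-reported BMI, or non-normal tails, none of which the
generator emulates.

## Data handling choices

* EA is an 8-level ordered scale of highest completed Dutch education,
  treated as continuous everywhere; `encode_ea()` maps labels and Dutch
  aliases to levels at ingestion. Generated EA values are continuous and
  may fall outside 1-8; the 1-8 range is enforced only for labelled
  input.
* Age adjustment regresses each trait on age and age squared within each
  role group, keeping residuals. The functional form is a package
  choice: quadratic is the minimal shape that captures the well-known
  curvature of BMI over adulthood; collinear terms are dropped, so a
  constant-age group reduces to mean-centering.
* EA below age 25 is masked (attainment may not be final); the BMI
  range filter (15-45) is a sensitivity device, not a default.
* Families with more than three offspring of one gender keep the three
  oldest (ties broken by person id) — a deterministic rule chosen for
  reproducibility.
* Missingness is carried as NA plus a mask; no sentinel values exist
  anywhere in the pipeline.

## Problem sizes used by the test-suite and acceptance checks

Stochastic properties are verified at sizes chosen to balance
Monte-Carlo precision against runtime, and these sizes are package
choices stated here: transmission recovery at 50,000 complete families
(one fit), likelihood-ratio type-I calibration with 500 replicates of
2,000 families, parameter-recovery bias/coverage with 20 replicates of
5,000 families, gender-suite scenarios at 4,000 families, and generator
moment checks at 30,000-100,000 families. At 50,000 families the Wald SE
of the shared paternal BMI→BMI coefficient is about 0.003, so recovery
within three SEs tests agreement to about ±0.01 on a coefficient of
0.212.

## Known limitations

* The model is linear-Gaussian; liability-threshold treatment of
  dichotomized BMI is deliberately out of scope.
* Sibling residual correlations are estimated freely per slot pair;
  zygosity (twin-specific) structure is not modelled.
* Standard errors assume a correctly specified likelihood (no
  sandwich/robust variant) and CIs are symmetric Wald intervals.
* The indirect-effect decomposition is a point decomposition; no
  uncertainty is attached to indirect or total effects.
* With heavily restricted compositions some parameters are structurally
  unidentified; they are reported as dropped rather than silently
  estimated.
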