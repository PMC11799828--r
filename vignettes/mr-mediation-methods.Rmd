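---
title: "Summary-data MR mediation: models, inference and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Summary-data MR mediation: models, inference and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The estimation problem

Mediation analysis decomposes the causal effect of an exposure X on an
outcome Y into a component transmitted through a mediator M (the indirect
effect) and a residual direct effect. With individual-level data this is
classically done by comparing regression coefficients; the difficulty is
unmeasured confounding of the X–M, X–Y and M–Y relationships. Mendelian
randomization (MR) sidesteps confounding by using genetic variants as
instruments: under the linear structural model

$$X = \gamma_X' U + \textstyle\sum_k a_k G_{X,k} + \varepsilon_X, \qquad
  M = \alpha X + \gamma_M' U + \textstyle\sum_k b_k G_{M,k} + \varepsilon_M, \qquad
  Y = \delta X + \beta M + \gamma_Y' U + \varepsilon_Y,$$

the total effect is $\tau = \alpha\beta + \delta$, the indirect effect
$\alpha\beta$, and the mediation proportion $\rho = \alpha\beta/\tau$.
Everything is estimable from GWAS summary statistics alone: per-SNP
association estimates $\hat a_k$ (with X), $\hat b_k$ (with M) and
$\hat\pi_k$ with standard error $\hat\sigma_k$ (with Y), aligned to a
common effect allele, plus instrument lists $G_X$ and $G_M$.

Because the union of two separately clumped instrument sets can contain
cross-correlated variants, the sets are re-pruned jointly ("double
clumping", `double_clump()`): LD blocks are connected components of the
thresholded r² graph and only the most significant variant of each block
survives, giving mutually uncorrelated subsets $G_X'$ and $G_M'$. The
package consumes a precomputed r² lookup rather than a genotype reference
panel; real-data clumping belongs to dedicated LD tooling, and a missing
pair in the lookup is an error rather than an implicit claim of
independence.

## The eight estimators

Two frameworks, each with inverse-variance weighted (IVW), Egger and
weighted-median engines:

| method | total effect | direct / mediator path | inference for IE |
|---|---|---|---|
| Diff-IVW0 | MR-IVW on $G_X$ | MVMR-IVW on $G_X' \cup G_M'$ | Var sum, Cov $\equiv$ 0 |
| Diff-IVW | MR-IVW on $G_X'$ | MVMR-IVW | Var sum with reconstructed Cov |
| Diff-Egger | MR-Egger on $G_X'$ | MVMR-Egger | as Diff-IVW |
| Diff-Median | MR-Median on $G_X'$ | MVMR-Median (weighted L1) | parametric bootstrap percentiles |
| Prod-IVW0 | MR-IVW on $G_X$ | $\alpha$: MR-IVW on $G_X$; $\beta$: MVMR-IVW | delta method, independence assumed |
| Prod-IVW | MR-IVW on $G_X'$ | $\alpha$: MR-IVW on $G_X'$; $\beta$: MR-IVW on $G_M'$ | delta method |
| Prod-Egger | MR-Egger | Egger throughout | delta method |
| Prod-Median | MR-Median | median throughout | delta method on bootstrap SEs |

The difference framework computes IE $= \hat\tau - \hat\delta$ and the
product framework IE $= \hat\alpha\hat\beta$ with
$\mathrm{Var}(\hat\alpha\hat\beta) \approx
\hat\alpha^2\mathrm{Var}(\hat\beta) + \hat\beta^2\mathrm{Var}(\hat\alpha)$.
In both frameworks the three point estimates obey TE = DE + IE exactly, and
$\hat\rho$ = IE/TE with a delta-method variance (carrying the TE–DE
covariance term in the difference framework). A negative $\hat\rho$ is
reported as-is; it usually signals opposing direct and indirect paths, where
the proportion lacks a clean interpretation.

The `*0` methods reproduce legacy practice predating double clumping: the
total effect (and, for `Prod-IVW0`, the exposure–mediator effect) is
estimated on the full $G_X$, and `Diff-IVW0` assumes zero covariance
between $\hat\tau$ and $\hat\delta$. They are included as comparators, not
recommendations: retaining instruments correlated with mediator instruments
biases $\hat\tau$ (and $\hat\alpha$) through the partner variants' direct
mediator effects, and the zero-covariance assumption makes the legacy
difference interval for IE very conservative. Both pathologies are visible
in the simulation study below.

## Covariance between the total- and direct-effect estimators

Both $\hat\tau$ (UVMR) and $\hat\delta$ (MVMR) are weighted least-squares
estimators, hence linear in the SNP–outcome statistics:
$\hat\tau = \sum_k c_k \hat\pi_k$ over $G_X'$ and
$\hat\delta = \sum_k d_k \hat\pi_k$ over $G_X' \cup G_M'$, with weight
vectors exposed by every fit. In the two-sample setting the outcome
statistics are the only ingredients the two estimators share, so

$$\widehat{\mathrm{Cov}}(\hat\tau, \hat\delta)
  = \sum_{k \in \text{shared}} c_k\, d_k\, \hat\sigma_k^2 .$$

Two design choices here were genuinely open:

* **Which SNPs are shared.** The linear-representation approach answers
  this automatically (the SNPs appearing in both weight vectors), including
  for Egger fits, where the intercept column simply reshapes the weights.
* **Heterogeneity scaling.** The variances entering
  $\mathrm{Var}(\text{IE})$ use the multiplicative random-effects inflation
  $\phi = \max(1, Q/\mathrm{df})$, and one could symmetrically scale the
  covariance by $\max(1, \sqrt{\phi_\tau\phi_\delta})$. We validated both
  options against Monte-Carlo oracles: over regenerations of the outcome
  statistics the *unscaled* sum matches the empirical covariance of
  $(\hat\tau, \hat\delta)$, while the clamped scaling biases it upward
  (under no heterogeneity $E[\max(1, Q/\mathrm{df})] > 1$), which in full
  scenario replications translates into under-coverage of the
  indirect-effect interval (0.83 vs the expected ~0.95 at our study
  conditions). The covariance is therefore left unscaled; the variances
  keep their own $\phi$. Residual overdispersion from balanced pleiotropy
  is then absorbed conservatively (variances grow, covariance does not).

The exactly-identified limit is a useful sanity check: when the same single
instrument determines both estimators, $c = d = 1$ and
Var(IE) $= \sigma^2 + \sigma^2 - 2\sigma^2 = 0$, matching the fact that
IE $\equiv 0$ in that degenerate case.

A consequence of this construction worth knowing: under *shared*
directional confounding pleiotropy (scenarios S9–S11 below) the biases of
$\hat\tau$ and $\hat\delta$ largely track each other, so their difference
stays closer to the truth than either component while the heterogeneity
inflation widens the interval — in our replications the covariance-aware
difference method retains substantial indirect-effect coverage in those
scenarios, whereas the product-framework IVW collapses to zero coverage. A
covariance scaled by the (large) heterogeneity parameters would instead be
over-subtracted there, shrinking the interval onto a biased estimate; that
is the main practical argument for leaving the covariance unscaled.

## Median engines and the parametric bootstrap

The weighted median of the per-SNP Wald ratios $\hat\pi_k/\hat a_k$
(weights $1/\text{SE}^2$, midpoint-cumulative interpolation at 1/2) is
consistent when more than half of the instrument weight is valid. Its
multivariable analogue minimizes the weighted sum of absolute residuals
$\sum_k w_k |\hat\pi_k - \delta \hat a_k - \beta \hat b_k|$ through the
origin, solved by IRLS with an $\varepsilon$-smoothing of $10^{-8}$ on the
residuals and polished by direct search on the exact objective; the fit is
validated in the tests against a grid-search oracle and must weakly beat
the IVW solution's L1 objective.

Median-type estimators have no usable closed-form variance, so inference is
by parametric bootstrap: every summary statistic is redrawn from a normal
distribution centred at its observed value with its reported standard
error, independently across the three traits (a three-sample assumption,
recorded in the output), the whole method is re-estimated, and `Diff-Median`
takes percentile intervals (the other median methods use the bootstrap
standard deviations inside the delta formulas with normal intervals).
Defaults: 1000 replicates for a single analysis, a mandatory seed wherever
randomness enters, and replicate failures are dropped and counted with an
error above 20%.

## The simulation engine

`scenario_spec()` defines eleven evaluation scenarios; `generate_scenario()`
draws one replicate of individual-level data and reduces it to summary
statistics by per-SNP ordinary least squares, exactly as GWAS would.

The generative model: 80 exposure and 80 mediator SNPs per trait, of which
the first 60 in each set are mutually uncorrelated ($G_X'$, $G_M'$) and the
trailing 20 form cross-trait pairs with genotype correlation 0.5 and shared
allele frequency; allele frequencies uniform on (0.3, 0.7); genetic effects
$a_k, b_k$ uniform on (0.02, 0.06); causal effects
$(\alpha, \beta, \delta) = (0.3, 0.3, 0.21)$, so TE = 0.3, IE = 0.09,
$\rho$ = 0.3; three correlated normal confounders (variances 0.6,
covariances 0.2/0.4/0.2) loading on the traits with coefficient patterns
(1,0,1), (1,1,0), (0,1,1); standard-normal trait errors; n = 80,000 per
sample, with the exposure and mediator sharing one sample in the two-sample
design and all three traits drawn independently in the three-sample design.

Pleiotropy patterns per scenario: none (S1); type (a) — exposure
instruments directly affecting the mediator and vice versa (S2/S7);
type (b) — horizontal effects on the outcome (S3/S8); type (c) — effects
routed through the confounders (S4/S9); all three combined (S5/S6 and
S10/S11, the latter pair three-sample). For each affected coefficient
family, exactly 20% of the 80 SNPs (drawn uniformly without replacement,
independently per family and per replicate) receive nonzero values, uniform
on (−0.03, 0.03) in the balanced scenarios and (−0.02, 0.04) in the
directional ones. A SNP is flagged invalid when any of its pleiotropy
coefficients is nonzero; in single-type scenarios this gives 48/60 valid
instruments per pruned set in expectation, and mixed-type scenarios
fluctuate around 34/60 and 31/60.

Two generator conventions deserve comment:

* **Correlated pairs** are built as a shared/independent allele-draw
  mixture: each of a pair's two allele draws is the same Bernoulli(p)
  outcome with probability 0.5 and independent otherwise. This yields
  exactly the target genotype correlation with identical Binomial(2, p)
  marginals, without any Gaussian-copula machinery.
* **Genotype dosages are standardized** (population mean and variance per
  SNP) before entering the confounder and trait equations, so each SNP
  contributes $a_k^2$ to the trait variance regardless of allele frequency.
  With raw dosages the same effect-size range would yield roughly half the
  instrument strength; the standardized convention gives mean per-SNP
  F-statistics near 45 (exposure) and 36 (mediator) and joint explained
  variances near 3.3% and 2.6% at n = 80,000, the operating point the
  estimator comparison is designed around. The mediator-side figures
  include the covariance between $\alpha X$ and the mediator's confounder
  load, which materially inflates Var(M) — a detail that is easy to miss
  when back-calculating instrument strength by hand. Causal-effect estimates are
  invariant to the genotype scale (they are ratios), so this choice only
  pins the instrument-strength regime. A `standardize_genotypes = FALSE`
  switch retains the raw-dosage variant.

The intercepts of the trait models are irrelevant to slope-based summary
statistics and are fixed at zero.

What the generator does *not* emulate: real LD structure beyond the fixed
0.5-correlation pairs, allele-frequency-dependent effect sizes, binary
outcomes and case-control ascertainment, sample overlap between the
exposure/mediator and outcome GWAS, population stratification, and
palindromic-strand ambiguity (simulated SNPs are keyed by identifier).
Passing the simulation study therefore demonstrates correctness of the
estimators and their inference under the stated linear model, not
robustness to every pathology of real GWAS data; the harmonization layer
addresses the allele-orientation part of that gap for real inputs.

## Legacy-method composition

One compositional point is ambiguous in the way legacy pipelines are
usually summarized: which instrument set the legacy product method uses for
the exposure–mediator stage. Pruning advice applies to the *proposed*
methods; the legacy pipeline predates it. We therefore compose `Prod-IVW0`
with $\hat\alpha$ estimated on the full $G_X$ (like its total effect), not
on $G_X'$. The distinction matters: with correlated tail pairs in the
instrument set, $\hat\alpha$ absorbs the partner SNPs' direct mediator
effects (a bias of roughly +0.12 at the simulation's operating point) and
the legacy indirect-effect interval collapses to far-below-nominal
coverage — the documented failure mode that motivates the pruned,
UVMR-only product method. Composing the legacy method with $\hat\alpha$ on
$G_X'$ instead would make it nearly indistinguishable from `Prod-IVW` in
the no-pleiotropy scenario and would not reproduce that failure.

## Numerical conventions and degenerate inputs

* Heterogeneity scales are clamped at 1 (no benefit from underdispersion);
  denominators are K − p with p the number of fitted parameters.
* Egger engines orient SNPs to non-negative exposure associations (flipping
  all of a SNP's statistics), the convention under which the intercept
  estimates average directional pleiotropy.
* Exposure-side uncertainty is ignored in point estimation (the standard
  no-measurement-error convention); instrument strength is diagnosed by
  per-SNP F-statistics and an experimental conditional-strength statistic,
  not corrected for.
* Ties in weighted-median interpolation and clumping are broken
  deterministically (identifier order); a zero exposure association drops
  the SNP from ratio-based engines with a warning; a zero total-effect
  estimate flags the mediation proportion as undefined; K below an engine's
  minimum (1 for IVW, 3 for Egger/median, 4 for their MVMR analogues) is an
  error; a negative reconstructed Var(IE) (possible when the covariance is
  large and heterogeneity estimates disagree) is truncated at zero with a
  warning.
* All randomness flows from explicit seeds; bootstrap and simulation
  results are bit-reproducible given the seed.

## Problem sizes in the shipped tests

The test suite replicates the evaluation at reduced scale chosen to keep a
full run around twenty minutes: the S1 coverage/recovery study uses 300
replicates at the full n = 80,000 (coverage estimates then carry a
Monte-Carlo SE of about 0.015–0.03), the directional-robustness checks use
20 replicates per scenario, interval-width comparisons use 3 replicates per
scenario at n = 40,000, and bootstrap sizes inside replicated studies are
150–200 (1000 remains the single-analysis default). Unit tests of the
estimators run on small synthetic fixtures against independent oracles
(generic weighted least squares via `lm`, brute-force cumulative-weight
medians, grid searches, connected-component enumeration, Monte-Carlo
covariance and calibration oracles).

## Known limitations

Single mediator only; no exposure–mediator interaction or non-linear
pathways; no correlated-instrument (generalized) IVW, so the r²-pruned
instrument sets are a prerequisite rather than an option; the conditional
instrument-strength diagnostic is a qualitative stand-in for the published
two-sample conditional F-statistic, whose exact formula is not implemented;
binary outcomes are handled only presentationally (odds-ratio
exponentiation of the results table); and sample-overlap configurations
other than the declared two- and three-sample designs (e.g., partially
overlapping GWAS) are not modelled — the design flag is metadata the user
asserts, not something inferable from summary data.
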