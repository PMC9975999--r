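---
title: "Methods: twin modelling of fear-conditioning phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin modelling of fear-conditioning phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinfear)
```

## The scientific problem

Differential fear conditioning is an experimental model of anxiety
development and of exposure-based treatment. Participants see two neutral
stimuli; one (the CS+) is intermittently paired with an aversive outcome
during an acquisition phase, the other (the CS−) never is. During a later
extinction phase, neither is reinforced. On every trial participants rate,
on a 1–9 scale, how much they expect the aversive outcome. Discriminative
learning is indexed by the *differential score* — the mean CS+ expectancy
minus the mean CS− expectancy over a trial window. In a twin sample,
comparing monozygotic (MZ) and dizygotic (DZ) resemblance on these scores
separates additive-genetic (A), shared-environment (C) and non-shared
environment plus error (E) contributions, and multivariate modelling asks
whether the *same* genes influence fear acquisition and its extinction.

`twinfear` implements this analysis end to end: phenotype derivation from
trial-level ratings, moment-based twin descriptives, and trivariate
Cholesky ACE/AE models fitted by full-information maximum likelihood
(FIML), with a synthetic-data generator so every stage can be validated by
parameter-recovery simulation.

## Phenotype derivation

Three phenotypes are derived per participant:

* **initial development** — differential score over the first third of
  acquisition (trials 1–4 per stimulus, of 12);
* **consolidation** — last third of acquisition (trials 9–12);
* **extinction** — first third of extinction (trials 1–6 per stimulus, of
  18).

Design choices worth noting:

* *Thirds are counted per stimulus*, not over the interleaved presentation
  sequence, matching the convention of "first four trials of acquisition"
  for a 12-trial phase. The alternative (interleaved thirds) differs only
  when the presentation order is very unbalanced, which the pseudo-random
  order rules out.
* *Missing-trial tolerance*: a window mean is computed when at least half
  of that window's trials are rated for each stimulus, otherwise the
  phenotype is missing. This retains participants with sporadic skips
  without letting a single trial stand in for a window.
* Participants who removed headphones, lowered volume below 50% or exited
  the app are excluded entirely before any score is computed.
* Scores are residualized on age and sex by OLS (co-twins share both, so
  unmodelled age/sex effects inflate twin correlations), then normalised
  with a *signed* square root, `sign(x) * sqrt(|x|)`. A plain square root
  is undefined for negative residuals; the signed version is defined on
  the whole line, odd, and order-preserving, and reduces the heavy tails
  that differential scores inherit from the bounded rating scale. This is
  the package's resolution of an ambiguity in common practice ("residuals
  were square-root transformed"), chosen once and kept.
* Sex is coded as a 0/1 indicator with a configurable reference level;
  residuals are invariant to the choice.
* Opposite-sex DZ pairs are pooled with same-sex DZ pairs into a single DZ
  group; sex effects on means are already regressed out.

## Twin descriptives

Intraclass correlations are computed as **double-entry Pearson
correlations**: each complete pair contributes both orderings, which makes
the estimator exactly invariant to within-pair order and makes the
cross-twin cross-trait matrix — entry (i, j) is the correlation of trait i
of one twin with trait j of the co-twin — exactly symmetric, with the ICCs
on its diagonal. Phenotypic correlations pool all individuals, singletons
included. Singletons cannot contribute to pair statistics.

Confidence intervals come from a **stratified family bootstrap**: families
(pairs or singletons) are resampled with replacement within zygosity
strata, and percentile intervals are taken over (by default) 100
iterations. The percentile method is used throughout; with 100 iterations
the interval endpoints are themselves noisy, which is the accepted
trade-off at this iteration count.

## The biometric model

For each family the stacked phenotype vector of (twin 1, twin 2) is
modelled as multivariate normal with

* within-twin covariance `S = A + C + E`,
* cross-twin covariance `alpha * A + C`, with `alpha = 1` for MZ and
  `0.5` for DZ pairs,

where each component is parameterized as `L %*% t(L)` with `L` a 3×3 lower
triangular loading matrix (the Cholesky parameterization), so every
component is positive semi-definite for any parameter value. The AE
variant drops `L_C` (12 covariance parameters plus 3 means; ACE has 18
plus 3). One mean per trait is shared across twin order and zygosity —
the phenotypes are residualized, so a saturated means model would add
parameters without substance.

**FIML.** Each family contributes the normal deviance of its *observed*
subvector: complete pairs contribute 6 values, singletons up to 3, and
individual missing phenotypes are dropped row-wise. No imputation is done;
this is exactly the full-information likelihood. Families are grouped by
(zygosity, missingness pattern) so the deviance and its analytic gradient
are computed with one covariance factorization per pattern; both are
implemented in compiled code (RcppArmadillo), as is usual for SEM engines,
and the analytic gradient is verified against central differences in the
test suite. A numerically singular implied covariance returns a large
finite penalty rather than an error, so the optimizer can back away.

**Optimization.** `nlminb` (PORT quasi-Newton) with the analytic gradient.
The automatic start builds component matrices from Falconer-type moment
estimates on double-entry twin correlations (clipped to [0, 1]) combined
with the observed phenotypic correlation matrix. Convergence is declared
when the optimizer terminates normally and the gradient norm satisfies
`||g|| < 1e-5 * (1 + |-2lnL|)` — a scale-aware form of a fixed gradient
tolerance, since the deviance is of order 10^4 at realistic sample sizes.
On non-convergence up to 5 jittered restarts are attempted. After fitting,
each loading matrix has columns sign-flipped so diagonals are
non-negative; the likelihood is invariant to column signs (tested), so
this is purely a reporting convention. `L_C = 0` is an interior stationary
point of the Cholesky parameterization, so ACE fits are started with
small positive C loadings.

**Correlated-factors solution.** The fit is reported as standardized
variance components `a2 = diag(A)/diag(S)` (likewise `c2`, `e2`),
component correlations `rA = cov2cor(A)` (likewise `rC`, `rE`), and the
decomposition of each phenotypic correlation into component contributions
`contrib_A = A_ij / sqrt(S_ii S_jj)`, which sum to the phenotypic
correlation exactly. Sampling can push `rA` estimates beyond 1 when the
true value is near the boundary; they are reported as computed and only
truncated in printed displays.

**Model comparison.** ACE vs AE by likelihood ratio on 6 df (the six C
loadings) and by AIC. No boundary (chi-bar-square) correction is applied
to the reference distribution; this follows common practice in the twin
literature and makes the test slightly conservative toward the larger
model — a documented limitation.

**Bootstrap CIs.** The family bootstrap above, refitting the model on each
resample starting from the point estimate (a warm start; the resampled
likelihood is close to the original, so this is both fast and stable).
Non-converged resamples are dropped and counted; more than 20% failures
aborts with diagnostics.

## The synthetic-data generator

`generating_model()` specifies ground truth as standardized components
(`a2`, `c2`, `e2` summing to 1 per trait), component correlation matrices,
means, total variances and a sample plan; construction verifies every
implied covariance is positive semi-definite. `fear_generating_model()`
is the package's reference condition: an AE model with
`a2 = (0.15, 0.29, 0.15)`, genetic correlations 0.99 / 0.42 / 0.44,
non-shared-environment correlations 0.49 / 0.31 / 0.41, and a sample plan
of 250 MZ pairs, 288 DZ pairs and 860 singletons — effect sizes and a
sample structure representative of large remote fear-conditioning twin
studies, so recovery simulations run at realistic power. Where only a
range is reported for the rE pairings in that literature
(0.31–0.49), the pairwise assignment here (initial–consolidation 0.49,
initial–extinction 0.31, consolidation–extinction 0.41) is a documented,
configurable default consistent with the ranges. Singletons are assigned
MZ status with probability 250/538, the zygosity ratio among complete
pairs, as their mix is otherwise unknown.

Phenotypes are generated on a standardized scale (mean 0, variance 1);
the empirical transformed-residual scale is arbitrary, so nothing is lost.
Pairs are drawn from the 6-variate implied normal (via a symmetric
eigenvalue square root, which tolerates semi-definite cases such as
`e2 = 0`), singletons from the 3-variate margin.

**Seeding.** Every family has its own stream: the master seed and a
(block, index) counter determine a per-family seed, so enlarging any part
of the sample plan leaves earlier families' values unchanged, and the
phenotype-level and trial-level simulators agree on the latent values for
the same master seed.

**Trial-level emulation.** For each participant the CS+/CS− differential
follows a logistic rise over acquisition and an exponential decay over
extinction, scaled so the noiseless window means equal
`baseline + scale * latent` (defaults: baselines 2.35 / 4.0 / 2.0 rating
units, 1.5 units per latent SD). Ratings are a mid-level trajectory plus
and minus half the differential with Gaussian trial noise (SD 0.8),
rounded and clipped to 1–9; the CS+ is reinforced on exactly 9 of 12
acquisition presentations, and presentation order is pseudo-random with
at most 2 identical stimuli in a row (the cap is an assumption standing in
for unpublished presentation rules). Discretization and clipping attenuate
the derived phenotypes slightly relative to the latent ones — round-trip
recovery of heritabilities is therefore verified at a wider 0.08 band than
the phenotype-level simulations. What the generator does **not** emulate:
learning heterogeneity (non-learners, reversed contingency beliefs),
serially correlated attention lapses, floor/ceiling clustering of real
raters, and any dependence of compliance exclusions on the phenotype.
Passing recovery tests therefore validate the estimators under the stated
covariance structure, not the behaviour of the instrument itself.

## Numerical and testing choices

* Likelihood/oracle agreement is asserted at 1e-8 against an independent,
  unpooled per-family implementation in plain R.
* Recovery simulations use 200 replicates at the reference sample plan;
  medians of standardized estimates are compared with the generating
  values (bands 0.03 for variance shares and the near-boundary rA, 0.08
  for the noisier genetic correlations involving the low-heritability
  extinction trait).
* Bootstrap coverage is checked over 200 replicates of a reduced plan
  (100 MZ / 115 DZ pairs, 344 singletons) with 100 bootstrap iterations
  each — sizes chosen to keep the whole suite's runtime moderate while
  leaving Monte-Carlo error on a coverage proportion near 1.5 points.
* The Falconer consistency check at 50,000 pairs per zygosity uses the
  mean deviation over 5 datasets: the single-dataset Monte-Carlo sd of
  `2(rMZ − rDZ)` is ~0.012, close to the 0.02 consistency band, so a
  single draw would test seed luck rather than estimator bias.
* Degenerate inputs: zero-variance scores centre with a warning; collinear
  age/sex designs fall back to centering through `lm`'s rank handling;
  fewer than 3 complete pairs is an error for pair statistics; a
  single-zygosity dataset is rejected as unidentified.

## Known limitations

* The Cholesky parameterization constrains C to be positive semi-definite,
  so trait-wise shared-environment estimates cannot be negative; when the
  true c² is zero they therefore have a positive finite-sample median at
  realistic sample sizes (the constrained estimator piles up *near*, not
  *at*, the boundary in the trivariate case). The recovery tests document
  this: ĉ² medians shrink to zero as the sample grows, but at the
  reference plan they sit a few hundredths above it.
* No ADE, sex-limitation, dominance or moderation models; DZ genetic
  sharing is fixed at 0.5.
* Percentile bootstrap only; no profile-likelihood CIs.
* The chi-square reference for the ACE/AE comparison ignores the boundary
  constraint on C.
* Twin correlations are moment-based; no saturated SEM with equality
  constraints is fitted.
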