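---
title: "Functional network segregation and brain-behaviour association analysis with netsegfc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional network segregation and brain-behaviour association analysis with netsegfc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netsegfc)
```

## The scientific problem

In ageing cohorts, handgrip strength is an easily measured marker of
physical frailty that tracks cognitive function, and both are thought to
share neural substrates. Resting-state fMRI offers a window on those
substrates through *functional connectivity* (FC): the Pearson
correlation between the BOLD time courses of brain regions. A healthy
adult brain is functionally *segregated* — regions within a functional
network (default, control, salience/ventral attention, somatomotor, ...)
are strongly coupled to each other and only weakly coupled across
networks — and this segregation declines with age alongside cognition.

netsegfc implements the full statistical path from region-of-interest
(ROI) time series to segregation-based brain-behaviour inference:

1. **Connectivity**: per subject, Pearson-correlate every pair of ROI
   time courses and apply the Fisher transform $z = \mathrm{atanh}(r)$.
2. **Preparation**: set the diagonal and all negative $z$ entries to 0.
3. **Segregation**: with a region-to-network partition, compute the mean
   within-network connectivity $\bar{Z}_w$, mean between-network
   connectivity $\bar{Z}_b$, and
   $$\mathrm{Segregation} = \frac{\bar{Z}_w - \bar{Z}_b}{\bar{Z}_w},$$
   globally and per network, plus intra-network means, all pairwise
   inter-network means, and single-edge values.
4. **Phenotypes**: handgrip strength as the mean over hands of the
   per-hand maximum dynamometer reading; cognitive tests T-scored across
   the sample ($T = 50 + 10z$), averaged into domain composites
   (attention, processing speed, executive function) and a global score.
5. **Association**: covariate-adjusted OLS families with
   Benjamini-Hochberg FDR within each declared family.
6. **Mediation**: residualized single-mediator path models with
   percentile-bootstrap inference on the indirect effect.

Because cohort data of this kind are typically access-restricted, the
package ships a synthetic cohort generator that reproduces the
*statistical structure* the analysis assumes, so every stage is testable
end to end.

## Segregation: definitions and numerical choices

All segregation quantities are computed on the *prepared* matrix. Two
conventions matter and are fixed throughout:

* **Pooled-edge means.** Global $\bar{Z}_w$ is the mean over *all*
  unordered within-network region pairs pooled across networks (each
  pair counted once), not an average of per-network averages; likewise
  $\bar{Z}_b$ pools all between-network pairs. The consistency test
  suite verifies that the global quantities equal the pair-count
  weighted means of the per-network quantities.
* **Zeroed edges stay in the denominator.** An edge whose $z$ was
  negative before preparation contributes the value 0 to every mean; it
  is not dropped. Dropping it would bias means upward and make pair
  counts subject-dependent.

Whether intra-/inter-network mean FC should be computed on the prepared
(non-negative) matrix or on the raw Fisher-z matrix is genuinely open;
we compute it on the prepared matrix so that a single consistent matrix
state underlies every per-subject quantity, and the unprepared route
remains available by constructing a `ConnectivityMatrix` directly.

Degenerate inputs are rejected rather than patched: a region with zero
temporal variance (no defined correlation), a singleton network in a
network-level scope, and $\bar{Z}_w = 0$ (segregation undefined) all
raise errors naming the offender. Correlations of magnitude 1 — which
occur between affinely dependent columns in synthetic data — are clipped
to $1 - 10^{-7}$ (a $z$ of about 8.4) with a logged warning, since
$\mathrm{atanh}$ diverges there; the clip bound is a user-visible
argument.

Region pairs are always enumerated in lexicographic order by region
identifier, so edge-level result tables are reproducible across runs and
platforms.

## Association families

Families mirror the standard design for this analysis:

| family | predictor → outcomes | covariates | FDR scope |
|---|---|---|---|
| cognition | handgrip → 5 cognitive measures | age, sex, education | 5 measures |
| segregation | handgrip → 9 network segregations | + intracranial volume | 9 measures; global segregation reported alongside, uncorrected |
| focal_fc | handgrip → focal intra + 8 inter FC | + intracranial volume | 9 measures |
| focal_edges | handgrip → all focal-network edges | + intracranial volume | all edges (231 for 22 regions) |
| fc_cognition | each focal FC measure → 5 cognitive measures | + intracranial volume | 5 per FC measure |

Standard errors are classical (non-robust) OLS, p-values two-sided from
the t distribution — matching how coefficient/SE/t tables of this kind
are reported. The FDR adjustment is Benjamini-Hochberg step-up; the
package checks it against a direct min-over-suffix definition oracle in
its tests, and the worked examples in the acceptance suite reproduce
published adjusted-p tables from their printed uncorrected p-values to
within the propagated printed-precision bound. Rows with a missing value
in any model variable are dropped listwise per model with a logged
count. Validation selectors (`+smmse`, `+gds`, `+bmi`, `+whr`,
`+interval`, `gmv-swap`) add one covariate to every model or swap
intracranial for grey-matter volume; they never change family structure.

The SM-MMSE screening score is analyzed raw, not T-scored, so its
coefficients are on a different scale from the composite outcomes. Timed
tests (trail-making A/B) default to `higher_is_better = FALSE` before
T-scoring: the convention is not universal in test batteries, but a
composite in which longer completion times raise the score would be
incoherent; the flag is per-test and user-overridable in the battery
configuration.

## Mediation

`mediate()` follows the regress-out-first design: covariates are removed
from predictor, mediator and outcome by OLS, and the single-mediator
path model is fit on the residuals. The indirect effect is $a \cdot b$,
which for OLS on a single sample satisfies $c = c' + ab$ exactly (the
test suite asserts this identity to $10^{-8}$). Inference bootstraps
subjects with replacement — residuals treated as data — and reports a
95% percentile interval by default; percentile is the plainest reading
of "bootstrapped confidence intervals", and a bias-corrected and
accelerated (`ciType = "bca"`) variant is exposed. The bootstrap p-value
is the two-sided sign-crossing fraction
$2\min\{P(\hat{ab}^* \le 0),\ P(\hat{ab}^* \ge 0)\}$. The proportion
mediated $ab/c$ is flagged unstable (returned `NA`) when $|c|$ is
negligible relative to the outcome/predictor scale, since the ratio is
undefined at $c = 0$. A seed is mandatory; the same seed gives
bit-identical results.

## The synthetic cohort generator

`syntheticCohortSpec()` fixes the emulated study conditions as defaults:
148 subjects; 142 regions in nine networks (the salience/ventral
attention network has 22 regions, hence 231 within-network pairs;
subcortical has 30); 235 timepoints (an 8-minute scan at TR 2 s minus 5
discarded volumes); handgrip 22.3 kg (SD ≈ 7); age 72.8 (3.9) years;
education 7.28 (3.97) years; 83 female / 65 male; intracranial volume
1.4 × 10⁶ (1.3 × 10⁵) mm³.

Each subject draws a within-network correlation
$w_i \sim \mathrm{TN}(0.6, 0.08;\ [0.35, 0.85])$ and a between-network
correlation $b_i \sim \mathrm{TN}(0.2, 0.05;\ [0.02, 0.34])$; the ROI
correlation matrix is block-structured (within-network off-diagonals
$w_i$, all between-network entries $b_i$) and is provably positive
definite whenever $0 \le b_i < w_i < 1$, which the bounds guarantee by
keeping the between upper bound below the within lower bound. The
subject's latent segregation is defined on the measurement scale,
$$s_i = 1 - \frac{\mathrm{atanh}(b_i)}{\mathrm{atanh}(w_i)},$$
and the noise-free matrix shortcut (`generateMatrices()`) realizes it
exactly: the profiled `seg_global` equals $s_i$ to machine precision,
which the tests verify before replicate studies use the fast latent
route. Phenotypes couple linearly:
handgrip $= \alpha_0 + \alpha_1 s_i + $ covariate loadings $+$ noise,
and a latent cognition factor
$g_i = \beta_1 \cdot \mathrm{handgrip}_i + \beta_2 s_i + $ loadings $+$
noise drives all eight raw test scores (timed tests with negative
loading).

Rather than asking users to pick slopes in opaque units, the spec
calibrates them: `alpha1 = NA` solves for the slope that yields a target
covariate-adjusted partial correlation (default 0.27, the value implied
by a t of 3.32 at 142 residual degrees of freedom — the effect size this
kind of cohort reports for the salience/ventral attention network), via
deterministic quadrature over the truncated-normal correlation
distributions; no randomness enters calibration. `beta1` is calibrated
the same way to a default handgrip-cognition partial correlation of
0.26; `beta2` defaults to 0, so mediation structure is opt-in. Handgrip
noise SD 5.4 kg makes the total handgrip SD about 7 kg given the
covariate loadings (sex +8 kg for males, age −0.25 kg/yr, education
+0.1 kg/yr, intracranial volume 5 × 10⁻⁶ kg/mm³).

What the generator *does not* emulate: temporal autocorrelation, motion
and physiological artifacts, spatial geometry of parcels, and
network-specific effects — the same $(w_i, b_i)$ pair drives every
network, so all nine network segregations are equal in the noise-free
limit and the "focal network" signal is present in every network. A
passing pipeline therefore demonstrates statistical correctness of the
machinery, not that a specific network would be selectively detected in
real data.

## Problem sizes used in validation

The validation suites fix their own problem sizes: oracle-equivalence
checks run ≥ 100 random matrices up to 12 regions and ≥ 100 random OLS
designs; the type-I suite uses 500 null cohorts of n = 148 on a compact
18-region partition (two regions per network — null rejection rates do
not depend on region count, and the latent segregation route is verified
against the profiled route to 10⁻¹² beforehand); power uses 200
default-strength cohorts; recovery uses one n = 2000 cohort. The
recovery configuration programs strong couplings (partial correlations
0.6 and 0.5) rather than the default 0.27/0.26: at the default effect
size the sampling error of the recovered slope at n = 2000 is ~8% of its
true value, so a 10%-relative-error recovery criterion would fail by
chance alone roughly a quarter of the time regardless of implementation
correctness; recovery checks need an identifiable signal, and the
programmed-vs-recovered comparison is what is under test.

## Worked example

```{r example, eval = FALSE}
spec <- syntheticCohortSpec(nSubjects = 40, timepoints = 120, seed = 1)
dir <- tempfile()
simulateToDir(spec, dir)
res <- runPipeline(dir, file.path(dir, "out"), seed = 1, nBoot = 1000)
res$families$segregation
res$mediation
```

Every output table is TSV with fixed column order, and reruns with an
identical configuration are byte-identical (verified by checksum in the
test suite).

## Known limitations

* Preprocessing (motion correction, nuisance regression, band-pass
  filtering, parcellation) is out of scope; inputs are cleaned ROI
  time series.
* Negative-edge treatments other than zeroing (e.g. absolute value,
  signed variants) and graph-theoretic alternatives (modularity,
  participation coefficient) are not implemented.
* Single-mediator models only; no multiple mediators or sensitivity
  analysis.
* The published headline coefficients from restricted cohort data
  cannot be reproduced without that data; the package validates its
  arithmetic against the published tables' printed values and its
  statistical behaviour against simulation instead.
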