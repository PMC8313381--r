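---
title: "Trajectory-pattern screening for small-sample methylation studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory-pattern screening for small-sample methylation studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methpattern)
```

## The problem

Methylation arrays measure hundreds of thousands of CpG probes, but cell-line
and tissue-bank studies often provide only a handful of samples — here, the
emulated design is three myofibroblast tissue types (adjacent-tissue ATM,
cancer-associated CAM, unrelated-normal NTM) with three samples each, of
mixed sex, so some tissue-by-sex cells hold a *single* array. Probe-wise
tests with multiple-testing correction are essentially powerless at this
scale; what remains feasible is *screening*: ranking probes by evidence of a
structured, interpretable change while borrowing strength across probes.

`methpattern` does this with a constrained Bayesian mixture over trajectory
shapes, and keeps the two conventional companions alongside it for
comparison: a moderated t/F linear-model stage and a univariate Cox
screen of downstream candidate genes.

## Scales and transforms

Analysis happens on M-values, the log2-odds of the beta-value
(`m_from_beta()`, `beta_from_m()`); beta-values derive from allele
intensities with a positive offset (`beta_from_intensities()`), so they lie
in `[0, 1)` and the logit is finite. User-supplied beta files may still
contain exact 0/1; those are clipped to `[1e-6, 1 - 1e-6]` with a warning
(configurable to an error), since silently infinite M-values would poison
every downstream stage. Hypo-/hypermethylation calls use the conventional
0.2 / 0.8 thresholds with strict inequalities — a value exactly at a
threshold is "intermediate", a deliberate tie-break since the thresholds'
closure is a convention, not a measurement.

## Prefiltering

`anova_filter()` applies a per-probe one-way ANOVA across the three tissue
types, pooling sexes (sex enters only in the mixture and moderated stages),
and retains probes with `p < alpha` (strict, default 0.05). Degenerate rows
are flagged rather than scored: all-constant probes get `p = 1`, zero
within-group variance with a real between-group difference gets `p = 0`.
The filter runs on M-values by default; it is a plain location test, so the
choice of scale matters little for screening purposes.

## The mixture model

For probe `j` in sex stratum `s`, given cluster `h`:

    y_jsi = a_js + x_si1 b_js1 + x_si2 b_js2 + e_jsi,   e ~ N(0, sigma2_h)

* **Design.** `x1` indicates ATM, `x2` NTM; CAM is the reference. Group
  means are `(a + b1, a, a + b2)`, so the sign pair of `(b1, b2)` fixes the
  trajectory shape over ATM → CAM → NTM; nine sign pairs give nine clusters
  and the cross-sex pair gives 81 patterns, `FlatFlat-FlatFlat` being the
  null. Sign constraints identify the components: there is no label
  switching to undo.
* **Slopes** `b_jsk` are probe-level, constrained by the assigned cluster:
  a zero-sign coordinate is a point mass at 0, a non-zero coordinate is
  half-normal on the cluster's side with *cluster-level* precision
  `tau_sh ~ Gamma(7, 5)` (prior mean 1.4, i.e. typical magnitudes near
  0.85 M-units). The cluster thus couples its member probes through the
  slope scale and the noise level while each probe keeps its own effect
  magnitude. The alternative reading — one slope value shared by all
  member probes — was implemented and rejected: with a few hundred probes,
  the null ensemble's *aggregate* group-mean fluctuation (a ~0.1 M-unit,
  ~3-sigma sampling event in roughly one dataset in ten) is fit by a
  shared slope with standard error `sigma / sqrt(p n)`, creating a
  degenerate posterior mode in which a sign cluster offering a tiny common
  slope absorbs the entire null mass. Probe-level slopes remove that mode
  structurally: pooled pseudo-evidence cannot exist because each probe
  pays its own Occam factor for a non-flat coordinate.
* **Intercepts** `a_js` are probe-and-stratum specific with prior
  `N(probe stratum mean, v_a = 10)`. A cluster-indexed intercept would be
  unidentifiable with one or two samples per design cell, so the
  probe-level random effect absorbs baseline methylation instead.
* **Noise** `sigma2_h ~ Inv-Gamma(2, 1)` per cluster, pooled over strata
  and member probes; **weights** are Dirichlet(1, …, 1) per stratum, with
  memberships independent across strata given the weights, so pattern
  probabilities are empirical frequencies of the joint membership pair. A
  joint 81-component prior would couple the strata more tightly but adds
  nothing at two strata.

### Sampler

Inference is partially-collapsed Gibbs. Per sweep and stratum:
weights → memberships → slopes → intercepts; then slope precisions and
noise variances. The membership draw *integrates each probe's constrained
slope out analytically* (the truncated-normal prior times a Gaussian
likelihood has a closed-form normaliser), so the marginal factorises over
probes and the whole update is a single vectorised categorical draw.
Collapsing matters: conditioning on a current slope value instead would
let a sign cluster whose slope happens to sit near zero absorb null
probes at no likelihood cost — the collapsed draw charges exactly the
Occam factor that keeps null probes in the null cluster, which is what
the null calibration below measures. Collapsing requires redrawing slopes
immediately after memberships (before anything that conditions on them),
hence the slope-before-intercept order. Empty clusters need no special
casing: with no members every full conditional reduces to the prior.

Truncated-normal draws use inverse-CDF sampling, switching to one-sided
exponential rejection deep in the tail where the CDF saturates. Membership
initialisation is a per-probe sign test on group-mean differences at three
standard errors, with the per-probe variances shrunk toward the
across-probe median (they carry only ~2 df each); with the default
1,000-sweep burn-in the initialisation is
immaterial. One root seed drives everything; identical data, arguments and
seed reproduce results bit-for-bit. No thinning is applied — draws are
cheap and autocorrelation only widens, never biases, the empirical pattern
frequencies.

### Selection

Per probe, the null probability `p0` is the posterior frequency of
`FlatFlat-FlatFlat`. Sorting `p0` ascending and taking running means gives
the Bayesian q-value — the estimated Bayesian FDR if every probe up to that
rank is called; ties share the value at the last tied rank, and the argmax
pattern breaks exact posterior ties at the lowest pattern index
(male-major enumeration). A probe is reported when `q < 0.05`, its modal
pattern is non-null, *and* that pattern's probability exceeds `pb = 0.5`;
the last clause keeps a probe whose posterior is smeared across several
non-null patterns out of the report.

## Moderated comparison stage

The comparison stage fits the 6-cell tissue-by-sex means model per probe
and tests the male−female difference within each tissue (three contrasts,
each column summing to zero), plus the joint moderated F. Residual
variances shrink toward an empirical prior
`s2~ = (d0 s0^2 + d s2) / (d0 + d)`, with `(d0, s0^2)` estimated by
moment-matching on `log s2` (digamma/trigamma inversion by Newton
iteration to 1e-8). `d0 = 0` reproduces classical t/F exactly; `d0 = Inf`
(declared when the spread of `log s2` falls below its sampling floor) is
propagated explicitly, making the reference normal. Empty tissue-by-sex
cells are an error; singleton cells only warn — they contribute no
residual degrees of freedom but their means are still estimable, which is
exactly the emulated design's situation. With `n = 9` the moderated F has
3 and ~3+d0 degrees of freedom; under a global null, BH-adjusted
significance is a rare event — the behaviour the acceptance suite checks.

## Survival screen

Candidate genes are screened with univariate Cox models on continuous
expression (`h(t) = h0(t) exp(b1 x)`), Breslow tie handling, Wald p-values,
BH across genes. Continuous screening is the default — dichotomised
expression is offered for presentation (`dichotomize()`, Kaplan–Meier
curves via `km_estimate()`) with user-supplied thresholds per gene, not an
automatic threshold search, which would invalidate the p-values. The
reported `sign` column reads "+" as higher expression associated with
longer survival (negative log hazard ratio). Degenerate inputs (no events,
constant covariate) are flagged, and a monotone partial likelihood is
reported as non-converged rather than silently returning a huge estimate.

## What the simulators emulate — and what they don't

`simulate_methylation()` runs the mixture forward: patterns drawn from a
configurable 81-vector (default: 60% null, the rest spread over the eight
sex-discordant catalog patterns), slope magnitudes
`effect_size + U(0, jitter)` (defaults 2 + U(0, 0.5) M-units — clearly
separated trajectories, the regime the screening method targets), probe
intercepts `N(0, 1)`, noise SD 0.3, and the 9-sample mixed-sex layout.
`simulate_survival()` draws standard-normal expression, exponential event
times with hazard `0.1 exp(sum b1 x)`, and uniform censoring calibrated
numerically to the target censoring fraction (default 20%, a typical
cohort value). The generators share nothing with the fitting code beyond
the design encoding, so recovery tests are meaningful.

They do **not** emulate: beta-value heteroskedasticity or array noise
chemistry, probe cross-reactivity, batch effects, correlated probes within
CpG islands, or non-proportional hazards. Passing recovery tests therefore
demonstrates correctness of the *inference machinery* under the stated
model, not robustness to those real-data pathologies.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use 200-probe studies (five
seeds) for recovery, 500 probes for null calibration, and 3,000 sweeps
with 1,000 burn-in — a few seconds per chain, since every update is
vectorised over probes; posterior
summaries are visually stable well before that. The 30,000/10,000 default
on the fitting function is the conventional production setting for
array-scale runs. Other tie-breaks and degenerate-input rules are
documented where they occur: strict threshold inequalities, `p = 1` for
constant ANOVA rows, clipped logits, flagged singleton cells, flagged
non-converged Cox fits.

## Known limitations

Two sex strata are assumed (more are rejected with a clear error), as are
exactly three tissue levels; covariates beyond tissue and the stratifying
factor are out of scope. The q-value here is the cumulative-mean Bayesian
FDR over sorted posterior null probabilities — a posterior quantity, not a
frequentist FDR guarantee; its small-sample behaviour is characterised
empirically by the null-calibration test. Cluster-level slope sharing is a
modelling choice, not a fact about probes: probes whose true effect sizes
straddle a cluster's posterior slope are pulled toward it, which is the
price of power at `n = 9`.
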