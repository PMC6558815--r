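---
title: "Models, assumptions and design choices in meristevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, assumptions and design choices in meristevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meristevo)
```

## The scientific problem

`meristevo` tests macroevolutionary trend hypotheses on meristic traits —
countable skeletal elements such as the branchiostegal rays of bony fishes —
scored for both extant and extinct species on a time-scaled phylogeny.
Williston's law postulates a long-term reduction in the number of repeated
skeletal elements; the package frames that hypothesis as a model-comparison
problem in two complementary ways:

1. **Continuous trait models.** The count is treated as a continuous
   character evolving along the tree, and the fit of five Gaussian process
   models is compared by Akaike weights: Brownian motion (BM), a
   non-stationary fixed-root Ornstein–Uhlenbeck process (OU), early burst
   (EB), BM with a directional trend, and non-phylogenetic white noise (WN).
   A Williston-like dynamic predicts support for the trend model with a
   negative drift, or OU with an optimum below the root state.
2. **Ordered Markov models.** The count is treated as a discrete state on
   `0..S-1` with single-step gains and losses. A likelihood-ratio test
   between the one-rate symmetric model (MkS) and the two-rate asymmetric
   model (MkA) asks whether losses outpace gains.

Model *adequacy* (not just relative fit) is assessed with phylogenetic
independent contrasts and posterior-predictive simulation, and the
robustness of both support and estimates to the fossil sample is probed by
taxon jackknifing.

## Model definitions

All five continuous models are multivariate normal over the tips. With
`S_ij` the shared root-to-MRCA path length of tips `i, j` and `T_i` the
root-to-tip depth:

| model | mean | covariance | free parameters (k) |
|---|---|---|---|
| BM    | `theta0` | `sigma2 * S_ij` | `theta0, sigma2` (2) |
| TREND | `theta0 + trend * T_i` | as BM | + `trend` (3) |
| EB    | `theta0` | `sigma2 * (exp(beta*S_ij) - 1)/beta` | + `beta` (3) |
| OU    | `theta1 + (theta0-theta1) e^{-alpha T_i}` | `sigma2/(2 alpha) e^{-alpha(T_i+T_j-2S_ij)} (1 - e^{-2 alpha S_ij})` | `theta0, theta1, sigma2, alpha` (4) |
| WN    | `theta0` | `sigma2 * I` | `theta0, sigma2` (2) |

The OU variant is the *fixed-root, non-stationary* one: the root state
`theta0` is a free parameter distinct from the optimum `theta1`. This is
deliberate — it is the only variant that is well defined on non-ultrametric
trees with fossil tips, and it is the parameterization whose root state and
optimum can disagree, which is what a trend test needs. EB's `beta` is
constrained `<= 0` by default ("early burst" proper); a configuration switch
allows `beta > 0`.

### Identifiability on ultrametric trees

On a strictly ultrametric tree every `T_i` is equal, so the OU mean columns
(`e^{-alpha T}`, `1 - e^{-alpha T}`) and the TREND columns (`1`, `T`) are
collinear: the root state versus optimum distinction and the trend parameter
are *structurally unidentifiable without fossils*. `fit_ml()` detects this
case, collapses to the identified common level (OU reports
`theta0 = theta1`; TREND warns and reports `trend = NA`), and the parameter
recovery tests therefore use fossil-bearing trees. This is the statistical
restatement of the package's premise: paleontological data are what make
trend parameters estimable at all.

## Fitting strategy

The likelihood of every model factorizes as `Cov = sigma2 * V0(shape)` with
at most one nonlinear shape parameter (`alpha` or `beta`). `fit_ml()`
therefore profiles the location parameters (`theta0`, `theta1`, `trend`) by
generalized least squares through a Cholesky factorization of `V0`, profiles
`sigma2` in closed form (ML, divisor `n`), and searches only the shape
parameter numerically: a log-spaced grid of candidates (default 12) followed
by 1-D golden-section refinement in the best bracket, tolerance `1e-8`. BM,
TREND and WN are exactly closed form. This replaces multi-start box
optimization with an exact profile and is why fits are deterministic and
fast. Bounds default to `beta * height` in `[-10, 0]` and
`alpha * height <= 500`, scaled by tree height so the same numbers apply on
unit-height and My-scale trees.

Degenerate inputs: constant traits return `sigma2` at the floor `1e-10` with
a warning rather than an error; 2-tip trees are allowed for BM and WN only.
Covariance factorizations get a single `1e-10` relative diagonal jitter
before failing with condition diagnostics.

Akaike weights are computed in log space
(`w = exp(-delta/2 - logsumexp(-delta/2))`) so that AIC gaps of several
hundred units give tiny but nonzero weights instead of underflowing.

## Ordered Markov machinery

The rate matrix is tridiagonal (`q_gain` above the diagonal, `q_loss`
below). The pruning likelihood decomposes `Q` once per evaluation
(birth–death chains have real spectra) and builds each branch's transition
matrix from the cached eigensystem, renormalizing rows against round-off;
partial likelihoods are rescaled whenever they drift below `1e-6`, with the
log factors accumulated. The state count `S` defaults to the maximum
observed discretized state plus one and is recorded in every fit, because
the uniform root prior makes the likelihood depend on `S`. Root priors:
uniform (default, matching the convention of standard Mk fitting functions),
equilibrium, or user supplied.

The symmetric fit is a 1-D optimization in log-rate space; the asymmetric
fit runs L-BFGS-B from three starts including a warm start at the symmetric
optimum, with non-finite objective values penalized rather than thrown, and
the symmetric optimum is always admitted as a candidate so the nesting
inequality `lnL_asym >= lnL_sym` holds by construction.

The simulator is a Gillespie walk along branches (exact event sampling, not
endpoint draws), so event counts are inspectable and boundary states reflect
naturally — only the feasible move is available at `0` and `S-1`.

## Time-scaling and tip-age resampling

`timescale_mbl()` implements minimum-branch-length stratigraphic
time-scaling as a single post-order sweep: every internal node keeps its
input (clock-derived) age unless a descendant's age plus the floor forces a
rootward shift, in which case the node moves by the minimal amount and the
constraint cascades toward the root. Nodes never move tipward, so clock ages
are preserved exactly wherever possible. Fossil tip ages are resampled
uniformly on `[LAD, FAD]` — the least-informative choice on a stratigraphic
interval — and each resampled tree is re-scaled with the same floor
(default 1 My). "Present" is anchored at the deepest tip, so extant tips
have age exactly 0.

## Contrast-based adequacy

If the fitted model is true, independent contrasts computed on the
model-rescaled tree (`unit_tree()`: BM branches times `sigma2`, EB branch
over depths `[t1, t2]` gets `sigma2 (e^{beta t2} - e^{beta t1})/beta`) are
iid standard normal. Four statistics summarize departures: the mean squared
contrast; the coefficient of variation of absolute contrasts (rate
heterogeneity); the OLS slope of `|contrast|` on the nodal ancestral value
(state-dependent rates; raw scale by default with a square-root-transform
switch); and the Kolmogorov–Smirnov distance of the contrasts from
`Normal(0, sqrt(mean squared contrast))`, evaluated on both sides of every
ECDF step. Monte-Carlo p-values are two-tailed with the `+1` correction and
record which tail was extreme, since one-sided readings are common in
applied reports. Zero-length cherry denominators are floored at `1e-12`
with a warning.

## The synthetic world

The generator's defaults state the analysed empirical design: a birth–death
tree conditioned on 440 surviving species (birth 0.05/My, death 0.025/My —
a turnover giving a root age of a few hundred My, commensurate with a
Paleozoic origin), exactly 66 extinct lineages retained as fossil tips, a
10 My stratigraphic window bracketing each fossil's true age, and counts
generated under EB with the published unit-height-scale estimates
(`theta0 = 5.8`, `sigma2 = 4708.2`, `beta = -5.04`). Continuous values are
rounded half-up and floored at 0 to make counts; 25% of species get a
reported polymorphic range of half-width 1–2 (the literature reports most
documented intraspecific ranges within about one element); the pre-rounding
values and generating parameters are kept in a truth attribute for recovery
tests.

What the generator does *not* emulate — and what a green test therefore does
not establish:

- **Discreteness interacts with the late-EB regime.** Under a strong burst
  the late-time rate is tiny, so integer rounding acts like added white
  noise that can dominate shallow divergences. On desk-scale trees this
  visibly attenuates `sigma2` and `beta` estimated from counts relative to
  the generating values; at the 506-tip scale EB selection is still
  overwhelming.
- **No rate jumps.** The empirical data contain a few contrast outliers
  suggesting jump-like divergence, which is precisely what made the
  published adequacy tests reject EB. Data simulated from a pure EB process
  are, by construction, adequate for EB; the package's adequacy tests are
  validated by calibration (uniform p-values under the true model), not by
  reproducing the published rejections.
- **Low-fossil model support.** On the empirical data EB support was
  overwhelming with as few as 7 retained fossils. On the synthetic stand-in,
  EB support decays once fewer than about 20–26 fossils remain, because with
  few fossils the tree is nearly ultrametric and rounding noise masks the
  late-EB signature. The jackknife acceptance test asserts the stability
  claims the stated world actually supports (support ordering stable through
  19 removals; overwhelming support with at least 26 fossils retained) and
  documents the rest as a property of the empirical data that cannot be
  checked without it.

## Numerical and design choices

- `sigma2` uses the pure-ML divisor `n`; this is the variant consistent with
  the published white-noise row (`2k - 2 lnL` reproduces the printed AIC).
- "Nearest upper integer" for discretizing mean counts is read as ceiling.
- A reported minimum with unknown maximum is treated as a hard minimum:
  soft range `(m, m + 1)`. Point counts without polymorphism data get
  `(max(0, c-1), c+1)`.
- Polytomies are resolved to zero-length binary splits in input order; the
  Gaussian likelihoods are invariant to the arbitrary resolution, and
  zero-length contrast denominators are floored.
- All randomness flows from one run seed through a documented integer
  splitting scheme (`child_seed()`, kept below 2^31). Replicated draws
  inside one operation come from a single seeded stream rather than
  per-replicate reseeding, which measurably improves calibration.
- Ensemble summaries compute Akaike weights from mean AICs across trees
  (reproducing table-style weights computed from printed mean AICs);
  per-tree weights are also stored.
- Run configuration is a JSON file with documented keys (no YAML parser is
  assumed available); every command writes a manifest with input hashes,
  seed and package version, and reruns are byte-identical.
- Jackknife removal counts are a rounded linear ramp `cap/steps .. cap`; the
  fossil cap defaults to the whole fossil pool and the extant cap to 15% of
  the extant pool, mirroring the published design. The published figure's
  labelled sizes are not perfectly consistent with any single rounding rule,
  so the ramp, cap and rounding are configurable.

## Known limitations

Single-regime OU only (the multi-optimum extension is out of scope, and the
single-regime fit is acknowledged to be biologically coarse); no measurement
error term beyond what soft ranges express; adequacy battery limited to the
four statistics above; MBL is the only time-scaling method (no stochastic
cal3-style variants); OU and WN fits are excluded from GLS ancestral-state
reconstruction by design. Finite-sample ML bias of `alpha` and `beta` is
real and tree-dependent: on fossil-poor or shallow-fossil trees the EB
`sigma2` can be attenuated by 15–25% at a few hundred tips, which is worth
remembering before interpreting parameter magnitudes — the jackknife
facility exists precisely to make that instability visible.
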