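---
title: "Radiobiological model, synthetic cohorts and analytic methods in bedfx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiobiological model, synthetic cohorts and analytic methods in bedfx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bedfx)
```

## The dose-protraction model

A Gamma Knife session delivers its dose through `n` sequentially visited
isocentres over a total session time `T` (minutes to an hour), with a mean
beam-on time `t` per isocentre. Sublethal damage is repaired during
delivery, so the quadratic (damage-interaction) term of the
linear-quadratic model must be attenuated by an incomplete-repair factor

$$f(\mu T) = \frac{2}{\mu T}\left(1 - \frac{1 - e^{-\mu T}}{\mu T}\right),$$

the normalised double integral of $e^{-\mu|u-v|}$ over the exposure
window. Repair is biexponential: a fast compartment (rate $\mu_1 =
\ln 2 / T_{1/2,\mathrm{fast}}$, weight $x$) and a slow one ($\mu_2$, weight
$1-x$). The session BED used throughout the package is

$$\mathrm{BED} = x\,nd\left[1 + \tfrac{nd-d}{k} f(\mu_1 T) +
\tfrac{d}{k} f(\mu_1 t)\right] + (1-x)\,nd\left[1 + \tfrac{nd-d}{k}
f(\mu_2 T) + \tfrac{d}{k} f(\mu_2 t)\right]$$

with $k = \alpha/\beta$ and $d = D/n$. The reading of the two bracketed
interaction terms is the only one consistent with sequential isocentre
delivery: damage deposited at *different* isocentres interacts across the
session duration $T$, damage within one isocentre across its own beam-on
time $t$. It also makes the acute limit exact: as $T, t \to 0$ all $f \to
1$ and the expression reduces to $D(1 + D/k)$, which the test suite asserts
to $10^{-9}$ relative for all four pathology parameter sets.

Assumptions worth keeping in mind:

* dose is split equally across isocentres and across fractions of a course;
* fractions are separated by ~24 h, long against both repair half-times,
  so course BED is the plain sum of session BEDs (*complete inter-fraction
  repair*);
* no cobalt-decay dose-rate drift, no voxel-level spatial structure: the
  session is summarised by $(D, n, T, t)$.

### Inter-fraction carry-over (sensitivity variant)

`bed_course_with_carryover()` relaxes the complete-repair assumption. The
rule is the simplest Lea-Catcheside-style extension: each ordered fraction
pair $(i, j)$ contributes $c^{\,j-i} \cdot 2 D_i D_j / k$, i.e. the usual
quadratic cross term attenuated geometrically with lag, split between the
fast and slow compartments with the same weights $x$ and $1-x$ as the
intra-fraction terms. At $c = 0$ it reproduces `bed_course()` exactly and
it is strictly increasing in $c$; for a 3 x 8 Gy reference course a 5%
carry-over adds a few percent of the base BED. The exact bookkeeping
behind any particular published carry-over percentage is not fixed by the
model itself, so this rule is a documented package choice and is tested by
its properties (identity at zero, monotonicity, magnitude), not against
external numbers.

### Units and numerics

Interfaces take times in minutes (the scale of treatment records) and
convert to hours before applying repair rates, which are in h^-1. For
$\mu T < 10^{-4}$ the factor $f$ is evaluated by its Taylor expansion
$1 - \mu T/3 + (\mu T)^2/12$; the closed form loses all significant digits
there through cancellation. Closed-form identities in the tests are held
to $10^{-9}$ relative, comparisons against the independent double-integral
oracle to $10^{-6}$.

## Pathology parameter sets

| set | alpha/beta (Gy) | T½ fast (h) | T½ slow (h) | x fast |
|-----|-----------------|-------------|-------------|--------|
| AVM | 2.47 | 0.19 | 2.16 | 1/1.98 ≈ 0.505 |
| VS  | 3.0  | 1.5  | 12   | 0.5 |
| BM  | 10   | 0.25 | 6    | 0.9 |
| MEN | 3.5  | 0.5  | 4    | 0.8 |

Low alpha/beta plus fast repair (AVM) makes BED highly sensitive to the
time structure; slow repair against short sessions (VS) compresses the BED
range; high alpha/beta (BM) makes BED behave almost like physical dose.
The sets live in `inst/extdata/pathologies.yaml` and can be overridden by
a user registry file.

## What the cohort generators emulate

`simulate_cohort()` draws, per patient: a fractionation scheme (AVM
1/3/5 fractions equiprobable; VS 70/30 for 1/3; BM 70/25/5; MEN 50/35/15),
a per-fraction prescription dose uniform over the scheme's clinical range,
a lesion volume uniform over the pathology's range, an isocentre count
linear in volume with Gaussian noise (rounded, clipped to the stated
range), and per-fraction beam-on and overhead times uniform over their
ranges. Uniform sampling is the minimal assumption — only the volume
distribution is explicitly uniform by construction; everything else is a
range without a stated shape. The isocentre-volume line maps the volume
minimum to the isocentre minimum and, for AVM, the mean volume (8 cc) to
the typical AVM isocentre count of ~12 per fraction; the other pathologies
map the volume midpoint to the isocentre-range midpoint. Non-predictive
covariates (age, sex, location, prior surgery) are generated only where
the pathology's description lists them; VS carries volume only.

Outcomes follow pathology-specific logistic models in BED and volume
(plus prior radiotherapy for AVM):

* AVM obliteration: $\mathrm{logit}\,p = 0.06(\mathrm{BED} - 160) -
  0.05(V - 5) - 0.5\,\mathrm{RT}$;
* VS control: $1.386 + 0.35(\mathrm{BED} - 58) - 0.10(V - 4)$;
* BM control: $1.5 + 0.07(\mathrm{BED} - 65) - 0.15(V - 2)$;
* MEN control: $-0.5 + 0.08(\mathrm{BED} - 70) - 0.04(V - 5)$.

The AVM reference volume (5 cc) matches the planning module's virtual
patient. Binary outcomes are Bernoulli draws; every patient has an
independent RNG substream derived from the root seed, so cohorts are
bit-for-bit reproducible and the first `n` records do not change when a
cohort is enlarged.

What the generators do **not** emulate: real prescription selection
(doses are independent of volume given the scheme), histology
heterogeneity, imaging ambiguity, censoring or competing risks, and any
correlation between geometry and outcome beyond what BED mediates. A
model that looks well-calibrated here has only been shown to recover a
known logistic law from plans with realistic time structure — not to
predict clinical outcomes. Two known tensions with published summaries are
deliberate consequences of following the printed coefficient values: the
MEN generator's overall control rate is well below the headline figure
usually quoted for meningioma series, and in the BM generator the BED
term contributes slightly more outcome variance than volume.

## Analytic layer

**Feature families.** Family A is clinical covariates plus physical
dose/time descriptors and contains no BED-derived column; family B swaps
the dose block for BED features (total BED, mean per-fraction BED and,
for AVM, indicators for crossing 133 and 180 Gy_2.47); family C is the
union. Categoricals are one-hot encoded.

**Models and evaluation.** The gradient-boosted classifier is fixed at
200 trees, depth 3, learning rate 0.05, row and column subsampling 0.8;
logistic regression and random forest are library defaults. Evaluation
uses a stratified 75/25 split, rank-statistic (Mann-Whitney, tie-averaged)
AUC and the Brier score, percentile bootstrap intervals from 200 resamples
of the held-out pairs (single-class resamples are redrawn, capped at 1000
attempts), equal-width calibration bins (default 10; empty bins are
flagged, never interpolated) and stratified 5-fold cross-validation.
Shapley attributions come from TreeSHAP on a full-cohort refit and are
summarised as mean |SHAP| per feature.

**Alpha/beta recovery.** The posterior of $(\alpha/\beta, \beta_0,
\beta_1)$ under $\mathrm{logit}\,p_i = \beta_0 + \beta_1
\mathrm{BED}_i(\alpha/\beta)$ with $\alpha/\beta \sim U(0.5, 10)$ and
$\beta_{0,1} \sim N(0, 2)$ is sampled after precomputing BED on a
60-point log-spaced alpha/beta grid and interpolating with monotone cubic
Hermite polynomials (Fritsch-Butland slopes, shared grid, vectorised
across patients; interpolation error is below $10^{-3}$ relative
everywhere, tested). The sampler is an adaptive random-walk Metropolis:
chains start from a dispersed alpha/beta with slope/intercept initialised
by a logistic fit at that value, the joint proposal covariance and scale
adapt during warm-up and are then frozen, and alpha/beta proposals reflect
at the prior bounds. Convergence is declared at split-chain R-hat < 1.01
and alpha/beta ESS > 400; anything else is flagged in the returned object,
never silently accepted. The contract is the posterior, not the sampler
brand — a gradient-based sampler would target the identical distribution.

Two structural facts shape what recovery can show. First, the model is an
exact reparameterisation of a two-predictor logistic regression, because
$\mathrm{BED}(k) = A + B/k$ per patient: the information about $k$ is the
information about the ratio of two GLM coefficients, and with ~1000
patients under the AVM design that ratio carries a standard error near 1
Gy. Credible intervals therefore cover the generating 2.47 Gy reliably
(tested by repeat simulation), while the posterior mean moves by several
tenths of a Gy between data realisations. Second, when the outcome-BED
link is destroyed the alpha/beta marginal is *not* exactly the uniform
prior while $\beta_1$ remains free: integrating $\beta_1$ out leaves a
factor proportional to the width of its likelihood, which grows with
alpha/beta as the BED spread shrinks. The no-signal checks therefore
assert that the slope posterior concentrates at zero and alpha/beta stays
diffuse, and that the marginal is exactly uniform when $\beta_1$ is fixed
at zero. The recovery experiment's generating coefficients are $\beta_0 =
-5$, $\beta_1 = 0.05$, fixed once so the event rate falls in the 20-50%
band.

**Neural surrogate.** A two-hidden-layer (64, 64) ReLU perceptron trained
with mini-batch Adam (batch 200, learning rate $10^{-3}$, MSE loss, 500
epochs, no early stopping) maps 7 course descriptors to the engine BED on
an 80/20 split. Inputs *and* targets are z-scored with training
statistics (predictions are returned in Gy): with ~100 Gy targets and
Adam's per-parameter step of order the learning rate, an unscaled output
bias cannot traverse the target range within the fixed epoch budget.
Training courses are drawn at 5000 per run with 1/3/5 fractions, the AVM
dose ranges, a clipped-Poisson isocentre count (4-30, mean ~12) and 5-15
min overheads; AVM kinetics only — the surrogate is not a cross-pathology
emulator.

**Planning curves.** The planning surrogate is deliberately a standardized
3-feature logistic regression (total BED, volume, prior RT): its
predictions are strictly monotone in BED, so curves swept over continuous
dose grids cannot oscillate the way tree ensembles do. It is evaluated on
a stratified 75/25 split, then refit on the full cohort for curve
generation. Under detected separation (non-converged or diverging
coefficients) a small-ridge IRLS ($\lambda = 10^{-2}$ on the standardized
scale) replaces the fit. The virtual grid is 30 uniformly spaced total
doses per scheme (1 fx 18-24 Gy, 3 fx 27-33 Gy, 5 fx 30-40 Gy) with fixed
geometry (7 isocentres, 2.5 min each, 8 min overhead) for a 5 cc virtual
patient without prior radiotherapy. Because the surrogate sees dose only
through BED, the three scheme curves coincide on the BED axis; the
dose-axis ordering 1 fx > 3 fx > 5 fx at matched total dose follows from
the monotone BED ordering and is asserted over the overlapping dose
ranges.

## Problem sizes and seeds

Default experiment sizes are the study conditions themselves: 300 AVM,
200 VS, 250 BM, 250 MEN patients; 1000 patients for alpha/beta recovery;
5000 courses for the surrogate. The test suite repeats stochastic checks
over small fixed seed batteries (3-12 replicates) and shrinks only
auxiliary experiments (e.g. the repeat-simulation coverage check runs at
n = 300 with shorter chains), sizes chosen so the whole suite completes in
a few minutes while keeping each check's sampling error well inside its
assertion tolerance. All randomness flows from explicit seeds: cohorts use
per-patient substreams, chains per-chain substreams, and `run_all()`
derives every stage's seed from one root.

## Known limitations

* Session geometry is collapsed to $(D, n, T, t)$; no voxel-level BED, no
  organ-at-risk constraints, no cobalt-60 decay.
* Long-interval staged treatments (weeks apart, with interim volume
  change) are out of scope; the carry-over variant models short lags only.
* The alpha/beta posterior's width is a property of the design, not the
  sampler; pinning the ratio tighter needs either more patients or
  schedules engineered to decorrelate the linear and quadratic dose terms.
* Synthetic cohorts validate method behaviour under a known law; nothing
  here is clinical evidence.
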