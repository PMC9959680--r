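---
title: "Methods: low-data QSAR for pyrrole antioxidants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: low-data QSAR for pyrrole antioxidants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyrroqsar)
```

## The modelling problem

A congeneric series of pyrrole antioxidants — one scaffold, varied
substituents — is characterized by 33 molecular descriptors per compound:
X1–X23 from quantum-chemical calculations (bond lengths in Å, atomic
charges, HOMO energy and polarizability in a.u.) and X24–X33 from
cheminformatic software (AlogP, Connolly surface area in Å², and so on).
Three radical-scavenging activities are measured per compound and stored
on the (percent scavenging)/10 scale, so all activities live in [0, 10]:
Y1 for the hydroxyl radical, Y2 for superoxide, Y3 for DPPH•.

With ~15 compounds and 33 candidate descriptors the central statistical
danger is selection-induced overfitting: almost any 3 of 33 columns can
correlate with 12 training responses by chance. The package therefore
pairs every fitted model with the diagnostics that expose this (R²CV via
leave-one-out PRESS, the significance-of-regression F against its
critical value) and uses Bayesian regularization rather than a validation
split for the network, since no data can be spared.

## Kennard–Stone splitting

`ks_split()` selects the *training* set by the maximin rule — seed with
the globally most distant pair, then repeatedly add the compound whose
minimum Euclidean distance to the selected set is largest — and leaves
the remainder as the test set. Selecting the training side is the
standard use of the algorithm: it guarantees the training set covers the
descriptor space so the model interpolates rather than extrapolates to
the test compounds.

Distances are computed on the autoscaled (zero-mean, unit-variance) full
descriptor matrix. Without autoscaling, surface areas (hundreds of Å²)
would dominate bond lengths (~1.5 Å) by four orders of magnitude and the
split would effectively use one descriptor. Ties in both the seed pair
and later picks are broken by lowest row index, making the split fully
deterministic; permuting the input rows permutes only the labels.
Training size is `round(fraction * n)` with half-way ties resolved
upward; a test set of one compound is allowed with a warning, an empty
one is an error.

## GA-MLR descriptor selection

`ga_select()` implements a GFA-style genetic search without spline terms,
so every candidate model is an ordinary least-squares regression on a
fixed-size descriptor subset. Defaults mirror common practice for series
of this size: equation length exactly 3 (all three published-style
equations have three terms), population 1000, at most 500 generations,
mutation probability 0.1, fitness = training R².

Choices the fitness criterion leaves open were fixed as follows:
tournament selection of size 2 (robust at large population sizes, no
fitness-scaling parameters), elitism of 10 individuals (makes best
fitness non-decreasing, which the tests assert), uniform crossover over
the union of the parents' descriptor sets (closed by construction — no
repair step can produce duplicate ids), and early stopping after 50
stagnant generations. Fitness values are memoized per descriptor set:
the landscape is static, so the search cost is bounded by the number of
*distinct* subsets visited, and on pools with a few thousand subsets the
GA typically evaluates most of the good ones. `exhaustive_best()`
enumerates every subset (capped at 1e5) and is the oracle the GA is
tested against. Singular fits score fitness 0 with a warning rather than
aborting a generation.

All randomness flows from `ga_config(seed = )`; a fixed seed reproduces
the whole `ga_result` bit for bit.

## Regression diagnostics

For observed `y`, fitted `ŷ`, `n` observations and `p` parameters
including the intercept:

* RSS = Σ(ŷᵢ−yᵢ)², TSS = Σ(yᵢ−ȳ)², ESS = Σ(ŷᵢ−ȳ)²; for OLS with
  intercept TSS = ESS + RSS (asserted at 1e-9 relative everywhere).
  Throughout the package ESS is the *explained* sum of squares and RSS
  the *residual* one; the F statistic is the explained-to-residual
  mean-square ratio (ESS/(p−1))/(RSS/(n−p)), compared against the upper
  5% quantile of F(p−1, n−p).
* PRESS refits the model n times, each time omitting one observation and
  predicting it; R²CV = 1 − PRESS/TSS. The hat-matrix closed form
  Σ(eᵢ/(1−hᵢᵢ))² is used as an independent check in the tests, not as
  the implementation, so the two routes validate each other. PRESS ≥ RSS
  always holds for OLS (leverages in [0,1)).
* RMSE uses divisor n (not n−p), matching its use as a plain prediction-
  error summary on both training and test sets.
* A perfect fit makes F infinite; this is reported as `Inf` with a
  warning rather than an error, since exactly representable targets occur
  in tests. Zero-variance columns make Pearson correlations undefined;
  `pearson_matrix()` returns `NA` there with a warning naming the column,
  never a silent 0.

## The Bayesian-regularized 3-3-1 network

`ann_fit()` trains a multilayer perceptron with three inputs (the
descriptors selected for that activity), three tanh hidden units, and one
linear output — 16 weights in all. Inputs and target are affinely mapped
to [−1, 1] (min–max, stored and inverted on prediction); initial weights
are uniform in ±0.5 from the seeded generator.

Training minimizes the regularized objective F = β·E_D + α·E_W with
E_D = ½Σr² (scaled-space residuals) and E_W = ½Σw². Levenberg–Marquardt
proposes Δw = −(βJᵀJ + (μ+α)I)⁻¹(βJᵀr + αw); a proposal is accepted only
if F decreases, otherwise μ is raised ×10 (to a cap of 1e10, treated as
convergence); acceptance lowers μ ×0.1. μ starts at 1e-3. Training stops
at 1000 epochs or when the largest gradient component falls below 1e-7.

After every accepted step the evidence-framework (MacKay) updates run:
γ = N_w − α·tr(H⁻¹) with H = βJᵀJ + αI, then α = γ/(2E_W),
β = (n−γ)/(2E_D). Two stabilizations matter in the 12-observation regime
where N_w = 16 exceeds n:

* γ is clamped to [0, min(N_w, n)] — the data cannot constrain more
  parameters than there are observations;
* the β numerator is floored at one residual degree of freedom,
  max(n−γ, 1). Without this, the very first update (α starts at 0, so
  γ = N_w > n) drives β to ~0, the weight penalty crushes the network to
  zero before it has fit anything, and training is trapped there.

Even stabilized, the regularized objective is multi-modal on 12-point
sets: some initializations end at a shrunk near-zero fit, others at the
good signal-tracking optimum. The package treats restarts as part of the
method — fit a handful of seeds and keep the best training R², as
`reference_refit(ann = TRUE)` does. On pure-noise targets all basins are
shrunk ones, which is precisely the desired behavior (γ ends far below
N_w/2; the tests assert this), so best-of-restarts does not reintroduce
overfitting. A related bias is visible at strongly saturating targets:
large hidden weights are expensive under the α·E_W prior, so in that
regime the regularized optimum accepts training error somewhat above the
noise floor. The noise-floor test therefore runs at the generator's
default moderate gain.

The analytic Jacobian is verified against central finite differences at
1e-6 relative; an undamped (μ = 0, α = 0) LM step solves weight-linear
problems exactly in one step, which the tests check against the OLS
solution.

## Design screening

`screen_candidates()` predicts Y1–Y3 for candidate descriptor rows with
the three linear models (by default the reference pyrrole equations, with
their printed coefficients) and optionally the three trained networks.
Pass rules are strict inequalities on the percent/10 scale: the radical
pair rule Y1 > 8.0 AND Y2 > 8.0, and the DPPH rule Y3 > 7.0 ("more than
80%/70%" reads as strictly greater; a prediction exactly at the threshold
fails). Flags are pure functions of (predictions, thresholds), so they
are exactly recomputable, and raising a threshold can never increase a
count. Candidate descriptor values must be supplied — the package
computes no descriptors itself.

## The synthetic generator

`generate_descriptors()` draws latent standard-normal blocks with a
shared within-block factor (exact latent correlation
`block_correlation`), truncates at ±3σ, and maps each column affinely
from [−3, 3] onto its physical range. Truncation guarantees every value
lies inside the declared range (a construction invariant the tests rely
on) at the cost of slightly compressed tails; correlations survive the
affine map essentially unchanged. Generic default ranges are physical:
bond lengths 1.30–1.60 Å, HOMO energy −0.40 to −0.25 a.u.,
polarizability 80–250 a.u., AlogP −1 to 6, Connolly surface area
250–600 Å².

`synthetic_qsar_dataset()` — the canonical 15 × 33 fixture — instead uses
*congeneric-series* ranges: within one scaffold the labile bonds vary by
only ~0.02–0.03 Å. This is not a cosmetic choice. The reference equation
coefficients (e.g. −90.879 per Å of X17) were fit on such a series;
applied across the full generic 1.30–1.60 Å range they would swing
activities by ±14 units, far outside the [0, 10] scale. The narrow
ranges were set analytically from the coefficients so that each planted
activity has mean ≈ 5–7.7 and signal sd ≈ 0.4–0.6, inside the observed
activity span; noise sds (0.18/0.17/0.23 for Y1/Y2/Y3) were then chosen
as signal_sd × sqrt(0.15/0.85) for a population R² of 0.85, matching the
regime the diagnostics are meant to operate in.

`plant_linear_activity()` adds Gaussian noise to a linear model and clips
to [0, 10] with a warning (clipping, not resampling, keeps the noise
model honest — and the calibrated defaults essentially never clip).
`plant_nonlinear_activity()` uses a fixed documented saturating form,
y = c + a·Σₖ tanh(g·zₖ) over standardized planted columns, so the
achievable R² ceiling is computable in closed form for tests. The noise
stream is seeded at `spec$seed + 1` by default, keeping it independent of
the descriptor draws; planting several activities on one table uses
distinct noise seeds.

What the generator does *not* emulate: real quantum-descriptor
distributions are neither normal nor independent across physics (bond
lengths, charges and orbital energies co-vary through the electronic
structure); measured activities have assay error structure, not i.i.d.
Gaussian noise; and the real descriptor–activity map is not exactly
linear or exactly a tanh sum. Passing tests therefore demonstrate the
*machinery* — selection, diagnostics, regularization, recovery — under
the assumed statistical structure, not predictive validity on new
chemistry.

## Problem sizes and tolerances in the test suite

The suite runs in well under a minute: identity checks on fits up to
n = 40; GA-vs-exhaustive agreement over 20 seeded replicates of 30 × 8
instances (C(8,3) = 56 subsets); maximin verification on 20-point
instances; pipeline recovery over 20 seeds of 60 × 12 instances; network
checks on 10–100-point sets; one study-default GA run on the 15 × 33
fixture. Identities are asserted at 1e-9 relative, cross-route oracle
agreement at 1e-8, Jacobian agreement at 1e-6. The refit of the
reference descriptor subsets on the *measured* series requires that
series' descriptor/activity tables, which are not redistributable with
the package; `reference_refit()` runs on any such table placed under
`inst/extdata/appendixA/`.

## Known limitations

* Exact reproduction of a published train/test split is not guaranteed:
  whether the original split autoscaled, and over which columns, is not
  stated in the sources that define the algorithm's use; this package
  fixes both (autoscaled, all columns) and documents the choice.
* The GA is compared to exhaustive enumeration at the level of the
  selected subset; search-trajectory equivalence with closed-source GFA
  implementations is out of scope.
* Network training on ~12 observations is multi-modal; results are
  reported per seed, and best-of-restarts is the supported idiom.
* Descriptor computation (quantum chemistry, surface areas, logP) is out
  of scope; the package consumes descriptor tables.
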