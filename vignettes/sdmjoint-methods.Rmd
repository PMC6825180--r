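---
title: "Methods: joint and single-species distribution models for presence-background data"
author: "sdmjoint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint and single-species distribution models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdmjoint)
```

## Scope

`sdmjoint` compares two ways of modelling where a species can occur from
presence-only records and environmental rasters:

* a **single-species presence-background SDM** in the maximum-entropy
  family (linear/quadratic/hinge/product/threshold features, L1
  penalty), and
* a **multivariate probit joint species distribution model (JSDM)** in
  which the focal species and a set of interactor species are modelled
  jointly, so that co-occurrence can be split into an *environmental*
  part (similar habitat response) and a *residual* part (association
  left over after the environment is accounted for).

The package also contains the occurrence-preparation stages these
models need (deduplication, spatial thinning, home-range buffering,
background sampling, design extraction), probability-of-occurrence
mapping, threshold/AUC evaluation at several map resolutions, and a
synthetic-landscape generator that provides ground-truth data for
testing every stage.

## The joint model

Let $y_{ij} \in \{0,1\}$ indicate species $j$ at site $i$, with
predictor vector $x_i$. The multivariate probit posits a latent normal
score per species,

$$ z_i \sim \mathcal{N}(\alpha + B x_i,\; R), \qquad
   y_{ij} = \mathbf{1}[z_{ij} > 0], $$

where $R$ is a correlation matrix (the variance is not identified in a
probit and is fixed at 1). Rows of $B$ are each species' environmental
response; off-diagonals of $R$ are **residual correlations**.

Fitting is by Gibbs sampling with three blocks per sweep:

1. **Latent scores.** Each $z_{ij}$ is drawn from its full conditional,
   a univariate normal truncated to $(0,\infty)$ or $(-\infty,0]$
   according to $y_{ij}$, with mean and variance from the multivariate
   normal conditional on the other species' scores (the Albert–Chib
   augmentation). Truncated draws use direct rejection near the bulk
   and Robert's exponential rejection in the tail, so extreme
   conditional means do not degrade accuracy.
2. **Coefficients.** With $z$ and $R$ fixed and a
   $\mathcal{N}(0, \tau^2)$ prior on every intercept and slope
   ($\tau = 10$ by default, weakly informative on standardized
   predictors), $(\alpha, B)$ has a conjugate multivariate-normal full
   conditional.
3. **Residual correlation.** $R$ is updated by parameter expansion: an
   unrestricted covariance is drawn from its inverse-Wishart full
   conditional (prior $\mathrm{IW}(I_J,\, J+1)$ on the expanded
   covariance), then rescaled to correlation form, with the latent
   scores and coefficients rescaled to match. Every retained draw is
   checked to be symmetric, unit-diagonal and positive definite.

Chains are run sequentially with seeds derived from the master seed by
fixed offsets; retention is every `thin`-th sweep after burn-in, so a
fit is exactly reproducible from `(seed, chains, iter, burnin, thin)`.
The sampler core is C++ (RcppArmadillo) and draws all randomness from
R's RNG.

Two presets ship with the package: `"paper"` (5 chains of 1,000,000
iterations, burn-in 15,000, thinning 1,000 — a publication-scale run;
note the burn-in is short relative to the run length, which we preserve
as the convention rather than "correct") and `"desk"` (4 chains of
20,000, burn-in 5,000, thinning 10), which the test suite uses.
Single-species fits skip the correlation update entirely (a 1×1
correlation is degenerate), which makes the $J=1$ case the exact
textbook Albert–Chib sampler — the test suite exploits this by
comparing it against an independently coded univariate oracle with a
Kolmogorov–Smirnov test.

**Co-occurrence decomposition.** For each retained draw, the
environmental linear predictor $\eta_{ij} = \alpha_j + B_j x_i$ is
evaluated over the fitted sites (a prediction grid can be supplied
instead; the fitted-sites default is the natural choice because those
are the locations the model saw); the *environmental correlation* of a
pair is the Pearson correlation of the two site vectors, and the
*residual correlation* is $R_{jk}$ itself. Both are summarized as
posterior mean ± sd per pair — the table behind the classic
environment-vs-residual scatter (`plot()` on a fitted model).

**Convergence.** `convergence_check()` reports split-chain potential
scale reduction and an initial-positive-sequence effective sample size
for every scalar parameter, flagging anything with $\hat R$ above 1.1
by default.

## The single-species baseline

The presence-background model is an L1-penalized Bernoulli likelihood
over MaxEnt-style features — the standard penalized-likelihood
formulation of maximum-entropy SDM fitting. We deliberately do *not*
re-implement the sequential-update MaxEnt program: the model family is
identical and coordinate-descent optimization (glmnet) is deterministic
and reproducible. Consequences of that choice:

* The **regularization multiplier** maps linearly onto the L1 penalty
  weight (base rate 0.01 at multiplier 1, on glmnet's mean-likelihood
  scale). The conventional tuning grid (multipliers 0.25–6 by feature
  classes L, LQ, H, LQH, LQHP, LQHPT) is the default in `tune()`, which
  scores specifications by cross-validated predictive deviance — the
  selection criterion is pluggable since the conventional wrapper
  packages do not commit to one.
* **Percent contribution** is permutation importance: the drop in
  training gain when all features of one predictor are permuted,
  clipped at zero and normalized to sum to 100. This is stable and
  oracle-checkable, unlike the path-dependent gain accounting of the
  original algorithm, and lives on the same 0–100 scale.
* **Output** is the raw probability from the penalized logistic model;
  no post-hoc output transform is applied.
* Hinge/threshold knots sit at 10 equally spaced interior quantiles per
  predictor — enough flexibility at desk scale without exploding the
  feature count.
* `fit_replicates()` refits on seeded random subsamples (80% by
  default) and averages predictions, retaining per-replicate held-out
  AUC so results can be reported as mean ± sd over replicates (100
  replicates is the conventional count; tests use fewer).

Backward elimination follows the conventional screen: iteratively drop
the weaker member of any predictor pair with $|r| \ge 0.75$, then any
predictor contributing $\le 1\%$, until all survivors clear both rules.

## Occurrence preparation

* **Thinning** enforces a minimum pairwise great-circle distance
  (haversine on WGS84 — correct at country scale without choosing a
  projection). The retention rule is *greedy in input order*: a record
  is kept iff it is at least the radius away from every previously kept
  record. The rule had to be fixed somewhere — greedy-in-order is
  deterministic, documented, and matches common practice; a seeded
  random-order mode exists for sensitivity analysis. Thinning is
  idempotent and its output provably satisfies the distance bound. The
  3 km default is the conventional spatial-autocorrelation correction
  for dense citizen-science records; species-specific foraging-distance
  thinning uses the same semantics with the species' radius.
* **Ranges** are unions of circular home-range buffers around retained
  records; interactor species enter the joint model as range-membership
  presence/absence labels (responses only — never predictors).
* **Background points** (10,000 by default) are sampled uniformly
  *without replacement* among valid grid cells outside the focal range
  ("additional data points" are distinct locations); masked cells are
  excluded. Background sites carry focal response 0.
* **Grids** are regular lon/lat lattices indexed row-major from the
  north-west corner with half-open cell-edge intervals — fixed so map
  I/O round-trips bit-exactly. Rasters are read and written as ESRI
  ASCII grids, a plain-text single-band georeferenced format.
* The order of the fixed-radius and foraging-distance filters is not
  canonical; the pipeline applies the fixed filter first and the
  foraging filter second by default, and both are exposed separately so
  either order can be run.

## Prediction and evaluation

Maps apply the grid-wise probit formula
$\mu = \Phi(\alpha + B_1 P_1 + \dots + B_p P_p)$ per cell, by default
averaged over retained posterior draws ("average probabilities"); a
plug-in-posterior-mean mode exists and the two differ by the Jensen gap
of $\Phi$ (the draw average is larger below 0.5 and smaller above, a
property the tests assert). Grid layers are standardized with the
constants stored at fitting time. Analysis and map resolutions are
separate configuration values (conventionally 0.0004° for analysis,
0.004° for map generation); neither is hard-coded.

Evaluation uses:

* **AUC** in the rank-statistic formulation (ties count half), with
  background pseudo-absences as the negatives — there are no true
  absences in this design.
* The **maximum sensitivity + specificity threshold**, chosen among
  observed score values; ties at the threshold count as predicted
  presence ($\ge$), and objective ties resolve to the lowest qualifying
  threshold. Both conventions must be fixed for reproducible
  sensitivity numbers.
* **Sensitivity by cell size** (0.004–0.05° by default): the thresholded
  surface is aggregated to a coarser lattice, a coarse cell being
  predicted-present iff *any* constituent fine cell is (so a record
  counts as correctly located whenever any overlapping fine-scale cell
  is suitable). Under this rule sensitivity is non-decreasing in cell
  size; a mean-aggregation alternative sits behind a flag.
* **Cross-validation**: seeded random 60/40 train/validation splits
  (5 by default), refitting per split; splits that lose a response
  class are redrawn up to a retry cap.
* `compare_models()` aligns reports into the two-model-by-cell-sizes
  comparison table and refuses to compare reports whose evaluation data
  fingerprints differ. No winner is declared — that judgement is
  interpretive.

## The synthetic landscape

The generator exists so every stage can be tested against known truth:

* **Predictor fields** are white noise smoothed with a Gaussian kernel.
  The kernel sd is set to $L / (2\sqrt{\ln 2})$ so the field's
  autocorrelation falls to 0.5 exactly at the requested correlation
  length $L$ (in cells). This emulates smooth climate-like gradients;
  it is not an exact variogram model and makes no claim about any real
  landscape's covariance.
* **"Urban" layers** are additionally clipped below their 75th
  percentile and rescaled, giving right-skewed, patchy fields that are
  exactly zero over most of the extent — the dominant predictor in
  urban-invader systems is patchy, not smooth, and a smooth field would
  make the SDM's job unrealistically easy.
* **Communities** are drawn from the same multivariate probit the JSDM
  assumes, with true marginal probabilities retained. Site cells are
  sampled uniformly with replacement (sites are survey events); an
  effort-bias mode samples proportionally to a chosen layer to emulate
  reporting concentrated near anthropogenic centres — a test device for
  the thinning stage, not a claim about real sampling effort.
* **Presence-only records** are Bernoulli subsamples of true presences
  at a configurable detection rate; absences are never emitted.

Because the community generator *is* the JSDM's assumed data-generating
process, passing recovery tests shows the sampler is correct, not that
the model is right for real data: real records carry detection
covariates, spatial sampling artefacts and non-probit dependence that
the generator deliberately omits (and no temporal dynamics or abundance
are simulated).

## Numerical choices and test scales

* Degenerate inputs fail loudly before sampling: non-positive-definite
  correlation matrices, species with all-0/all-1 responses (probit
  separation), empty tuning grids, evaluation cell sizes below native
  resolution.
* Standardization constants ride along with fitted models so map
  prediction and inverse-standardization round-trip raw values to
  machine tolerance.
* Test problem sizes are chosen for a desk machine: recovery runs use
  4 species × 3 predictors × 800 sites at the desk preset (posterior
  mean of $B$ correlates with truth at $r > 0.9$; ±0.6 residual
  correlations are recovered with correct sign), coverage runs use 20
  replicates of 3 × 2 × 300 at reduced chain length, and the
  end-to-end pipeline runs on a 100×100-cell landscape at 0.004°. The
  acceptance script uses a 150×150 landscape with 13 species
  (focal + 12 interactors), ~2,400 sites after preparation, a
  25-replicate SDM and a 2-chain × 8,000-iteration JSDM, with 5-fold
  60/40 cross-validation at shorter chain length.

## Known limitations

* The residual-correlation update is the standard parameter-expanded
  inverse-Wishart rescaling; its implied prior on $R$ is the one
  induced by the expanded $\mathrm{IW}(I, J+1)$, not an explicit
  marginally-uniform prior.
* The SDM is the penalized-likelihood equivalent of maximum-entropy
  fitting, not the MaxEnt program; percent contributions are
  permutation-based and will not numerically match the original
  algorithm's gain bookkeeping.
* Great-circle geometry treats buffers as circles in distance, not
  projected polygons; at sub-degree extents the difference is
  negligible.
* No spatial random effects, latent factors, abundance responses or
  temporal dynamics — the model family is the plain multivariate
  probit.
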