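---
title: "Classifier-driven power transforms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifier-driven power transforms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boxcoxopt)
```

## The model

The Box-Cox family is a one-parameter family of monotone power transforms of
a positive variable $y$:

$$
T(y; \lambda) =
\begin{cases}
\dfrac{y^{\lambda} - 1}{\lambda}, & \lambda \neq 0,\\[4pt]
\ln y, & \lambda = 0.
\end{cases}
$$

Classically $\lambda$ is chosen by maximizing a Gaussian profile
log-likelihood, i.e. the transform is tuned so the *marginal* distribution
looks as normal as possible. The premise of this package is different: when
the transformed data feed a classifier, normality is a proxy at best. The
right target is the classifier's own performance, so `boxcoxopt` selects a
per-feature exponent vector $\Lambda = (\lambda_1, \dots, \lambda_p)$ by
minimizing the in-sample misclassification loss $L(\Lambda) = 1 -
\mathrm{ACC}(\Lambda)$ of the downstream classifier, retrained at every
candidate $\Lambda$. Because accuracy is piecewise constant in $\Lambda$,
the search is derivative-free: grid scans and coordinate descent rather than
gradient steps.

The fitted pipeline (a `bcx_model`) is a fixed sequence whose every stage is
estimated on training data only and replayed verbatim at prediction time:

1. **Range standardization** to $[1, 2]$. The transform needs strictly
   positive inputs, and mapping into $[1, 2]$ keeps $y^\lambda$ numerically
   tame across the whole exponent range $[-5, 5]$ (at $y = 2, \lambda = -5$
   the magnitude is still only $2^{-5}$). Test points that fall outside the
   training range are clipped below at $10^{-6}$ above zero so positivity is
   never violated.
2. **Power transform** with the optimized $\Lambda$, applied column-wise.
3. **Standard scaling** (zero mean, unit variance, population divisor $n$) so
   that scale-sensitive classifiers compare features fairly.
4. **Classifier training** on the transformed features.

`predict()` reuses the stored scaler states and $\Lambda$; nothing is refit.

## Search strategies

Five optimizers are provided, trading fidelity against cost on a shared
candidate grid (default: 11 points, $\{-5, -4, \dots, 5\}$):

* **`mle`** — classical column-wise maximum likelihood, ignoring the
  classifier. Included as the classical baseline and as the default start
  point for the iterative search.
* **`spherical`** — a single shared exponent $\lambda$ for all features:
  one 1-D scan, $|{\rm grid}|$ evaluations.
* **`diagonal`** — each direction scanned independently with all other
  exponents held at the neutral value $1$; the per-direction winners are
  then assembled into one vector. Cost $p \cdot |{\rm grid}|$. This is a
  deliberate heuristic: the vignette section below shows it can assemble a
  *jointly* poor vector out of individually good coordinates, which is why
  the joint searches exist.
* **`grid2d`** — exhaustive scan of the full 2-D grid (two features only),
  the gold standard the cheaper searches are compared against.
* **`iterative`** — coordinate descent over epochs: each epoch scans every
  direction in turn, updating the incumbent only on *strict* improvement
  (ties keep the earlier candidate, making results order-deterministic).
  Cost is exactly $\text{epochs} \times p \times |{\rm grid}|$ criterion
  evaluations, and the best-so-far accuracy trace is non-decreasing by
  construction.

Three escape mechanisms can be scheduled on the iterative search, each with
its own period and enable flag (`optimizer_config()`):

* **finer** (`finer_epoch`) — shrink the candidate spacing by the factor
  `finer_factor` (default $0.5$) and re-attach the grid locally as offsets
  around the current coordinate, refining resolution without leaving the
  basin.
* **shuffle** (`shuffle_epoch`) — draw a new random direction order for the
  scan; the permutation persists until the next shuffle.
* **shift** (`shift_epoch`) — restart the scan from a fresh uniform random
  point in the original grid domain. While shifting, the restart base
  carries each direction's best-found coordinate forward so the restart is
  explored coherently; any strict improvement over the incumbent ends shift
  mode. When several mechanisms trigger on the same epoch they apply in the
  order finer, shuffle, shift.

All randomness (restarts, permutations) is drawn inside
`withr::with_seed(config$seed, ...)`, so a fit is a pure function of its
inputs and seed, and never perturbs the caller's RNG stream.

Six named presets (`resolve_preset()`) bundle benchmark-tested epoch
schedules, from the plain search (4 epochs, no mechanisms) to heavier
combined settings (16 epochs, all three mechanisms, optionally a 21-point
grid).

## Classifiers

`classifier_spec()` covers five model families chosen to span decision
geometry: a linear one-vs-rest perceptron (hand-written, compiled; learning
rate 1, up to 1000 shuffled epochs, early stop on a $10^{-3}$ tolerance with
patience 5), 5-nearest-neighbours, Gaussian naive Bayes, an RBF support
vector classifier, and a small multilayer perceptron (two hidden layers of
10 ReLU units, softmax cross-entropy, full-batch Adam at learning rate 0.01
for 200 iterations, seeded He initialization). The perceptron and MLP are
implemented in the package (Rcpp/RcppArmadillo) rather than wrapped from a
heavyweight dependency, because the optimizer retrains the classifier at
every grid cell and the training loop is the hot path; the MLP's compiled
loop is roughly 20x faster than an equivalent pure-R version, which is the
difference between seconds and minutes per heatmap. KNN, naive Bayes, and
the SVC wrap `class` and `e1071`, which are battle-tested and already fast.

## Evaluation

Out-of-sample quality is measured by repeated stratified $k$-fold
cross-validation (default $k = 10$, 5 repetitions). Folds are built by a
per-class shuffle followed by round-robin assignment, so class proportions
are preserved to within one sample per fold; the shuffle seed is
`base_seed + repetition`, making every fold assignment reproducible and
shareable. Sharing matters: `grid_exploration()` evaluates an entire
$\Lambda$ grid with *identical* partitions in every cell, so the cell at
$\Lambda = (1, 1)$ — where the transform is a pure shift absorbed by
standardization — equals the untransformed baseline exactly, and
differences between cells are attributable to $\Lambda$ alone, not fold
noise. `annotate_optima()` marks the unconstrained optimum, the best shared
exponent (the grid diagonal), and the per-direction assembly on such a
heatmap, and `delta_table()` reports before/after accuracy deltas in
percent.

Within a fold, the transform uses the feature-wise range standardization
fitted on the *full* pre-scaled matrix (the grid axes must mean the same
thing in every fold), while the zero-mean/unit-variance scaler and the
classifier are fitted per training fold — the quantities that would
otherwise leak label-correlated information.

## Synthetic data

Four seeded two-feature binary generators (`make_synthetic()`) probe
different geometries:

* `gaussian_quantiles` — one isotropic Gaussian cloud split at its median
  radius, so the classes are concentric and no linear rule works;
* `half_circles` — two interleaving arcs (an upper unit semicircle and a
  lower, shifted semicircle) with optional Gaussian jitter; noise-free arcs
  are separable but not linearly so;
* `blobs` — two Gaussian blobs at uniform random centres in
  $[-10, 10]^2$ with spread 1.5;
* `random_linear` — two centroids at $\pm$`class_sep` mixed through a
  random $2 \times 2$ matrix, giving anisotropic, linearly separable-ish
  clouds.

These are idealizations: two features, balanced classes, homoscedastic
noise, no outliers, no missing data. They are good at isolating the effect
of the exponent on decision geometry, and bad at representing tabular data
in the wild — which is why `load_tabular()` exists, with strict validation
(numeric features, no missing values) and a chi-square feature ranking
(`chi2_rank()`) to select a feature pair from wider tables.

## Numerical choices

* **Zero branch.** $|\lambda| < 10^{-12}$ is treated as $\lambda = 0$ (the
  log branch). The transform is continuous in $\lambda$, so the switch is
  invisible at that tolerance.
* **Population variance.** Both the profile likelihood and the standard
  scaler use the $1/n$ divisor. For the likelihood this is the maximum
  likelihood estimate itself; for the scaler it matches the convention of
  the common array-programming stacks, easing cross-checks.
* **Tie-breaking.** Every search resolves ties toward the first candidate
  in scan order (ascending $\lambda_1$ outer, $\lambda_2$ inner). On the
  flat plateaus that in-sample accuracy produces, this is what makes
  results reproducible across runs and platforms.
* **MLE search.** The profile log-likelihood is prescanned on 201 points
  over $[-5, 5]$ and then polished with `stats::optimize()` in the
  bracketing interval — cheap insurance against the optimizer settling in
  the wrong local basin.
* **Degenerate columns.** Constant columns map to the midpoint $1.5$ under
  range standardization, get $\lambda = 1$ under the `mle` start policy
  (their likelihood is undefined), and scale factor 1 under standard
  scaling, so they pass through harmlessly.

## Problem sizes

Defaults (sample size 1000, grid 11, $10 \times 5$ CV) are chosen so a full
heatmap exploration with the cheapest classifiers completes in seconds and
with the most expensive in a few minutes on one core. The package's own
test suite exercises reduced sizes (e.g. $n = 300$, $5$-fold, 2
repetitions, 10 dataset seeds) for the multi-classifier comparisons; these
are the package's choices for keeping a full verification run within a
single coffee's time, not statements about the method's limits.

## Limitations

* The selection criterion is *in-sample* training accuracy. It is cheap and
  matches the pipeline's design, but it can overfit the transform on small
  samples; the cross-validated heatmap is the honest report, and the two
  can disagree.
* Accuracy is piecewise constant, so large plateaus are common and the
  reported optimum is merely the first cell of a tied region.
* The exhaustive search and heatmaps are limited to two features; beyond
  that only the spherical, diagonal, and iterative searches scale, with the
  usual caveats of coordinate descent on a non-separable objective.
* Exponents are only searched inside $[-5, 5]$; data that want a more
  extreme transform will pin at the boundary.
* The generators are two-dimensional toys; conclusions about real tabular
  data should be drawn from `load_tabular()` inputs, not from the synthetic
  families.
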