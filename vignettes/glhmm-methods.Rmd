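---
title: "Gaussian-linear hidden Markov models: model, inference and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian-linear hidden Markov models: model, inference and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glhmmr)
```

## The model and its assumptions

The GLHMM describes two simultaneously sampled multivariate series, the
independent data $X_t \in \mathbb{R}^p$ (optional) and the dependent data
$Y_t \in \mathbb{R}^q$, by a discrete latent state $s_t \in \{1,\dots,K\}$:

$$Y_t \sim N(\mu_{s_t} + X_t\,\beta_{s_t},\ \Sigma_{s_t}), \qquad
  P(s_t = k \mid s_{t-1} = l) = \theta_{l,k}, \qquad P(s_1 = k) = \pi_k,$$

with $\pi$ the start distribution of every data *segment* (a session or trial
— each segment draws its first state afresh). Two assumptions do the work:
a finite number of discrete states, and the Markov property of the chain.
Neither need be literally true of the data-generating system for the model to
be a useful, parsimonious description; the state time courses can and do show
long-range structure that the Markov prior does not penalise.

Each of $\mu$, $\beta$, $\Sigma$ can be **state-dependent**, **shared**
(global), or **pre-specified** ($\mu$ or $\beta$ fixed to zero, $\Sigma$ to
the identity), and an estimated $\Sigma$ can be full or diagonal. This gives
$3 \times 3 \times 5 = 45$ combinations; the 12 with no state-dependent
component are rejected as trivial, leaving the 33 variants that
`enumerate_valid_configs()` returns. Setting `beta_mode = "none"` recovers
the standard Gaussian HMM; `mean_mode = "none"` with `beta_mode = "state"`
is a piecewise decoding/encoding regression without intercept.

`X` and `Y` must have the same number of rows and be simultaneously sampled;
rows with missing values must be removed (jointly) before loading, and the
loaders refuse any `NA`.

## Priors and their defaults

All priors are conjugate and overridable via the `prior` argument:

* $\mu$, $\beta$: zero-mean Gaussian with variance `coef_var` (default 100)
  per entry — weakly informative on the standardised scales the model is
  typically used at. A diffuse value keeps the posterior mean close to the
  weighted least-squares estimate; shrink it for ill-posed designs.
* $\Sigma^{-1}$: Wishart with `wishart_dof` $= q$ degrees of freedom and
  scale $I/q$, so the prior mean precision is the identity. With
  `cov_shape = "diagonal"` the factors are the matching independent Gammas
  (shape $q/2$, rate $q/2$ per channel).
* $\pi$ and each row of $\theta$: Dirichlet with base concentration 1 on
  every allowed entry, plus `dirichlet_diag` (default 10) on the diagonal of
  $\theta$'s prior. `dirichlet_diag` is the temporal-regularisation dial: it
  adds prior mass to *staying* in a state, making switching harder; large
  values progressively prune states. It is measured in pseudo-counts of
  self-transitions, so its effect is relative to the segment lengths.

## Variational inference

The posterior is factorised as
$q(s)\,q(\pi)\,\prod_l q(\theta_{l\cdot})\,\prod q(\text{coefficient blocks})
\,\prod q(\text{precisions})$, with the coefficient factors further
factorised over output channels (and over the $\mu$/$\beta$ blocks when one
is shared and the other state-dependent). Each cycle alternates:

1. **E-step**: scaled forward–backward per segment on the *expected*
   log-parameters — digamma-based $E[\log \pi]$, $E[\log \theta]$ and the
   expected Gaussian log-density including the posterior-covariance
   correction terms. Scaling (rather than log-space) recursions give exact
   state probabilities and the per-segment log-normalisers reused in the free
   energy.
2. **M-step**: exact conjugate updates of the coefficient blocks (weighted
   Bayesian regressions with weights $\gamma_{\cdot k}$, cycling channels so
   full-covariance cross-channel coupling is honoured), the
   Wishart/Gamma precision factors, and the Dirichlet chain factors.

Because every update is exact coordinate ascent on one objective, the free
energy — computed as $-\sum \log Z$ from the forward pass plus the KL
divergences of all factors from their priors — never increases across
cycles; the test suite asserts this (tolerance $10^{-8}$) over all 33
variants. The trace is recorded after each E-step. After convergence
(relative free-energy change below `tol`, default $10^{-5}$, maximum
`max_cycles` 500 by default, smaller in the examples), a trailing M-step and
E-step leave the stored posterior and state time courses mutually consistent.

**Initialisation** is the one genuinely open design point: the model formulation
itself does not pin it down. We use a k-means-style assignment on `Y`
(or on the residuals of `Y ~ X` when a regression component exists),
softened to probabilities and multiplicatively perturbed; `n_inits` such
starts (default 5) each run `init_cycles` (default 10) cycles and the lowest
free energy is continued. K-means on the residual target aligns the
initial partition with whatever component is state-dependent.

**Masked transitions** (sequential, circular, forward-only, block/gate,
custom) are enforced exactly: masked entries carry zero Dirichlet prior
concentration, receive no expected counts, and are $-\infty$ in the decoder,
so they have zero posterior mass rather than merely small mass.

**Numerical choices**: symmetric-factorisation (Cholesky) checks with a
$10^{-10}$ symmetry tolerance decide covariance validity; forward recursions
shift by the row maximum before exponentiating; an all-$-\infty$ likelihood
row raises an error rather than propagating NaN; Viterbi ties break toward
the lowest state index, deterministically.

## Stochastic variational inference

For data sets with many units, `method = "svi"` updates the same posteriors
from mini-batches: a random batch of units (segments, or subjects when a
subject map exists — exposed as an option since either is defensible), an
E-step on the batch only, batch sufficient statistics rescaled by
$n_\text{units}/|\text{batch}|$, and a convex blend of old and new statistics
with step size $\rho_c = (c + \text{delay})^{-\text{forgetting\_rate}}$
(defaults delay 2, forgetting rate 0.75). Because the conjugate M-step is a
deterministic function of the accumulated statistics, a full batch with
$\rho_c \equiv 1$ (forgetting rate 0) reproduces plain variational inference
exactly — the equivalence test asserts agreement to $10^{-8}$ — and per-cycle
E-step cost scales linearly with the batch. The free energy reported during
stochastic cycles is the population-rescaled batch estimate; a final
full-data E-step produces the exact value and state time courses.

## Dual estimation

Subject-level models come from re-running the conjugate M-step on one
subject's rows with the *group* state time courses frozen (they are not
allowed to update), starting from the group posterior: one pass, since each
factor's update is the exact optimum given the frozen responsibilities. This
keeps state identities aligned across subjects — state $k$ is the same state
in every subject-level model — which is what testing and prediction need.
Following the same logic we also refresh $\pi$ and $\theta$ from the frozen
pairwise probabilities; the exact per-subject chain recipe is this package's
choice. A state never active in the subject keeps its prior-anchored group
value.

## Aggregated statistics

Fractional occupancy (FO) is the per-unit mean of the state probabilities;
FO entropy $H = -\sum_k FO_k \log FO_k$ is reported in natural log (the
field writes $\log$ without a base; nats make $H$ comparable with the free
energy). Dwell times and switching rates are computed on the Viterbi path by
default — a categorical path makes "visit" unambiguous — with visits
truncated at segment boundaries; unvisited states yield `NA` dwell times
rather than 0, so downstream tests are not biased toward short dwells. FO
for testing defaults to the probabilistic time courses (an option for the
Viterbi path exists via `dwell`/`switch` statistics), since probabilities
retain uncertainty that hard paths discard.

## Permutation testing

All tests share the design: observations (subjects, trials or sessions) in
rows of `D` (predictors) and `R` (outcomes), optional confounds `C`
residualised out of both sides (intercept always included), and a
permutation scheme deciding what may exchange with what:

* **across-subjects** — free exchange, or, with family blocks, members
  permute within a family and whole families of equal size may swap (the
  simplest exchangeability structure consistent with hierarchical family
  trees);
* **across-trials** — trials permute within their session only;
* **across-sessions** — entire sessions exchange with order kept inside,
  requiring equal trial counts per session (unequal counts are rejected);
* **across-visits** — no row permutation at all: the null is built from
  surrogate Viterbi paths that keep every visit's timing but redraw its
  state label (uniform first visit, then uniform over the $K-1$ labels
  different from the previous visit's).

Statistics are explained variance (multivariate regression test, $q$
p-values) or absolute Pearson correlations (univariate test, $p \times q$
p-values, two-sided). P-values use the add-one estimator
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_\text{perm})$, so they are
never zero and the test is exact-level. The rows of `R` are what gets
permuted (equivalent to permuting `D` under free exchange, and the cleaner
choice under blocks). Bonferroni and Benjamini–Hochberg corrections wrap
`stats::p.adjust`; cluster-based correction scores contiguous
supra-threshold runs by summed mass against the permutation distribution of
the maximum cluster mass. Tests on state time courses run the same engine
per within-trial time point with shared permutations, so cluster correction
applies directly. The across-visits observed statistic ("one state versus
the rest", "state versus state") is not fully pinned down at the
formulation level; this package uses explained variance by state indicators
for the omnibus contrast and absolute mean differences for the pairwise
ones.

Calibration is verified empirically: under null scenarios all four schemes
reject at the nominal $\alpha = 0.05$ within the 95% binomial band over 500
repetitions with 199 permutations (the acceptance suite runs exactly this).

## Prediction

Fisher scores are the gradients of a subject's data log-likelihood with
respect to the group model's point parameters (posterior means — the
variational analogue of the classical construction; using posterior
expectations is this package's documented choice), evaluated with the
subject's own forward–backward responsibilities. Probability rows are scored
in softmax coordinates and diagonal variances in log coordinates so all
gradients live in unconstrained spaces; full covariances are scored on their
unique entries (off-diagonals doubled). The linear or Gaussian kernel over
score rows (Gaussian bandwidth defaulting to the median pairwise distance)
feeds kernel ridge regression or ridge-penalised kernel logistic
classification, both with nested cross-validation: outer folds from a
group-aware plan that never splits a family across folds, inner folds (also
group-aware) selecting the penalty, and confound regressions estimated on
training folds only and applied to test folds. Held-out explained variance
is $1 - SSE/SST$ with $SST$ around the training-fold mean, so the
intercept-only baseline scores exactly 0 and any positive value means real
out-of-sample signal. Score standardisation is available but off by default:
with a precomputed kernel as the CV input, per-fold standardisation is not
expressible, and global standardisation is a (documented, negligible here)
leak. The summary-metric alternative concatenates FO, dwell times (zeros
plus a missingness indicator where unvisited), switching rate and FO
entropy.

## The synthetic scenarios — what they do and do not show

The scenario catalogue (`generate_scenario()`) mirrors the regimes the model
is used for: `gaussian_states` (unsupervised, fMRI-like), `regression_states`
(decoding, LFP/ECoG-like), `sequential_task` (trial-locked cascades,
MEG-like), `cohort_traits` (a 24-subject cohort, 8 twin pairs plus
singletons, a trait shifting state 1's mean with strength `effect`, an
independent confound), and `visits_signal` (a continuous co-recorded signal
whose level tracks the active state). Defaults are small but realistic for
desk-scale verification: segment lengths 150–250, state separations of about
2 noise standard deviations, self-transition probabilities around 0.9, and
effect sizes (0.5 for the trait, 1 for the visits signal) chosen once as
values a cohort study of this size could plausibly detect. Bundles are
bit-reproducible from `(name, seed)`, and `effect = 0` is an exact null by
construction.

What passing these tests shows: the inference is internally correct (exact
agreement with enumeration, monotone free energy), recovers planted
structure at reasonable signal-to-noise, and the testing layer holds its
nominal error rate under the generator's assumptions. What it does not
show: robustness to real-data violations — autocorrelated noise within
states, non-Gaussian tails, drift, unmodelled artefacts — nor anything
about the scientific validity of discrete states for a given modality.
Problem sizes in the tests and acceptance script (e.g. T of a few thousand,
100 enumeration seeds, 500 calibration repetitions) are the package's own
verification choices.

## Known limitations

* Forward–backward and Viterbi are pure R, sequential in time; they are
  comfortable at the tested sizes (tens of thousands of time points) but a
  compiled kernel would be the next step for channel counts or lengths an
  order of magnitude larger.
* The mean-field factorisation ignores posterior correlations between
  coefficient blocks and between coefficients and precisions; the free
  energy is therefore a strict bound except in the fully conjugate
  special cases (e.g. fixed identity covariance, where the tests verify
  exact agreement with the closed-form evidence).
* Time-delay embedding, autoregressive lag construction and PCA are left to
  the user upstream, and state spectra are out of scope.
* Only binary classification is provided; multiclass would be one-vs-rest
  composition on top of the same kernel machinery.
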