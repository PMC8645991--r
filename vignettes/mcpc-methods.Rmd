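---
title: "Combining multiple brain-connection patterns with a multi-kernel SVM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining multiple brain-connection patterns with a multi-kernel SVM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcpc)
```

## The problem

Resting-state fMRI yields, for each subject, a $T \times N$ matrix $X$ of
BOLD signals over $N$ regions of interest (ROIs). A *brain connection* (BC)
summarizes $X$ as a weighted graph over the ROIs, and connection weights are
an established feature space for classifying patient groups such as mild
cognitive impairment (MCI) versus normal controls. Different estimators
capture different statistical structure, and no single one is uniformly most
discriminative. `mcpc` implements three standard patterns and fuses them in
one classifier whose per-pattern weights are learned from the data, together
with the full evaluation protocol (nested leave-one-out cross-validation,
ROC/AUC, DeLong comparisons) and the downstream network analyses (hubs,
consensus connections).

## The three connection patterns

**Pearson correlation (PC).** For ROI series $x_i$, the edge weight is the
centered inner-product correlation

$$W_{ij} = \frac{(x_i-\bar x_i)^\top (x_j-\bar x_j)}
{\sqrt{(x_i-\bar x_i)^\top(x_i-\bar x_i)\,(x_j-\bar x_j)^\top(x_j-\bar x_j)}}.$$

The matrix is symmetric with entries in $[-1,1]$. The diagonal is set to 0
rather than 1: self-correlation carries no edge information and every
downstream computation (features, degrees) concerns off-diagonal structure.
No Fisher z-transform is applied.

**Sparse representation (SR).** A partial-correlation-like network obtained
by one lasso regression per node:

$$\min_{W}\ \sum_i \Big\|x_i - \sum_{j\neq i} W_{ij}\,x_j\Big\|^2
  + \lambda \sum_{j \neq i} |W_{ij}|,$$

solved per row by cyclic coordinate descent (soft-thresholding updates,
convergence when the objective decreases by less than $10^{-6}$ in a full
sweep, cap of 10,000 sweeps; non-convergence is an error carrying the
objective gap). The raw solution is asymmetric; for downstream feature maps
the symmetrization $(W + W^\top)/2$ is used by default, with the raw matrix
retained.

*Column scaling.* Columns are centered and z-scored (unit variance) before
fitting, and coefficients are reported on that scale. With unit-variance
columns the inner products $x_j^\top x_i$ scale with $T$, so the
conventional penalty grid $\{2^{-5},\dots,2^5\}$ spans a useful range from
essentially unpenalized to visibly sparse at typical scan lengths
($T \approx 140$). We considered scaling columns to unit $\ell_2$ norm
instead, but then $|x_j^\top x_i| \le 1$ and the exact lasso null threshold
$\lambda \ge 2\max_j |x_j^\top x_i|$ is crossed by the entire upper half of
the grid — every $\lambda \ge 2$ returns the empty network and the protocol
default $\lambda = 2^3$ becomes meaningless. Unit-variance scaling keeps the
published grid and default usable; `scale = "l2"` and `"none"` remain
available.

**Granger causality mapping (GCM).** Directed effective connectivity. For
each ordered pair $(x, y)$, a restricted autoregression of $y$ on its own
$p$ lags is compared with the unrestricted regression adding $p$ lags of
$x$:

$$F_{x \to y} = \ln \frac{\operatorname{var}(\zeta_t)}{\operatorname{var}(\eta_t)},$$

with $\zeta_t, \eta_t$ the residuals of the restricted and unrestricted
fits. Residual "variance" is computed as RSS divided by the number of
regression rows; the common factor cancels in the ratio. Nested
least-squares fits guarantee $F \ge 0$; tiny negative values from finite
precision are clipped to 0. The default lag order is $p = 1$ (configurable);
for $p = 1$ all $N(N-1)$ regressions are solved in closed form from the
lag-0/lag-1 cross-moment matrices, which is algebraically identical to the
per-pair least-squares fit.

## Feature maps and kernels

Symmetric patterns contribute the strict upper triangle in row-major order
($d = N(N-1)/2$ features); the directed GCM contributes all off-diagonal
entries in (row, column) order ($d = N(N-1)$). Features are z-scored with
training-fold statistics (raw connection weights have wildly different
scales across patterns, and a linear kernel is otherwise dominated by the
largest-variance edges). Each pattern then yields one linear Gram matrix,
divided by $\mathrm{trace}/n$ so all kernels share a common scale before
weighting — without this the learned kernel weights would be confounded
with kernel scale.

## The multi-kernel SVM

With $M$ kernels $k_m$ and weights $\beta$ on the probability simplex
($\beta_m \ge 0$, $\sum_m \beta_m = 1$), the decision function is

$$f(x) = \operatorname{sign}\Big(\sum_{i=1}^n y_i \alpha_i
  \sum_{m=1}^M \beta_m k_m(x_i^m, x^m) + b\Big),$$

where $\alpha$ solves the soft-margin SVM dual on the combined kernel
$\sum_m \beta_m k_m$ subject to $0 \le \alpha_i \le C$ and
$\sum_i \alpha_i y_i = 0$. A decision value of exactly 0 maps to $+1$
(deterministic tie rule).

Optimization follows the SimpleMKL alternating scheme:

1. solve the SVM dual at fixed $\beta$ by SMO (maximal-violating-pair
   working sets, KKT tolerance $10^{-6}$, compiled code);
2. take a reduced-gradient step on the simplex — the gradient of the dual
   optimum with respect to $\beta_m$ is $-\tfrac12 (\alpha \circ y)^\top
   K_m\, (\alpha \circ y)$ — with a golden-section line search over the
   maximal admissible step.

Iterations stop when $\beta$ changes by less than $10^{-4}$ in max-norm, the
reduced gradient vanishes, or the line search finds no improvement (cap 100
outer iterations). The line search only accepts strict decreases, so the
outer objective is monotone non-increasing; $\beta$ starts uniform at $1/M$.
With $M = 1$ the procedure is the ordinary kernel SVM and $\beta = 1$.

## Evaluation protocol

Because cohorts of this kind are small, the protocol is nested leave-one-out
cross-validation (LOOCV). For each outer fold, exactly one subject is held
out, and *everything* fitted — feature-selection filter, feature
standardization statistics, the cost $C$, and the kernel weights — is
computed from the remaining $n-1$ subjects only:

- **Feature selection.** A two-sample Welch t-test filter at
  $\alpha = 0.05$ per pattern (the evaluation of consensus connections
  presupposes per-fold selected sets; a t-test filter is the convention in
  this literature, and `none` is available). Zero-variance features are
  excluded; if the filter selects nothing, all usable features are kept so
  the kernel stays defined.
- **Cost grid.** $C \in \{2^{-5},\dots,2^5\}$, scored by an inner LOOCV on
  the training fold; ties break toward the smallest $C$ (prefer the
  simplest model).
- **Kernel weights.** For multi-kernel methods, $\beta$ is learned (not
  grid-searched). Within the inner loop, $\beta$ is learned once per
  candidate $C$ on the full training fold, and each inner fold refits only
  the SVM dual at that fixed $\beta$; the final model at the chosen $C$
  re-learns everything on the training fold. Learning $\beta$ inside every
  inner fold as well would multiply the cost roughly by the number of
  SimpleMKL iterations while changing only the inner accuracy estimate used
  to rank $C$ values; no information about the held-out subject enters
  either way.
- **SR penalty.** Fixed at the protocol default $\lambda = 2^3$ by default;
  a per-fold inner-LOOCV choice over the grid (`lam_mode = "cv"`) is
  implemented for sensitivity analysis.

Held-out decision values (not labels) are stored, confusion counts aggregate
over outer folds, and accuracy, sensitivity (patient detection; patients are
the positive class) and specificity follow the standard percentage
definitions. Metrics are kept unrounded internally and rounded only at
presentation, half away from zero (78.125 prints as 78.13), to 2 decimals
for percentages and 3 for AUC. The AUC uses the rank (Mann–Whitney)
formulation with ties counted 1/2, which equals exhaustive
positive–negative pair counting; correlated AUCs are compared with the
DeLong placement-value test (two-sided normal reference; identical score
vectors give $p = 1$ exactly, and a nonzero AUC difference with degenerate
variance estimate gives $p = 0$).

With three patterns the report covers seven methods: each single pattern,
each pair, and the full combination (the multiple-connection-pattern
combination, "MCPC").

## Network analyses

- **Group networks and hubs.** Per-group entrywise mean matrices; weighted
  degree on absolute weights without binarization (no principled threshold
  exists, and weighted degree avoids the arbitrary sparsity choice).
  Undirected degree symmetrizes first; the directed pattern reports in- and
  out-degree separately. Hubs are the top $\lceil 0.05\,N \rceil$ nodes
  ($6$ for $N = 116$); ties at the cutoff are all included and flagged, so
  a report may exceed the nominal count.
- **Consensus connections.** Edges selected in at least a threshold
  fraction of outer folds; the default threshold 1.0 is the intersection —
  the edges selected in every fold, read as the most stable discriminative
  features. Consensus degree ranks ROIs by incident consensus edges,
  descending, ties broken by ascending ROI number; directed patterns get
  separate in/out tables.
- **Annotation.** A shipped lookup maps ROI numbers 1–116 of the AAL atlas
  to region names and functional subnetwork codes (DMN, VN, FTC, SH, CTC,
  DAN, AN, SN, SBN); ROIs without a published subnetwork assignment carry
  `"unassigned"`.

## The synthetic cohort generator

Real MCI/control cohorts are access-restricted, so the package ships a
generator that emulates the *statistical situation* rather than the BOLD
physiology: each subject is an independent stationary VAR(1) realization
$x_t = A_g x_{t-1} + \varepsilon_t$, $\varepsilon_t \sim N(0, \Sigma_g)$,
with a 100-sample burn-in discarded. The two groups differ on a sparse known
edge set, one mechanism per pattern family:

- contemporaneous differences — `n_diff_edges_cov` off-diagonal entries of
  the innovation covariance differ by $\pm$`effect_size`$\cdot$`noise_sd`² —
  drive PC and SR;
- lagged differences — `n_diff_edges_lag` entries of the transition matrix
  differ by $\pm$`effect_size` — drive GCM.

Planted edges are drawn uniformly without replacement with alternating
signs (avoiding systematic mean shifts); specs whose transition matrix has
spectral radius $\ge 1$ or whose covariance is not positive definite are
rejected with explicit errors. Identical specs (including the seed)
reproduce bit-identical cohorts.

Defaults: $N = 116$ ROIs (the atlas size) and $T = 140$ time points (a
typical resting-state scan length; the source protocol does not state one).
The effect defaults — 6 + 6 planted edges at `effect_size` 0.15, unit
innovation sd — were calibrated once so that a desk-scale cohort
($n = 40$, $N = 20$, $T = 140$) lands in the accuracy regime clinical
studies of this design report (single patterns roughly 72–88%, the directed
pattern weakest, fusion best) instead of saturating at 100%, which would
make method comparisons vacuous. They were then frozen.

What the generator does *not* emulate: hemodynamic response convolution,
scanner noise spectra, motion artifacts, inter-subject heterogeneity of the
base network, or realistic anatomical covariance structure. Passing tests
on synthetic cohorts therefore validate the estimators, the fusion, and the
leakage-freedom of the protocol — not clinical effect sizes.

## Validation strategy and problem sizes

The test suite checks every estimator against an independent oracle
(direct-formula Pearson, glmnet lasso objective, per-pair `lm()` Granger
fits, an interior-point QP solve of the SVM dual, exhaustive AUC pair
counting, a 10,000-replicate bootstrap of the DeLong variance), plus
protocol-level properties at desk scale: label-permuted cohorts
($n = 40$, $N = 20$, 10 repetitions) must classify at chance — a leakage
detector — and cohorts with complementary planted signals (10 seeds) must
show the fused classifier matching or beating every single pattern. The
`scripts/acceptance.R` entry point reruns the full pipeline on one such
cohort from a caller-supplied seed.

## Known limitations

- Bivariate (not conditional/multivariate) Granger causality; common-driver
  effects appear as edges in both directions.
- Dynamic (sliding-window) connectivity is out of scope.
- LOOCV accuracy at the null has a known slight pessimistic bias (the
  majority class of each training fold opposes the held-out subject);
  at these cohort sizes it is small relative to the binomial noise band.
- The hub-count rule reports $\lceil 0.05 N \rceil$ nodes with ties
  included; published hub tables of this design sometimes list more nodes
  than that, under selection rules that are not recoverable, so both the
  fraction and the tie policy are configurable.
- With `lam_mode = "cv"` and multiple patterns the grid is searched jointly
  over $(\lambda, C)$, which is substantially slower; the fixed-$\lambda$
  default reproduces the published protocol.
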