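---
title: "Multi-study regulatory network inference: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-study regulatory network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`multigrn` infers transcription-factor → gene regulatory networks jointly
across several expression datasets. This vignette is the package's account
of the underlying model, the estimation machinery, the tunable parameters,
and the design decisions taken where more than one reasonable choice
existed. The worked numbers quoted in the README are produced by the code
shown there and by `scripts/acceptance.R`; nothing here asserts an
empirical result that those runs and the test suite do not themselves
compute.

## The generative view

Expression of gene $i$ in condition $j$ is modelled as a sparse weighted sum
of latent transcription-factor activities,
$X_{ij} = \sum_k w_{ik} \hat{A}_{kj}$. Activity — the concentration of TF
protein actually engaging its targets — is not measured by expression
profiling (it is shaped by post-translational regulation, complex formation
and chromatin context), so it is treated as latent and estimated from the
expression of *known targets*: given a signed prior connectivity matrix
$P$ (genes × TFs; $+1$ activation, $-1$ repression, magnitudes may be motif
counts), we posit $X = PA$ and take the least-squares solution
$\hat{A} = P^{+}X$ with $P^{+}$ the Moore–Penrose pseudo-inverse.

For time-series conditions a regulatory delay $\tau$ separates activity
from its transcriptional consequence: the regression pairs expression at
$t$ with activities at $t-\tau$, and activity estimation uses expression
advanced by $\tau/2$ (splitting the delay symmetrically between the two
stages). Off-grid times are obtained by linear interpolation along each
sample chain.

**Interpolation boundaries.** Only interpolation is defined by the model;
at series edges (e.g. $t-\tau$ before the first sample) we clamp to the
nearest observed sample rather than extrapolate. This is a package decision:
extrapolation would manufacture activity dynamics outside the observed
window. With $\tau = 0$ both operations are exact identities, which the
tests assert.

**Pseudo-inverse.** $P^+$ is computed by SVD with a relative singular-value
cutoff of $10^{-10}$ (`MASS::ginv`). Priors routinely contain TFs with
identical target sets, making $P^\top P$ singular; the printed
normal-equations form $(P^\top P)^{-1} P^\top$ would fail there, the SVD
form does not. Motif-count magnitudes are used as stored (a `clip` switch
binarizes them to signs); TFs with all-zero prior columns fall back to their
measured expression as an activity proxy. We deliberately do not center or
rescale $X$ or $P$ before inversion — the model is linear in the stored
units, and any fixed affine transformation would propagate into the
activity scale that the downstream standardization removes anyway.

## Joint estimation across datasets

For one gene and $D$ datasets, coefficients form a TFs × $D$ matrix
decomposed as $W = S + B$ and fitted by

$$\min_{S,B}\; \sum_d \frac{1}{2 n_d}\bigl\|X_i^{(d)} -
\hat{A}^{(d)\top}(S_{\cdot d}+B_{\cdot d})\bigr\|^2
+ \lambda_s \sum_{k,d} \Phi_{kd}\,|S_{kd}|
+ \lambda_b \sum_k \max_d |B_{kd}|$$

The row-wise $\ell_1/\ell_\infty$ penalty on $B$ makes whole TF rows enter
or leave together — the conserved component — while the elementwise
$\ell_1/\ell_1$ penalty on $S$ admits dataset-specific edges. Prior
knowledge enters through the adaptive weights $\Phi$: if TF $k$ targets the
gene in dataset $d$'s prior, $\Phi_{kd} = 1/\rho$ (prior weight
$\rho \ge 1$), otherwise $1$; each column is then rescaled to sum to the
number of TFs so that changing $\rho$ re-allocates rather than globally
shrinks the penalty budget. $\Phi$ applies to $S$ only: the prior is
treated as evidence valid in one dataset, not as evidence of conservation.

**Loss normalization.** Each task's squared error is divided by its own
$n_d$. Datasets differ in size, and without this the same $(\lambda_s,
\lambda_b)$ would penalize large datasets relatively less, making a shared
penalty grid incoherent.

### Coordinate descent with covariance updates

The objective is jointly convex in $(S, B)$. We minimize it by cyclical
coordinate descent: a sweep updates every $S_{kd}$ by soft-thresholding its
least-squares update (threshold $n_d \Phi_{kd} \lambda_s$ on the
inner-product scale), then every row $B_{k\cdot}$ by the proximal operator
of $\lambda_b\|\cdot\|_\infty$ under the task-weighted quadratic. Because
each step is an exact coordinate-block minimization, the objective is
non-increasing sweep by sweep (asserted in the tests). All data enter
through the per-task cross-products $A^\top A$ and $A^\top X$, cached once
and reused across all sweeps and penalty pairs — these products dominate
runtime, so caching them and warm-starting each grid point from the
previous one makes the grid search cheap. Genes are independent, so the
per-gene fits parallelize with bit-identical results. The inner solver is
compiled (RcppArmadillo), as is usual for penalized-regression packages.

**The $\ell_\infty$ prox.** For one row with per-task least-squares updates
$a_d$ and curvature weights $g_d$, the row problem is
$\min_b \sum_d \tfrac{g_d}{2}(b_d - a_d)^2 + \lambda_b \max_d |b_d|$. Its
solution clips every $a_d$ to $[-t, t]$, where $t$ solves the
piecewise-linear equation $\sum_d g_d(|a_d| - t)_+ = \lambda_b$ and the row
is exactly zero when $\sum_d g_d |a_d| \le \lambda_b$. We solve this
exactly by sorting the $|a_d|$ (datasets are few, so this is trivial). For
equal weights it coincides with the classical Moreau decomposition through
projection onto an $\ell_1$ ball; with one dataset it collapses to the
scalar soft-threshold, making the single-dataset multitask fit identical to
the lasso — the tests pin both reductions.

**Degenerate inputs.** Response and design rows are z-scored within each
dataset (population denominator, so a standardized vector of length $n$ has
squared norm exactly $n$); the $\ell_1$ penalty is scale-sensitive and the
EBIC compares fits across genes, so a common scale is required. A predictor
with zero variance within a task standardizes to the zero vector and its
coefficient stays exactly zero; a zero-variance response gene yields the
empty model. Convergence is declared when the largest coefficient change in
a sweep falls below $10^{-6}$ (at most 1000 sweeps).

### Model selection

Penalty pairs are searched on
$\lambda_b = c\,\sqrt{d \log p / \bar{n}}$ with 20 log-spaced values of
$c \in [0.01, 10]$ and $\lambda_s = r\,\lambda_b$ for
$r \in \{0.55, 0.65, 0.75, 0.85, 0.95\}$ — the ratios sit strictly inside
the admissible open interval $(\tfrac12, 1)$. Two renderings of the scale
factor were defensible ($\sqrt{d \log p / n}$ versus
$d\sqrt{\log p / n}$); we adopt the first, which is the rate the
dirty-model theory prescribes, with $\bar n$ the mean task size. The grid
is traversed from most to least penalized so warm starts stay sparse.

The winning pair minimizes the extended BIC,
$$\mathrm{EBIC} = \frac1D \sum_d \Bigl[\, n_d \ln \tfrac{\mathrm{RSS}_d}{n_d}
+ k_d \ln n_d + 2\gamma \ln \binom{pD}{k_d} \Bigr], \qquad \gamma = 1,$$
with $k_d$ the support size of column $d$. $\gamma = 0$ recovers the plain
BIC. The combinatorial argument $\binom{pD}{k_d}$ (the predictor space
spans tasks) was chosen over $\binom{p}{k_d}$; both are defensible readings
and differ little in the regimes exercised here. An RSS of exactly zero
(noise-free tests) is floored at machine epsilon inside the logarithm.
EBIC ties prefer the smaller support, then the larger penalties.

A property worth knowing: the EBIC is evaluated on the *penalized*
coefficients, so excluding each irrelevant predictor costs roughly twice
its squared spurious z-score (through the extra shrinkage the larger
$\lambda$ imposes on the true coefficients) against a gain of
$\ln n_d$. Exact support recovery is therefore reliable only for large
$n$ — the suite demonstrates it at $n = 1000$ — while edge *ranking*
through the confidence scores is robust at realistic sample sizes, which is
what the end-to-end benchmarks measure.

### Confidence scores and bootstrapping

A selected predictor's confidence is
$c_{ki} = 1 - \sigma^2_{\text{full}} / \sigma^2_{\text{without } k}$,
comparing OLS refits on the selected support with and without predictor
$k$. Refitting (rather than zeroing one penalized coefficient) makes the
reduced model nested in the full one, so $c_{ki} \in [0,1]$ by
construction. Exactly collinear support members are resolved by dropping
the later TF in canonical order and scoring it zero. The full fit and
scoring are repeated over bootstraps of the conditions (20 by default;
resampling acts on condition columns jointly in design and response so
time-linked pairs stay intact; bootstrap $b$ is seeded with `seed + b`).
Scores are rank-averaged across bootstraps — ties get fractional average
ranks, keeping the procedure permutation-invariant — and averaged ranks map
affinely to $[0,1]$ anchored at the best possible rank (1) and the worst
(the number of candidate edges). Ensembles of networks (the combined
STL-C/MTL-C networks) reuse the same rank-averaging.

### Evaluation

Precision–recall curves sweep the ranked list restricted to the TF and
gene universe of the gold standard, with AUPR as the stepwise integral
$\sum \text{precision}\,\Delta\text{recall}$ (no interpolation). Gold signs
are ignored for PR purposes. `filter_at_precision()` returns the maximal
ranked prefix holding a precision cutoff (0.5 in the overlap analyses),
and `overlap_counts()` tallies Venn-style edge sharing across networks.

## The synthetic benchmark

`generate_truth()` / `generate_expression()` emulate exactly the structure
the method assumes: per gene, a small number of regulators (default 2,
matching the 1–2 regulators per gene typical of curated bacterial and
yeast gold standards) with signed weights drawn uniformly from
$\pm[0.5, 2]$ (bounded away from zero so recovery is well posed); a
configurable fraction of each gene's edges (default 0.8) copied — weight
and sign included — across datasets; activities i.i.d. standard normal per
sample and independent across datasets; expression
$X = W_{\text{true}} A + \varepsilon$ with Gaussian noise. The default
noise σ of 1 puts per-gene signal-to-noise near 3, a mid-range regime for
expression compendia. Default study dimensions in the benchmark runs — 200
genes × 20 TFs × 3 datasets of 50 samples, 5 bootstraps — keep a full
MTL+STL comparison near a minute on one core while leaving the MTL/STL
contrast measurable. An AR(1) option generates a single time-series chain
for exercising the τ machinery.

`corrupt_prior()` implements the prior-noise design: keep a `recall`
fraction of true edges, then add one uniformly chosen false edge per five
kept true edges (the false set is disjoint from all planted edges by
construction and flagged for later scoring). `split_gold_standard()`
produces disjoint, exhaustive prior/evaluation partitions (10 by default).
All generator randomness flows from one integer seed through fixed, named
substreams (truth / activities / noise / prior / splits), so each component
is independently reproducible.

**What passing tests do and do not show.** The generator is linear,
homoscedastic, and activity-observed-in-distribution; it contains no batch
effects, no platform differences, no nonlinear saturation, no
autocorrelated biological replicates, and its prior corruption is uniform
rather than biased toward plausible-but-wrong edges. Recovery results on it
therefore validate the estimation machinery — not performance on any real
compendium, where TFA estimation error and prior bias are the binding
constraints.

## Parameters at a glance

| Parameter | Default | Units / range | Notes |
|---|---|---|---|
| `tau` | 0 | time units of `delta_t` | 15 is the customary choice for *B. subtilis*-style time series; per dataset |
| `prior_weight` (ρ) | 1 | ≥ 1 | 1 disables prior-biased selection; prior still drives TFA |
| `n_boot` | 20 | count | bootstraps of conditions |
| `gamma` | 1 | [0, 1] | EBIC weight; 0 = BIC |
| `c_range`, `c_grid_size` | [0.01, 10], 20 | — | log-spaced λ_b scale grid |
| `ratios` | 0.55…0.95 | (½, 1) | λ_s/λ_b placements |
| `tol`, `max_sweeps` | 1e-6, 1000 | — | coordinate-descent stopping rule |
| `tfa_mode` | `prior_pinv` | — | or `expression` (TF expression as activity) |
| `num_workers` | 1 | count | per-gene parallelism; bit-identical to serial |

## Known limitations

Priors and gold standards are matched to expression by exact,
case-sensitive identifier equality (no aliasing). Missing expression values
are rejected at load rather than imputed, because the covariance-update
solver assumes complete matrices. The ensemble combination assumes all
networks cover the same edge universe. Batch correction, prior construction
from chromatin accessibility, and task-similarity weighting are outside the
package's scope.
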