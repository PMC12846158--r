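---
title: "Methods: constrained and transposed IVA-G, stability selection, and the synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constrained and transposed IVA-G}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ivafuse)
```

This vignette is the package's own account of its models, numerical choices,
and the limits of what its tests establish. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The model and its assumptions

For K datasets, each reduced to N components over S samples, the generative
model is $x^{[k]}(v) = A^{[k]} s^{[k]}(v)$ with invertible $A^{[k]} \in
\mathbb{R}^{N\times N}$. The n-th *source component vector* (SCV) collects
the n-th source from every dataset,
$s_n(v) = [s_n^{[1]}(v), \dots, s_n^{[K]}(v)]^\top$. Under the Gaussian SCV
model (IVA-G) with covariance $\Sigma_n \in \mathbb{R}^{K\times K}$ and
i.i.d. samples, the maximum-likelihood objective in the demixing matrices
$W^{[k]}$ reduces (dropping additive constants, see §4) to

$$ J(\mathcal{W}) = \tfrac{1}{2}\sum_{n=1}^{N} \log\det \hat\Sigma_n
   \;-\; \sum_{k=1}^{K} \log\lvert\det W^{[k]}\rvert, $$

with $\hat\Sigma_n$ the sample covariance of the n-th estimated SCV. Only
second-order statistics enter: identifiability rests entirely on the SCVs
having *distinct* covariance profiles across $n$. Components with identical
$\Sigma_n$ cannot be separated by this model — the synthetic generator
guards against this (§5) and warns when asked to violate it.

Key assumptions a user inherits: linear instantaneous mixing; samples
treated as i.i.d. (spatial smoothness of real imaging data violates this —
it reduces the effective sample count but does not bias the estimator);
Gaussian SCVs (heavier-tailed sources still separate if their second-order
cross-dataset structure is distinct).

### The threshold-free constraint

Given references $r_1,\dots,r_M$ ($M \le N$), reference $n$ is assigned to
component $n$ by index. With $\epsilon$ the Pearson correlation,

$$ J_{\mathrm{ref}}(\mathcal{W}) = \sum_{n=1}^{M}\sum_{k=1}^{K}
   \Big[ \sum_{m \ne n} \epsilon^2(r_n, \hat s_m^{[k]})
   - \epsilon^2(r_n, \hat s_n^{[k]}) \Big], $$

and the full objective is $L_\lambda = J + \tfrac{\lambda}{2}
J_{\mathrm{ref}}$. Squared correlation is bounded, scale-free, and blind to
the sign ambiguity of blind source separation; no correlation-threshold
parameter is needed, which is the point of the construction — the
post-analysis correlation between component and reference then serves as an
honest measure of reference quality rather than a target that was imposed.
The leakage sum runs over the *other components* $m \ne n$; this is the only
reading consistent with "promote dissimilarity with all other components",
and it is what makes a poorly matched reference fail soft (the component
drifts; it is not clamped).

### Transposed IVA

Transposing each dataset ($X^\top = S^\top A^\top$) swaps the roles of the
factors: PCA acts on the voxel axis, the estimated sources are *subject
profiles*, and the back-projected mixing columns are spatial maps. Because
the statistical sample axis becomes subjects ($S = T \ll V$), SCV covariance
estimates are much noisier — the sample-poor regime. This is precisely the
setting where a behavioral reference on the profile adds real information,
and the package's constrained-vs-unconstrained contrast (acceptance
criterion 5) quantifies that: the same seeds, the same data, with and
without the constraint.

## 2. Parameters that matter

| Parameter | Default | Units / scale | Why |
|---|---|---|---|
| `lambda` | 100 | dimensionless; $J$ is $O(N)$, $J_{\mathrm{ref}} \in [-M K, (N-1)MK]$ | the field-standard weight balancing the two terms; z-scored references keep its meaning stable across inputs |
| `order` (standard view) | 45 | components | convention for subject-axis reduction of ~250-subject feature data |
| `order` (transposed view) | 6 | components | transposed runs are run at small orders; stability selection (§3) is the tool for choosing it |
| `n_runs` | 100 (pipeline), 10 in fast profiles | runs | run-to-run reproducibility is the selection signal; 10 is enough for the synthetic world |
| `w_change_tolerance` | 1e-6 | rotation-invariant demixing change | scale-free convergence test, below any scientifically meaningful change |
| `max_iterations` | 1024 | accepted steps | desk-scale runs converge in 250–800 steps |
| `ridge_scale` | 1e-8 | fraction of mean SCV variance | keeps $\hat\Sigma_n$ positive definite in the sample-poor regime; negligible elsewhere |
| `alpha` | 0.05 | FDR level | applied to BH-adjusted p-values, within-task family by default |

## 3. Stability selection

Run-to-run reproducibility is measured with the joint Amari-style
inter-symbol-interference score of the matrices $G^{[k]} = W_a^{[k]}
(W_b^{[k]})^{-1}$, aggregated as $\bar g = \sum_k |G^{[k]}|$ and normalized
to $[0,1]$; it is zero exactly when $\bar g$ is a generalized permutation
matrix, i.e. when two runs agree up to the inherent permutation/scale
ambiguity. The run minimizing the mean cross-joint-ISI to all other runs is
selected (ties break to the lowest index).

**On model-order scans.** The scan reports the per-order stability table and
the raw minimizer, but deliberately does not auto-select: underfit orders
merge components *reproducibly* and therefore often have the lowest
cross-ISI of all (in the package's synthetic world, order 2 beats the true
order 4 in most replicates). What the metric reliably signals is the
collapse of stability once the order exceeds the truth. The order-scan test
asserts exactly that — overfit orders are less stable than the true order,
and the true order is stable in absolute terms — rather than the naive
"minimizer equals truth", which is false in general.

## 4. Numerical choices

- **Reduction and whitening.** Per-dataset economy SVD of the row-centered
  data; the projection folds in $\sqrt{S}/d_i$ so the retained rows have
  exactly identity sample covariance (denominator $S$, used consistently
  everywhere). Each projection row's sign is fixed so its largest-magnitude
  entry is positive — reproducible across BLAS implementations. The
  back-projection is the analytic pseudo-inverse $U \mathrm{diag}(d)/\sqrt{S}$.
- **Optimizer.** Full-ensemble gradient descent with Armijo backtracking
  (factor 0.5, slope 1e-4, step floor 1e-14, step doubling after acceptance
  capped at 4x). Accepted steps never increase the objective — this
  monotonicity is asserted on every stored cost trace. Iterates that make
  any $W^{[k]}$ singular or any $\hat\Sigma_n$ non-PD evaluate to $+\infty$
  and are rejected by the line search rather than raised as errors;
  reaching the step floor is treated as stationarity. $\hat\Sigma_n$ is
  re-estimated at every evaluation (not lagged) — a package choice where the
  field's descriptions are silent.
- **Dropped constant.** The reported cost omits the additive
  $\tfrac{NK}{2}\log(2\pi e)$ of the Gaussian likelihood; the test-suite
  oracle that sums the actual log-density over samples subtracts this
  constant before comparing, and disables the diagonal ridge on both sides
  (the ridge perturbs the quadratic form at the 1e-8 level, above the
  comparison tolerance).
- **Sign and scale pinning.** After convergence, rows of each $W^{[k]}$ are
  L2-normalized (the objective is exactly invariant to row scale, so this
  costs nothing); constrained components are flipped to correlate positively
  with their reference, unconstrained components to positive sample
  skewness. For exactly Gaussian sources skewness is a coin flip in sign but
  still deterministic given the data — reproducibility, not meaning.
- **$\lambda = 0$.** A zero-weight constraint is replaced by the
  unconstrained path outright, so constrained-with-$\lambda=0$ and
  unconstrained runs at the same seed are *bitwise* identical (the two
  paths' sign conventions would otherwise differ even though every cost and
  gradient agrees).
- **Degenerate inputs.** Constant references, duplicate labels, zero
  pooled variance with unequal means, empty groups, orders above the data
  rank, and zero rows/columns in ISI aggregates are hard errors; zero
  pooled variance with equal means yields $t=0, p=1$ by convention.
- **Tie-breaks.** Run selection takes the first minimum; greedy component
  matching resolves by largest remaining absolute correlation.

## 5. The synthetic world

The generator emulates the geometry of a multi-subject, multi-task feature
study at desk scale: $K=3$ tasks, $T=120$ subjects in two balanced groups,
$V=5000$ voxels, $N=6$ components. Per component, sources are $V$ i.i.d.
draws of a $K$-variate Gaussian with compound-symmetric correlation, the
off-diagonals spaced $0.3\dots0.9$ across components — distinct profiles,
the identifiability guard. Mixing entries are standard Gaussian; a group
effect of Cohen's d is injected as a mean shift of the patient entries in
the chosen mixing column (population pooled SD 1, so the injected shift *is*
the population d). Observation noise is additive Gaussian with
`noise_sd = 0.1` — weak relative to unit-variance sources mixed across 6
components, chosen once as a realistic feature-data noise floor: reduction
to the true order absorbs most of it, and the acceptance experiments do not
move it. References are $\alpha\, z(\text{signal}) +
\sqrt{1-\alpha^2}\, z(\text{noise})$, so the expected correlation with the
truth equals the requested fidelity exactly.

Deliberate simplifications, and what a green test therefore does *not*
establish: no spatial autocorrelation (real voxels are smooth, so real
effective sample counts are far below $V$); no hemodynamic or task-design
structure; Gaussian sources only (matching the second-order model — a
heavy-tailed world would favor other SCV densities); mean-shift group
effects only (no variance or topology differences). Recovery at ISI < 0.05
here means the estimator and its optimization work; it is not a claim about
any particular acquisition.

Sub-streams for sources, mixing, noise, and references are derived from the
master seed at fixed offsets, so each generator is independently callable,
reproducible, and uncorrelated with the others.

## 6. Experiment design choices

- The constrained-vs-unconstrained contrast targets **component 1**, whose
  SCV correlation (0.3) is the weakest and which is therefore the hardest
  component for unconstrained IVA-G — the regime the contrast is about. The
  reference is built from (and the comparison made against) dataset 1's
  profile; the index-assignment convention makes the constrained component
  index 1 by construction.
- Group-effect detection is evaluated in task 1's BH family (6 components,
  within-task adjustment — the narrowest defensible family; pooling across
  tasks is available via `fdr_family = "all"`).
- Behavioral references are z-scored before use. This is the package's
  choice (correlation-based similarity is invariant to it; numerical
  conditioning and the interpretability of $\lambda$ benefit).
- Feature matrices are *not* variance-normalized per subject before PCA by
  default; no flag is exposed because the correlation-based constraint and
  the whitening make the pipeline scale-free where it matters.

## 7. Known limitations

- The optimizer is first-order; Newton-type IVA-G implementations converge
  in far fewer iterations. The gradient scheme is the contract here because
  its monotonicity is cheaply testable; at desk scale a run takes on the
  order of a second.
- Cross-joint-ISI compares runs at equal order only; the order scan compares
  stability *across* orders, which conflates estimator stability with
  problem difficulty (§3).
- One reference per constrained-tIVA run is enforced (override available):
  behavioral measures probing overlapping constructs would otherwise fight
  each other through the leakage term.
- NIfTI support is the minimal uncompressed single-file NIfTI-1 subset
  (float32 data, identity orientation): enough to exchange masks and
  component maps with standard viewers, not a general neuroimaging I/O
  layer.
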