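---
title: "Optimal allocation of observations in discrete-time cluster studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal allocation of observations in discrete-time cluster studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wedgealloc)
```

## Model and design problem

A layout is a set of available cluster-period cells of a $K \times T$
lattice with fixed treatment indicators $Z_{kt} \in \{0,1\}$; at least one
epoch must contain both arms, or no controlled comparison exists. For the
$i$-th observation in cell $(k,t)$ we assume the cross-sectional linear
mixed model

$$y_{kti} = \beta_t + \theta Z_{kt} + \gamma_{kt} + \varepsilon_{kti},$$

with independent clusters, $\mathrm{cov}(\gamma_{ks},\gamma_{kt}) =
\rho\sigma^2\,\Gamma_{st}$ and
$\mathrm{var}(\varepsilon_{kti}) = (1-\rho)\sigma^2$. The Toeplitz matrix
$\Gamma$ of cluster autocorrelations is parameterized as
$\Gamma_{st} = \alpha r^{|s-t|} + (1-\alpha)\delta_{st}$, which nests the
exchangeable (EXC), block-exchangeable (BEX) and discrete-time-decay (DTD)
models, and the identity when $\alpha r = 0$. $\Gamma$ is invertible
everywhere on the unit square except the EXC corner; the package never
inverts $\Gamma$ itself, only the cell-mean covariance, which is positive
definite whenever $\rho < 1$ and all occupied cells are nonempty.

Given a total sample size $N$, an allocation $\pi_{kt} = n_{kt}/N \ge 0$,
$\sum \pi = 1$, determines the BLUE $\hat\theta = \sum a_{kt}\bar y_{kt}$
with weights constrained to sum to zero within every epoch (eliminating
$\beta_t$) and to one over treated cells. Its variance is

$$V(a, N\pi) = \sigma^2\Big[\rho \sum_k a_k'\Gamma a_k +
\frac{1-\rho}{N}\sum \frac{a_{kt}^2}{\pi_{kt}}\Big].$$

Minimizing over $\pi$ for fixed $a$ gives $\pi \propto |a|$ and the convex
objective $\Psi(a) = \rho \sum_k a_k'\Gamma a_k +
\frac{1-\rho}{N}\big(\sum|a_{kt}|\big)^2$, whose minimum over the
constraint set is the optimal-design variance. Because only the ratio
$N\rho/(1-\rho) = K S/(1-S)$ multiplies the quadratic form, allocations,
efficiencies and thresholds depend on $(N,\rho)$ only through the index of
cluster variation $S = M\rho/(1+(M-1)\rho)$, $M = N/K$. `design_scale()`
accepts $(N, K, \rho)$, $(S, K)$ or the raw ratio; when only $S$ or the
ratio is given, the canonical representative $N = K$, $\rho = S$ is stored,
which changes nothing scale-free.

## The alternating algorithm

`optimal_allocation()` alternates (i) a GLS fit on cell means giving the
BLUE weights for the current allocation, and (ii) the exact update
$\pi \leftarrow |a|/\sum|a|$. Each step is a partial minimization, so the
variance trace is non-increasing and the iteration converges; with
invertible $\Gamma$ the limit is the unique optimum. Numerical choices:

- GLS is computed on cell means, not observations — identical estimator,
  cubic in the number of cells instead of $N$. Within a cluster the
  cell-mean covariance is $c\,\Gamma + \mathrm{diag}(1/\pi)$ in scaled
  units, factorized by Cholesky per cluster.
- Convergence requires a relative variance change below `tol_var = 1e-12`
  *and* a fixed-point residual $\lVert\pi - |a|/\sum|a|\rVert_\infty$ below
  `tol_fix = 1e-10` (cap `max_iter = 1e5`). Support cells decay
  geometrically rather than hitting zero, so tail convergence near a
  support boundary is slow by nature; both tolerances sit far below the
  two-decimal precision of any reported quantity.
- A cell whose mass reaches zero can never re-enter the iteration, so the
  default start is uniform over all permitted cells, and a safeguard
  restart mixes 1% uniform mass into the converged allocation and
  re-converges, keeping the better result. Proportions below `1e-11` are
  treated as numerically dead and removed — a floating-point guard well
  under the `1e-5` *reporting* threshold used to classify support, which
  never feeds back into the iteration.
- During iteration the estimability guard on the information matrix is
  relaxed to `1e-13` (epochs en route to emptiness pass through
  near-singular states); the user-facing `blue_coefficients()` keeps a
  strict `1e-10` reciprocal-condition threshold and raises rather than
  pseudo-inverting, since inestimability signals a malformed design.
- Prohibited cells are handled by pinning their weights to zero
  (`optimize_sublayout()`); rounding to integer designs
  (`round_design()`) offers multiplier-based apportionment and
  largest-remainder rules with lexicographic tie-breaks, so results are
  bit-reproducible.

Under the EXC model $\Psi$ is convex but not strictly so; optima need not
be unique. Stepped-wedge problems are invariant under the skew
transformation (time reversal + arm interchange + cluster reversal), so a
skew-symmetric optimum always exists; `exc_optimum()` returns the
skew-symmetrized average, which cannot have larger variance.

## Natural allocations and thresholds

An allocation is *natural* if the BLUE equals the simple
treated-minus-control difference of means, i.e. $a = 2(2Z-1)\pi$; this
forces per-epoch balance, and the verdict depends only on $\Gamma$ — never
on $(N,\rho)$ — which `check_natural()` verifies at several probe scales.
The *best natural allocation* minimizes the natural variance
$\rho\sum_k a_k'\Gamma a_k + 4(1-\rho)/N$. Two independent routes are
implemented and cross-checked: a convex quadratic program over the natural
cone solved by a primal active-set method (no QP library is required), and
the alternating optimizer run at $S = 1/(K+1)$. The second route exploits
the threshold result — the optimum equals the best natural allocation for
every $S \le S_1$ and $S_1 \ge 1/(K+1)$ always. (Running the optimizer at
an arbitrarily tiny ratio instead is unreliable: as the ratio tends to 0
the correlation term becomes a vanishing perturbation and the iteration
loses its ability to discriminate among balanced allocations, so the
guaranteed-safe interior value $S = 1/(K+1)$ is used.)

For the threshold itself the package's primary method is exact: at the
natural coefficients, every subgradient optimality condition of $\Psi$ is
affine in the ratio $c = N\rho/(1-\rho)$, so the supremum of feasible $c$
is located by bisection *on feasibility* to machine precision and
$S_1 = c^*/(K + c^*)$. The operational alternative — the largest $S$ at
which the best natural allocation is at least 99.99% efficient, by
bisection over repeated optimizations — is kept as `method = "bisect"`;
it overshoots the exact threshold slightly (the efficiency dip above $S_1$
opens quadratically), which is why the exact method is the default. Under
the EXC model the exact method reproduces $S_1 = (K+1)/(K+4)$ to $10^{-9}$.
The 90%-efficiency threshold $S_{.9}$ has no exact analogue and is always
computed by efficiency bisection.

## Staircase designs

For stepped-wedge layouts the best natural allocation has *staircase*
support (the two cells flanking each switch, no baseline/endline) whenever
the first-order autocorrelation $\alpha r$ is large enough. The optimal
staircase weights are
$q_k \propto \cosh K\phi - \cosh{(2k-K)\phi}$ with
$\phi = \tfrac12\,\mathrm{arccosh}\{(\alpha r)^{-1}\}$, degenerating to
$q_k \propto k(K-k)$ as $\alpha r \to 1$; the variance has a matching
closed form, checked against the GLS engine to $10^{-10}$. The reciprocal
inside the arccosh is forced by three requirements: $\phi$ must be real for
$\alpha r < 1$, the $\alpha r \to 1$ limit must recover $k(K-k)$, and the
BEX $K=4$ support threshold must come out at exactly $\alpha = 2/3$ — all
three hold under this reading.

Whether the staircase *is* the best natural allocation is decided by an
exact dual-feasibility check of the closed-form staircase point in the
natural-cone quadratic program, computed cluster-wise without forming the
dense quadratic form (cheap for any $K$). Closed-form conditions are
available for the BEX family ($\cosh K\phi / \cosh\phi \le 3$ for odd $K$,
$\cosh K\phi \le 2 + 1/\alpha$ for even $K$) and the DTD family (bound
$(1+r)/(1-r)$, with the odd-$K$ left side divided by $\cosh\phi$), and
`staircase_is_best_na(method = "both")` raises on any disagreement. A
general-$(\alpha, r)$ closed form is not exposed: the candidate algebraic
unification we examined fails to reduce to the printed BEX special case,
so outside the named families the dual check is authoritative.

With $m = S_1/(1-S_1)$, the staircase remains the overall optimum at ICC
$\rho$ as long as the average cluster size satisfies
$M \le m(1-\rho)/\rho$. `staircase_s1()` reports this bound rounded to the
nearest integer, which is the convention under which the tabulated limits
(e.g. 79 at $K = 10$, study-length autocorrelation $r^K = 0.66$,
$\rho = 0.05$, where the exact bound is 78.87) are reproduced; truncating
instead would understate several entries by one. The exactness of the
underlying $S_1$ was verified by direct optimization on both sides of the
threshold.

## Scope of the validation suite

The test suite validates every layer against independent routes: hand GLS
solutions on two-cell comparisons, a split-variable convex QP oracle for
the full objective on small layouts, closed forms for two-sequence
parallel/cross-over layouts, the uncorrelated-cluster-period profile, the
staircase family, and the published case-study table. All of these are
exact model-based quantities; no synthetic outcome data are involved
anywhere, because the design problem depends on the model only through
$(\Gamma, \rho, N)$. Consequently the tests demonstrate correctness of the
design calculations, not robustness of the mixed model itself to
misspecified correlation structure at analysis stage — a question the
package deliberately leaves open. Problem sizes used throughout (layouts up
to $K = 10$ for optimization, $K \le 86$ for staircase support checks,
40-step bisections) were chosen to exceed the precision of every printed
reference value by several orders of magnitude.

## Limitations

- One cluster per sequence (or equal replication); unequal replication per
  sequence and the joint choice of switch times are out of scope.
- Continuous-time sampling schedules are not modeled; epochs are the
  discrete switch-point grid.
- No estimation of $(\alpha, r, \rho)$ from data: the correlation model is
  a design-stage input. Raw correlation matrices are accepted but not
  estimated.
- Under EXC the optimal allocation need not be unique; reported optima are
  canonical (skew-symmetrized) representatives with the optimal variance.
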