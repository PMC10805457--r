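---
title: "Selective inference for k-means clustering: model, computation, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective inference for k-means clustering: model, computation, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selkmeans)
```

## The model and the inferential problem

We observe an $n \times q$ data matrix $x$, modelled as a realization of a
matrix normal distribution: independent rows $X_i \sim N_q(\mu_i, \sigma^2
I_q)$ with unknown mean matrix $\mu$ and (initially) known noise level
$\sigma$. After running k-means clustering, an analyst picks two estimated
clusters $\hat{\mathcal C}_1, \hat{\mathcal C}_2$ and asks whether their
population means differ:

$$H_0:\; \textstyle\sum_{i \in \hat{\mathcal C}_1} \mu_i / |\hat{\mathcal C}_1|
 \;=\; \sum_{i \in \hat{\mathcal C}_2} \mu_i / |\hat{\mathcal C}_2|.$$

With the contrast $\nu_i = \mathbf 1\{i \in \hat{\mathcal C}_1\}/n_1 -
\mathbf 1\{i \in \hat{\mathcal C}_2\}/n_2$ this is $H_0: \mu^\top\nu = 0_q$,
and the natural statistic is $\|x^\top\nu\|_2$, the distance between the two
cluster centroids. Unconditionally $\|X^\top\nu\|_2 \sim (\sigma\|\nu\|_2)
\chi_q$ under $H_0$ — but only for a *fixed* $\nu$. Here $\nu$ was chosen
because k-means separated these clusters, so the naive survival probability
(`naive_p()`) is grossly anti-conservative: its null distribution piles up
near zero.

The remedy is to report a p-value *conditional on the clustering outcome
that generated the hypothesis*. The test here conditions on the complete
trace of a Lloyd's algorithm run — the initial sampled centroids and every
intermediate assignment vector $c^{(0)}, \ldots, c^{(T)}$ — together with
the standard nuisance statistics $\Pi_\nu^\perp X$ (the component of the
data orthogonal to the contrast) and $\mathrm{dir}(X^\top\nu)$. After that
conditioning, the only remaining randomness is the scalar
$\phi = \|X^\top\nu\|_2$, whose null distribution is $(\sigma\|\nu\|_2)
\chi_q$ *truncated* to the set of $\phi$ values consistent with the
observed trace. The test that rejects when this conditional tail
probability falls below $\alpha$ controls the selective Type I error at
$\alpha$ in finite samples; conditioning on the whole trace (rather than
only the final partition) is what makes the truncation set tractable — the
final-partition-only event would require enumerating exponentially many
intermediate assignment histories.

## The perturbation line and the truncation set

Varying $\phi$ while holding the conditioned quantities fixed moves the
data along a line through the observed matrix:

$$x'(\phi) = x + (\phi - \|x^\top\nu\|_2)\,
  \frac{\nu}{\|\nu\|_2^2}\,\{\mathrm{dir}(x^\top\nu)\}^\top,$$

so row $i$ of $x'(\phi)$ is *affine* in $\phi$ with slope $(\nu_i /
\|\nu\|_2^2)\, d$ for a fixed direction $d$. `perturbation_line()` stores
exactly this decomposition (base matrix, per-row scales, direction).
At $\phi = \|x^\top\nu\|_2$ the observed data are recovered exactly;
for the tested pair, $\phi$ *pushes apart* ($\phi$ large) or *collapses*
($\phi = 0$) the two centroids while leaving everything orthogonal to
$\nu$ untouched.

The conditioning event "re-running Lloyd's algorithm on $x'(\phi)$
reproduces every intermediate assignment" decomposes, iteration by
iteration and observation by observation, into *nearest-centroid
dominance* conditions: at iteration $t$, observation $i$ must be at least
as close to its assigned centroid as to each of the $K-1$ competitors.
Because every row of $x'(\phi)$ — and hence every fixed-weight centroid of
$x'(\phi)$ — is affine in $\phi$, each squared distance is an exact
quadratic in $\phi$, and each dominance condition is a difference of two
quadratics: again a quadratic, $a\phi^2 + b\phi + c \le 0$. For a vector
$u + \phi v$ the coefficients are simply $a = \|v\|^2$, $b = 2\langle u, v
\rangle$, $c = \|u\|^2$; `pairwise_coeffs()` and `weighted_coeffs()`
expose the two cases (initial centroids are held-fixed data rows;
later centroids use cluster-mean weights *frozen from the original
trace*, which is what makes the event polynomial in $\phi$).

`truncation_region()` solves all $nK(T+1)$ inequalities
(`solve_quadratic_inequality()`: interval, complement-of-interval,
half-line, everything, or empty, per the sign of $a$ and the discriminant)
and intersects the solution sets by a single sort-and-sweep over interval
endpoints (`intersect_all()`), which keeps the cost at
$O(KT(n+q) + nKT\log(nKT))$. The result is a finite union of closed
intervals, intersected with $[0, \infty)$ — the support of the chi
reference — before use. Two brute-force oracles validate the construction:
`grid_oracle_region()` re-clusters $x'(\phi)$ from the same initial
indices with the same tie-break at each grid point, and `mc_oracle_p()`
estimates the p-value by rejection sampling. The test suite requires exact
agreement away from interval endpoints and statistical agreement (within
three Monte Carlo standard errors) of the p-values.

## Computing the truncated survival probability

`truncated_chi_survival()` evaluates
$P(\phi \ge s,\ \phi \in S)/P(\phi \in S)$ for $\phi \sim
\text{scale}\cdot\chi_q$ by accumulating per-interval masses as
differences of survival functions *in log space* (`pchisq(log.p = TRUE)`
with a stable `log1mexp` subtraction). When a narrow interval deep in the
tail underflows even there, the mass is replaced by midpoint density times
width — an accurate approximation exactly in that regime. A region whose
total mass is numerically zero after both safeguards raises an error that
points to the Monte Carlo oracle rather than silently returning 0/0. This
matters in practice: well-separated clusters produce regions like
$[59, \infty)$ on a scale where both numerator and denominator are
$e^{-1700}$, yet the *ratio* is a perfectly ordinary number.

## Extensions

**Known covariance $\Sigma$** (`kmeans_sel_test_cov()`). Two procedures are
provided, which condition on different events and answer subtly different
questions; neither dominates. `mode = "whiten"` maps $x_i \mapsto
\Sigma^{-1/2} x_i$ and runs the spherical test with $\sigma = 1$: the
clustering is performed on whitened data. `mode = "direct"` clusters the
*raw* data; the statistic becomes $\|\Sigma^{-1/2} x^\top \nu\|_2 \sim
\|\nu\|_2 \chi_q$ under $H_0$, and the perturbation moves row $i$ by
$\phi\,(\nu_i/\|\nu\|_2^2)\,\Sigma^{1/2}\mathrm{dir}(\Sigma^{-1/2}
x^\top\nu)$ — still affine in $\phi$, so the identical quadratic machinery
applies with a (non-unit) direction vector. We derive the coefficients
generically from the affine decomposition rather than via specialized
closed forms; the grid oracle validates the result, and for $\Sigma =
\sigma^2 I$ the direct procedure reproduces the spherical test exactly
(with the region expressed on the whitened scale, i.e. divided by
$\sigma$). When no $\Sigma$ is known, `ridge_whitening_estimate()`
provides the pragmatic preprocessing transform
$U(\Lambda + \text{ridge}\,I)^{-1/2}U^\top$ from the eigendecomposition of
the sample covariance (default ridge 0.01), useful when features are
correlated or $q > n$; testing after *estimated* whitening is heuristic,
not exact.

**Unknown $\sigma$** (`sigma = "med"` / `"sample"`). The truncation set
does not involve $\sigma$, so a plug-in estimate only changes the
reference scale. $\hat\sigma_{\text{MED}}$ centres each column at its
median and matches the median squared residual to the $\chi^2_1$ median
(computed from the quantile function at run time, never hard-coded); it is
robust to sparse mean structure. $\hat\sigma_{\text{Sample}}$ is the
column-centred RMS with divisor $nq - q$; genuine cluster separation
inflates it, making the resulting test conservative — visibly so in the
power experiment, where its power *declines* as separation grows while its
Type I error stays controlled. Plug-in control is asymptotic (in $q$), not
finite-sample; the simulations below show it is excellent at $q = 2$
already.

## Simulation design

`simulate_type1()` draws global-null datasets ($\mu = 0$), clusters with
$K = 3$, tests a uniformly random pair, and records the naive, selective
and both plug-in p-values per replicate — reusing one truncation region
per replicate across the three selective variants, since the region is
$\sigma$-free. `simulate_power()` uses the three-equidistant-cluster
design: group means at $\mp\delta/2$ on the first coordinate and
$\sqrt{3}\delta/2$ on the last, the unique (up to rotation) placement with
all pairwise mean distances $\delta$; it reports the *detection
probability* (how often the tested pair coincides exactly, as sets, with
true clusters) and the *conditional power* (rejection rate among those
replicates, reported `NA` when none detected — at high noise the true
clusters are simply never recovered, and pretending otherwise would
overstate power). Replicates whose k-means run hits an empty cluster are
redrawn and counted (`$redraws`); the weights defining the conditioning
event are undefined for an empty cluster, so such runs cannot be tested
at all — a property of the method, not a numerical failure.

Default experiment sizes are 500 replicates for calibration runs and 2,000
per separation value for power runs at $n = 150$, $q = 10$; these give
binomial standard errors below 0.01 on rejection rates, and each
full run completes in well under a minute. What these simulations emulate
is the idealized model: isotropic Gaussian noise, independent
observations, known (or estimable) $\sigma$. What they do not emulate —
count-valued data, mean-variance coupling, correlated features beyond the
known-$\Sigma$ case, dependence between observations — is exactly what a
user of single-cell or imaging data should keep in mind: passing
calibration here demonstrates the mathematics, not robustness to model
misspecification.

## Numerical choices and edge cases

* **Tie-breaking.** Nearest-centroid ties go to the lowest cluster index,
  everywhere (original run, constraint construction, oracles). Under the
  continuous model ties have probability zero; what matters is that the
  rule is fixed and identical wherever assignment is re-evaluated.
* **Non-strict inequalities.** Constraints use $\le$, so truncation
  intervals are closed; boundary points carry no probability mass.
* **Tolerance.** Quadratic degeneracy and discriminant checks use a
  relative tolerance of $10^{-10}$ (exposed as `tol`). A discriminant
  within tolerance of zero is treated as a grazing vertex: a double root
  for convex constraints, no exclusion for concave ones. This prevents
  floating-point noise from carving spurious holes around the observed
  statistic, which always satisfies every constraint exactly.
* **Convergence.** Lloyd's algorithm is capped at `max_iter = 300`
  updates. A non-converged trace is still a valid conditioning event —
  the p-value conditions on iterations $0..T$ whatever $T$ is — but the
  result records `converged = FALSE`.
* **Empty clusters** abort with an error naming the iteration; the
  command-line tool advises re-running with a different seed.
* **Degenerate statistic.** If $\|x^\top\nu\|_2 = 0$ the perturbation
  direction is the zero vector, the region is all of $[0,\infty)$, and the
  p-value is 1 — the continuous-model-measure-zero case handled
  conservatively.
* **Initialization** is uniform sampling of $K$ data rows, held fixed by
  the conditioning; k-means++ or restarts would change the conditioning
  event and are deliberately not implemented.

## Known limitations

Conditioning on *every* intermediate assignment is more than the final
partition logically requires, and costs power relative to the (intractable)
final-partition-only test. P-values for several cluster pairs are reported
raw, with multiplicity handling left to the caller. The Gaussian
assumption is essential to the exactness argument; the plug-in variants
are exact only asymptotically. The whitened and direct covariance
procedures test hypotheses attached to different clusterings (of whitened
vs raw data), and the package takes no position on which a given analysis
should prefer.
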