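---
title: "Local structural equation models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local structural equation models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(localsem)
```

## The model

A covariance-structure SEM relates I observed indicators $X$ to latent
factors $\eta$ through $X = \nu + \Lambda \eta + \epsilon$, with
$\mathrm{Var}(\eta) = \Phi$, $\mathrm{Var}(\epsilon) = \Psi$, and optional
structural regressions $\eta = B\eta + \zeta$ among the factors.  The
implied covariance matrix is
$$\Sigma(\theta) \;=\; \Lambda (I-B)^{-1} \Phi \left[(I-B)^{-1}\right]^\top
\Lambda^\top + \Psi,$$
reducing to $\Lambda\Phi\Lambda^\top + \Psi$ without structural paths.
Estimation minimizes the maximum-likelihood discrepancy
$D(S, \Sigma) = \log|\Sigma| + \mathrm{tr}(S\Sigma^{-1}) - \log|S| - I$,
which is nonnegative and zero exactly at $S = \Sigma$.  Means are not
modeled; the mean structure is removed by local residualization (below),
so all estimands live in the covariance structure.

A *local* SEM treats the model parameters as smooth functions
$\theta(a)$ of a continuous moderator $a$ (age, in the motivating
applications).  At each focal point $a_t$ of a user-chosen grid, subjects
are weighted by a kernel in their moderator distance,
$w_{nt} = K\!\left((a_n - a_t)/bw\right)$, and weighted conditional
moments feed an SEM fit.

## Local moments

For each indicator and focal point, a local quadratic regression in the
centered moderator $(a_n - a_t)$ is solved by weighted least squares
(closed-form normal equations; the design degrades to linear and then to
an intercept when fewer than three distinct support points carry
weight).  Residuals $e_{nit}$ from these fits yield the conditional
covariance either by direct weighting,
$\hat\sigma_{ij}(a_t) = W_t^{-1}\sum_n w_{nt}\, e_{nit} e_{njt}$ with
$W_t = \sum_n w_{nt}$, or — `cov_mode = "local_regression"` — as the
intercept of a second local quadratic regression of the residual products
on the centered moderator.  The weighting form uses the $W_t$ denominator
(the ML-style $\div N$ analogue) with no finite-sample correction, so on
grid-valued data with a uniform kernel of half-grid-spacing bandwidth it
reproduces per-group ML sample covariances exactly; this is the bridge
behind the multiple-group equivalence below.  When `residualize = FALSE`
the residuals are deviations from the kernel-weighted mean rather than
the raw values, so conditional covariances remain central moments.

Missing indicator values are handled by pairwise deletion with per-pair
renormalization of the kernel weights.  Estimated matrices are not
guaranteed positive definite (especially under missingness), so
`repairPositiveDefinite()` clips eigenvalues at a relative floor of
$10^{-4}$ of the largest eigenvalue, reassembles, and rescales the
diagonal back to the input diagonal; the repair is idempotent on matrices
that are already positive definite.  The floor is the smallest
perturbation that keeps the ML discrepancy well defined.

## Kernels, bandwidth, grid

Kernels satisfy $K(0)=1$, symmetry, and monotone decay: Gaussian
$e^{-x^2/2}$, Epanechnikov, and uniform.  The Epanechnikov kernel is used
in its rescaled form $K(x) = (1-x^2)$ on $|x|\le 1$ so that it satisfies
the $K(0)=1$ axiom shared by the other kernels; since the moment formulas
are scale invariant in the weights, relative weighting — and hence every
estimate — is unaffected by this normalization.  The bandwidth follows
$bw = h\,N^{-1/5}\sigma_A$.  The default bandwidth factor is $h = 2$,
which our recovery simulations (consistent with the published
recommendation for this estimator class) favor over the classical
density-estimation value $h = 1.1$ that remains available.  The default
grid places `min(13, #distinct)` equidistant points between the 5th and
95th percentile of the moderator; explicit grids and percentile grids are
supported.  Focal points whose weight mass $W_t$ falls below `wt_min`
(default $5I$) are dropped with a warning — below that mass an $I \times
I$ covariance matrix is not reliably estimable.  The focal-point density
$\hat f(a_t) = W_t / \sum_s W_s$ weights all curve summaries; for a
continuous moderator this $W_t$-normalization is our documented choice of
a "discrete density" at the grid.

## Pointwise, joint, MGM, and DIF estimation

*Pointwise* estimation minimizes $D(\hat\Sigma_t, \Sigma_t(\theta_t))$
independently per focal point and reports per-focal-point fit statistics.
*Joint* estimation minimizes $\sum_t W_t D(\hat\Sigma_t, \Sigma_t(\theta_0,
\theta_t))$ in a single problem whose groups are the focal points,
weighted by $W_t$; the block $\theta_0$ is constrained equal across focal
points (`par_invariant`).  With no invariant parameters the joint
objective separates and the two modes coincide — a property the test
suite checks to $10^{-5}$.  Because subjects enter several focal points,
the joint objective is an M-estimation criterion rather than a true
likelihood; consequently no standard errors are taken from its
information matrix — inference is resampling-based only — and the global
fit statistics, computed with effective sample size $\sum_t W_t$, are
labeled approximate.

`type = "mgm"` discretizes the moderator (distinct values when few,
equal-frequency bins otherwise) and fits a classical multiple-group
model through the same engine.  On grid-valued moderators, a uniform
kernel with $bw = \Delta/2$ makes LSEM and MGM identical when the same
identification is used.

Polynomial constraints (`par_linear`, `par_quadratic`, piecewise
variants) encode equality of first- or second-order differences of a
parameter across equidistant focal points.  They are realized by
reparameterizing the per-focal-point values onto a polynomial basis in
the (centered, scaled) focal position — a truncated-power spline basis
when piecewise, with continuity at the equally spaced knots shared
between segments.  Because the difference constraints act on natural
parameter values, variance parameters under such constraints are *not*
log-transformed (see below); admissibility is then monitored rather than
enforced.

DIF (differential item functioning) effects answer "what would an
invariant parameter look like if freed?": with all focal-point-specific
parameters fixed at their joint estimates, the invariant block is freed
per focal point and the discrepancy re-minimized.  The problem separates
over focal points; it is solved as one masked optimization over the freed
coordinates.  DIF curves reuse the (possibly PD-repaired) conditional
covariance matrices of the main fit.

Identification defaults to a unit first loading per factor.  All-loading
invariance via `par_invariant` is the second standard option; a pointwise
average-loading constraint can be expressed through the constraint system
but is not a packaged default.

## The fitting engine

No SEM package is a dependency: the multi-group discrepancy, its analytic
gradient, and its expected-information (Gauss-Newton) Hessian are
implemented in compiled code over a sparse map from matrix cells to
working parameters (free per group, shared across groups, or polynomial
basis coefficients).  `nlminb` then takes Newton steps; on failure the
fit restarts quasi-Newton and with jittered starts (three attempts)
before reporting non-convergence — never silently.  Convergence demands a
gradient max-norm below $10^{-6}$ per unit of group weight.  Start
values: free loadings 0.7, variances half the relevant sample diagonal,
covariances and structural coefficients 0.  Plain free variances are
log-parameterized internally so bootstrap replicates cannot step into
inadmissible regions; results are reported on the natural scale.
Warm starts are used in two places: resampling replicates start from the
original solution, and pointwise fits pass the previous focal point's
solution along the grid.  Because a warm start can land in a different
basin of a just-identified problem, pointwise fits also try the default
start and keep the lower optimum.

Fit statistics follow the standard ML conventions: the chi-square
analogue is the weighted discrepancy at the minimum; RMSEA uses
$\sqrt{\max(0, (\chi^2 - df)/(df\,n_{\mathrm{eff}}))}$; SRMR is the root
of the group-weighted mean squared correlation-metric residual (diagonal
included); CFI and TLI are computed against the diagonal-covariance
independence baseline and clamped at 1; GFI is the trace-ratio form
averaged over groups.  The standardized solution is fully standardized:
factor covariances become correlations (total, i.e. reduced-form, factor
variances when structural paths are present), loadings are scaled by
factor SD over indicator SD.

## Inference on parameter curves

A curve is summarized by $\hat M = \sum_t \hat f(a_t)\hat\theta(a_t)$ and
$\widehat{SD} = (\sum_t \hat f(a_t)(\hat\theta(a_t) - \hat M)^2)^{1/2}$.
$\widehat{SD}$ is positively biased under no variation, so the
nonparametric bootstrap (subjects resampled with replacement; whole
clusters when a cluster structure is declared; or arbitrary replicate
weight matrices with a user `repl_factor` for jackknife-type designs)
provides $\widehat{SD}_{bc} = \sqrt{\max(0,\, 2\widehat{SD}^2 -
\overline{SD^{*2}})}$ and its standard error.  The SD test
$t = \widehat{SD}_{bc}/SE$ is referred to the one-sided upper normal tail
— our choice, since curve variability is a one-directional alternative
and SD is nonnegative; the normal reference is known to be approximate
and the simulation harness quantifies its inflation.  The Wald test uses
$\chi^2 = (H\hat\xi)^\top (HVH^\top)^{-1} H\hat\xi$ with the
first-difference contrast matrix $H$ and the replicate covariance
$V = c\sum_r (\xi^*_r - \bar\xi^*)(\xi^*_r - \bar\xi^*)^\top$,
$c = 1/R$ for the bootstrap; the statistic is invariant to the choice of
full-rank contrast basis, and a singular $HVH^\top$ falls back to a
pseudo-inverse with rank-adjusted degrees of freedom.  The functional
Wald variant regresses the curve on polynomial terms of the moderator by
generalized least squares and tests the non-intercept block.  The
permutation test shuffles the moderator column, re-estimates everything,
and uses the add-one convention
$p = (1 + \#\{SD^* \ge \widehat{SD}\})/(B+1)$.  Replicates that fail to
converge are dropped and counted; more than 20% failures abort.

## The synthetic-data generators

`lsemDGM()` provides three invariance profiles on a default grid of 13
moderator values (ages 6–18), mirroring the canonical study conditions
for this estimator family: `dgm1` varies loadings, factor variances and
the factor correlation (residual variances constant); `dgm2` holds the
measurement model invariant and varies only the structure; `dgm3` is the
fully invariant null.  The exact generating values are the package's own
documented choices, fixed once: anchor loadings 1 (so generating curves
live in the fitted identification), free loadings moving linearly within
0.5–0.9, factor variances $0.5 \pm 0.15u$ and $0.6 \mp 0.15u$ for
$u = (a-12)/6$, factor correlation 0.4–0.75, residual variances 0.5, and
(in `dgm1` only) a mild linear mean trend that exercises the
residualization step.  `makePopulation()` makes the per-moderator sample
moments *exactly* equal to their targets by whitening a normal draw with
the Cholesky factor of its own sample covariance and recoloring with the
target's — so local moments with a uniform half-spacing kernel reproduce
the generating $\Sigma(a)$ to numerical precision and estimator recovery
can be tested without sampling noise.  Default population size is 10,000
per moderator value; tests use smaller groups, which preserves exactness.

What the generator does *not* emulate: non-normal indicators, missing
data mechanisms, cluster dependence, moderator measurement error, and
continuous (non-grid) moderator distributions.  Passing recovery and
size checks on these populations therefore demonstrate correctness of
the estimator and test machinery under ideal distributional conditions,
not robustness to real-data violations.

## Simulation harness and problem sizes

`runRecoveryStudy()` reports pointwise bias, the density-weighted
absolute bias $\sum_t f(a_t)|Bias(\hat\theta(a_t))|$, and the weighted
pointwise RMSE for the factor variance, an invariant loading, and its DIF
effect.  `runSizePowerStudy()` reports rejection rates of the SD and Wald
tests (factor variance, DIF effects, residual variances; also pooled) and
the mean raw and bias-corrected SD.  The packaged test suite runs the
recovery study at 120 replications over $N \in \{250, 500, 1000, 2000\}$
and the null size study at 200 replications with 60 bootstrap replicates
at $N = 500$; the acceptance script runs the size study at the full
canonical condition (500 replications, 100 bootstrap replicates,
$N = 1000$, population groups of 10,000).  These sizes were chosen so the
whole validation runs on a single desktop core in minutes; Monte Carlo
standard errors at these sizes are reflected in the test tolerances.

With these conditions the harness reproduces the qualitative conclusions
that motivate the method's inference recommendations: the raw curve SD is
inflated under the null while the bias-corrected SD is pulled toward
zero; the bias-corrected-SD test at a nominal 1% level rejects at roughly
the 5% level; and the bootstrap Wald test is conservative.  Hence the
practical advice embodied in the defaults: for a target 5% level, run the
SD test at 1%.

## Numerical choices and known limitations

* Optimizer tolerances: `nlminb` relative tolerance $10^{-12}$, gradient
  max-norm $10^{-6}\cdot\max(1, \sum_g N_g)$, at most 1000 iterations,
  three restarts.
* The PD-repair floor ($10^{-4}$ relative), the $W_t$ floor ($5I$), and
  the SD noise floor ($10^{-10}$, below which a constrained-invariant
  curve is reported as exactly flat) are fixed constants, not tuning
  knobs.
* Sampling weights fuse multiplicatively with kernel weights — a
  documented choice; no established convention exists for the
  combination.
* Joint-estimation fit indices depend on the pseudo sample size
  $\sum_t W_t$ and on our baseline convention; they are comparable within
  an analysis, not across software.
* The kernel-smoothed curve is attenuated near the grid edges (one-sided
  weighting), so curve-SD statistics slightly understate edge-driven
  variation; bias-corrected SDs inherit this.
* Two-moderator models, categorical indicators, robust/WLS discrepancies,
  analytic (sandwich) standard errors, and error-in-moderator corrections
  are out of scope.
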