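---
title: "Noise-driven causal inference from snapshot covariance elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise-driven causal inference from snapshot covariance elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(induceR)
```

## The problem

Destructive single-cell assays — flow cytometry, mass cytometry,
immunofluorescence imaging — measure many cells once, so they give
per-condition *distributions* of molecular abundances but no time series.
Classical causal-inference tools built on temporal precedence (lagged
correlations, Granger tests) are unavailable. Yet the data are far from
uninformative: single-cell abundances fluctuate stochastically, and
fluctuations propagate *directionally* through a regulatory network — a
target inherits its regulator's noise, not vice versa. induceR implements a
method (INDUCE, Inference of Network Directionality Using Covariance
Elements) that turns this asymmetry into a directed causal call with a
p-value, using only snapshot covariance matrices measured along an ordinary
dose-response experiment.

## The stochastic model

Fluctuations around a stationary operating point are modeled by a linear
multivariate Langevin (Ornstein–Uhlenbeck) process,

$$\frac{d\mathbf{x}}{dt} = \mathbf{A}\,\mathbf{x} + \mathbf{Q}\,\boldsymbol\xi(t),$$

where $\mathbf{x}$ collects deviations from the mean, $\mathbf{A}$ is the
network connectivity ($A_{ji}$ = rate of change of species $j$ per unit
deviation of species $i$), $\mathbf{Q}$ sets the white-noise magnitudes,
and $\boldsymbol\xi$ is delta-correlated white noise. Stationarity ties the
three matrices together through the Lyapunov equation

$$\mathbf{A}\Sigma_0 + \Sigma_0\mathbf{A}^{\mathsf T} + \mathbf{Q}\mathbf{Q}^{\mathsf T} = 0,$$

with $\Sigma_0$ the stationary covariance (`solve_lyapunov()`,
a direct dense solve appropriate for 2–4 node motifs, residual checked
against $10^{-8}$). Because the $N(N{+}1)/2$ Lyapunov constraints cannot
determine the $N^2$ entries of $\mathbf{A}$, a single covariance matrix is
consistent with a whole family of connectivities,
$\mathbf{A} = (-\tfrac12\mathbf{Q}\mathbf{Q}^{\mathsf T} + \mathbf{U})\,\Sigma_0^{-1}$
for any antisymmetric $\mathbf{U}$ (`network_from_U()`) — this is exactly
why a *single* snapshot cannot identify causality. The symmetric
thermal-equilibrium special case, where the covariance does identify the
network, is provided as `thermal_network()`; its noise intensity carries
the fluctuation–dissipation factor,
$\mathbf{Q}\mathbf{Q}^{\mathsf T} = 2 k_BT\,\mathbf{I}$, which is the
strength required for the Lyapunov equation to return $\Sigma_0$.

Measured abundances are heavily right-skewed and well approximated as
lognormal, and their fluctuations do not vanish at high copy number, so the
dynamical variables are *log* concentrations: writing $\delta y_j$ for the
log deviation of species $j$ from its mean,

$$\frac{d\,\delta y_j}{dt} = \sum_{i\neq j} a_{ji}\,\delta y_i - \lambda_j\,\delta y_j + q_j\,\epsilon_j,$$

with $\lambda_j$ the decay rate, $q_j$ the intrinsic log-noise magnitude,
and the connection strength the local log-gain of the production rate
$f_{ji}$ (a Hill function of the regulator concentration $x_i$):

$$a_{ji} = \lambda_j \left.\frac{\partial \ln f_{ji}}{\partial \ln x_i}\right|_{x_i = \langle x_i\rangle}.$$

For an activating Hill edge with coefficient $n$ and half-response $K$ this
gain is $\lambda n K^n/(K^n + x^n)$ — maximal at low occupancy and vanishing
at saturation; for the repressive (decreasing) Hill form the calculus gives
$-\lambda n\,x^n/(K^n+x^n)$. Note that the gain is *not* the slope of the
dose-response plot: the slope of the response against log input,
$\partial f/\partial\ln x = n f (1 - f/\nu)$ (`transfer_slope()`), peaks
exactly at half-maximal activation $x = K$ for every $n$, which is why a
dose-response experiment modulates the interaction most effectively through
the middle of its dynamic range.

## The two-node signature

For an isolated directed edge $1 \to 2$ with equal decays $\lambda$ and
diagonal noise, the Lyapunov equation has the closed-form solution
(`two_node_covariance()`)

$$\sigma_1^2 = \alpha,\qquad
  \sigma_{12} = \frac{\alpha k}{2\lambda},\qquad
  \sigma_2^2 = \beta + \frac{\alpha k^2}{2\lambda^2},$$

with $\alpha = q_1^2/2\lambda$ and $\beta = q_2^2/2\lambda$ the
connectivity-independent noise floors and $k$ the connection strength.
Eliminating $k$:

$$\boxed{\;\sigma_2^2 = \beta + \frac{2\sigma_{12}^2}{\alpha},\qquad
  \sigma_1^2 = \alpha \text{ (constant)}\;}$$

Sweeping $k$ with a dose therefore traces a parabola in the
$(\sigma_{12}, \sigma_2^2)$ plane while $\sigma_1^2$ stays put — and the
roles reverse if the edge points the other way. That asymmetry is the
entire inferential signal: the *direction* of an edge is encoded in *which*
variance moves with the covariance.

```{r two-node-path}
ex <- example_motifs()$two_node_activation
tr <- motif_trajectory(ex$motif, ex$doses, ex$drive)
plot(tr$sigma12, tr$sigma22, pch = 16, xlab = "Cov(S, T)",
     ylab = "variance", ylim = range(c(tr$sigma11, tr$sigma22)))
points(tr$sigma12, tr$sigma11, pch = 1)
legend("topleft", pch = c(16, 1), legend = c("Var(T): quadratic",
                                             "Var(S): constant"), bty = "n")
```

Three-node motifs are handled numerically by the same machinery
(`motif_trajectory()` linearizes at each dose and solves the Lyapunov
equation; the convergent motif's covariance is computed this way rather
than from a closed form, which is exact for the linear model). When two
noise sources with *disparate dose sensitivities* feed the measured pair —
convergent regulation, or a cascade through an unmeasured upstream node —
the variance-vs-covariance path can fail to be single-valued. Such an
"open loop" (`detect_open_loop()`) is sufficient evidence for an unmeasured
upstream noise source, though its absence proves nothing: most cascade
parameterizations are indistinguishable from an isolated edge. Loop
detection compares the path against its own best-fit quadratic and fires
when two points with nearly equal covariance (within 2% of the covariance
range) have fit residuals differing by more than 5% of the variance range;
both tolerances are arguments. Residuals-about-the-quadratic, rather than
raw variance gaps, make the detector exact on single-valued quadratic
paths, so steeply curved two-node sweeps cannot false-positive.

## The synthetic-data generator

`simulate_ensemble()` draws per-dose single-cell ensembles directly from
the stationary law: log deviations from the zero-mean multivariate normal
with the analytic per-dose $\Sigma_0$, shifted by the log means and
exponentiated. This is justified by the ergodic assumption — a snapshot of
many clonal cells equals one cell observed over time at stationarity — and
makes marginals exactly lognormal. The default study design mirrors the
flow-cytometry scale of the validation experiments: 23 doses spanning the
transfer function's dynamic range on a log grid, $10^4$ cells per dose,
decay rates $\lambda = 1$ (time is measured in units of the protein
lifetime), and noise floors $\alpha = 0.04$, $\beta = 0.02$ (log-scale
standard deviations of 0.2 and 0.14, typical coefficients of variation for
fluorescence readouts). A master seed deterministically spawns per-dose
streams, so datasets are reproducible dose by dose.

The second route, `simulate_sde()`, integrates the log-deviation SDE by
Euler–Maruyama and cross-validates the whole linearization chain: its
stationary covariance must match the Lyapunov solution (it does, to within
Monte-Carlo error at the default step), and temporal statistics of one long
trajectory (`simulate_sde_trajectory()`) must match ensemble statistics —
the ergodicity the direct route assumes. The step-size guard requires
`dt < 0.1 / max rate`; at `dt` a fraction of the fastest timescale the
$O(dt)$ discretization bias of the stationary variance is well below the
Monte-Carlo tolerance used in the tests.

What the generator deliberately does *not* emulate: discrete-molecule
(chemical-master-equation) noise — the model absorbs low-copy effects into
the dominating rate-constant fluctuations; dose-dependent noise magnitudes
(the theory assumes $\mathbf{Q}$ independent of the ligand; an optional
multiplicative measurement-noise factor is available, off by default);
instrument artifacts such as compensation spillover, autofluorescence
baselines, debris and doublet events. Passing tests on synthetic data
therefore validate the estimation machinery under the model's own
assumptions, not robustness to every cytometry pathology.

## The estimation pipeline

Given an event table (one row per cell: dose, species intensities in
linear scale), `run_induce()` composes:

1. **Transfer fits** (`fit_transfer()`): Hill fits to each species'
   dose-wise mean log response (both orientations tried, better SSE kept;
   a Levenberg–Marquardt fit with a simplex fallback for responses that
   are not exactly Hill in dose). The target-vs-source slope sign records
   activation vs repression; a target log-response range under 0.1 flags a
   degenerate (flat) dataset.
2. **Normalization** (`normalize_dataset()`): intensities divided by the
   source's fitted $K$ and the target's fitted amplitude $\nu$, then logged.
   The division is a pure shift in log coordinates, so every covariance
   element is invariant to it; nonpositive events (possible after
   compensation) are dropped and counted.
3. **Per-dose covariance** (`dose_covariances()`): the maximum-likelihood
   bivariate-normal fit (sample mean and denominator-$n$ covariance), with
   element-wise uncertainties from 1000 within-dose bootstrap resamples.
4. **Constrained two-node fits** (`fit_two_node()`) in both directions:
   least squares over doses of $\{\sigma_{\mathrm{src}}^2 = \alpha$,
   $\sigma_{\mathrm{tgt}}^2 = \beta + 2(\sigma_{12}-c_0)^2/\alpha\}$, both
   residual streams entering jointly. $\alpha > 0$ is enforced by
   log-parameterization started from the median source variance, then
   polished on the analytic stationarity condition. The covariance offset
   $c_0$ is an optional third noise parameter (`third_param = TRUE`,
   default off) absorbing a dose-independent covariance component;
   inverse-bootstrap-variance weighting is likewise optional
   (`weights = "bootstrap"`), with unweighted least squares the default.
5. **The statistical test** (`compare_directions()`): per-dose fit errors
   $\epsilon_i = \Delta\mathrm{Var}_1^2 + \Delta\mathrm{Var}_2^2$
   (`fit_error()`) are compared between the two directed models by the
   paired Wilcoxon signed-rank test. The null "both models fit equally
   well" is tested two-sided at $\alpha = 0.05$ (configurable); if
   rejected, the model with consistently smaller errors is favored and its
   one-sided p-value reported. The p-value is *exact* up to $N = 25$
   pairs — the full sign-assignment null distribution is enumerated by
   convolution, with zeros dropped and average ranks for ties — and a
   tie-corrected normal approximation with continuity correction beyond.
   With 23 doses all favoring one direction the one-sided floor is
   $2^{-23} \approx 1.2\times10^{-7}$.
6. **Regulation sign**: activation vs repression is called from the sign
   of the bootstrap-precision-weighted sum of per-dose covariances
   $\sum_d \hat\sigma_{12,d}/\mathrm{sd}_d$, which concentrates the call
   on the doses where the covariance is well determined (the dynamic
   range) without a hard gate on which doses count.

```{r pipeline, eval = FALSE}
ds <- simulate_ensemble(ex$motif, dose_design(ex$doses, n_cells = 1e4,
                                              seed = 7), ex$drive)
run <- run_induce(ds, source = "S", target = "T", bootstrap = 1000, seed = 7)
run
```

## Numerical and design choices

* **Lyapunov solver**: direct dense Kronecker-vectorized solve —
  exact to round-off at these dimensions; stability is gated at
  $\max\mathrm{Re}\,\mathrm{eig}(\mathbf{A}) < -10^{-10}$, separating
  marginal from stable at double precision. Solutions are symmetrized so
  symmetry is exactly assertable, and positive semidefiniteness is checked
  to a $10^{-10}$ relative eigenvalue tolerance. The matrix exponential
  (lagged covariances, oracles) uses scaling-and-squaring.
* **Steady states** along a dose sweep come from damped fixed-point
  iteration on the linear-scale rate balance $f = \lambda x$ (tolerance
  $10^{-12}$); the supported motifs are feedback-free, where this always
  converges.
* **Convergent regulation** sums contributions in log-deviation
  coordinates, $\sum_{i\neq j} a_{ji}\,\delta y_i$ — i.e. regulators
  combine additively in the linearized log dynamics. Whether "additive"
  co-regulation should instead sum production rates in linear scale is
  ambiguous at the level of the linearized theory; the log-deviation
  convention is the one consistent with the dynamical equation above.
* **Repression** is encoded as a decreasing Hill form with a negative
  gain, keeping the Hill coefficient positive and testable.
* **Two-stage testing** (two-sided gate, then one-sided headline p) keeps
  the reported p-value interpretable as confidence in the *favored*
  direction while refusing a call when neither model wins.
* **Example parameterizations** (`example_motifs()`) are the package's
  own: the qualitative trajectory shapes (constant source variance,
  quadratic target variance, open loops for suitable cascades) are the
  claims being illustrated, not any specific published parameter set. The
  cascade entry uses a double-repression chain with disparate
  half-responses, a slow target and a noisy unmeasured source, chosen
  because it opens loops in both variance-covariance planes.

## Problem sizes used in the checks

The shipped verification suite exercises the study design at its native
scale — 23 doses $\times\,10^4$ cells for parameter recovery and the
power/calibration simulations (200 directed and 1000 null datasets),
$2\times10^4$ cells per Euler–Maruyama snapshot, a $2000$-lifetime single
trajectory for the ergodicity check, and 50 seeded runs for the
regulation-sign rule. Bootstrap depth is reduced from the default 1000 to
200 resamples where only the sign-weighting uses it.

## Known limitations

* The theory is a linearization around a stationary operating point; cells
  far from steady state (transient stimulation) violate it.
* $\mathbf{Q}$ is assumed dose-independent. A ligand that directly
  modulates noise magnitudes can mimic or mask directional signatures; the
  package does not implement a criterion to rule this out.
* Feedback motifs are out of scope; the two-node comparison presumes the
  measured pair is, from the noise-propagation viewpoint, effectively
  isolated. Open-loop detection flags one observable violation but its
  absence is not a proof of isolation.
* The exact test's floor $2^{-N}$ bounds attainable significance: with few
  doses even a perfect win cannot produce a very small p-value.
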