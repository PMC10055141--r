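---
title: "Network control energy of transitions between cortical activation states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network control energy of transitions between cortical activation states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nctr` models the cortex as a linear time-invariant network control system
and asks how much input energy is needed to steer it from one regional
activation pattern to another over a structural connectome. This vignette
is the package's own account of the model, the numerical choices behind the
implementation, and what the synthetic test bed does and does not show
about real neuroimaging data.

## The model

A brain state is a vector $x(t) \in \mathbb{R}^N$ of regional activation
values. Its evolution is linear in the state and in the control input:

$$\dot{x}(t) = A\,x(t) + B\,u(t),$$

where $A$ is the weighted structural connectome and $B = \mathrm{diag}(b)$
places input gains on regions. Because raw connectome weights are on an
arbitrary scale, $A$ is first normalized,

$$A_{\mathrm{norm}} = \frac{A}{\lambda_{\max}(A) + c} - I,$$

so the dynamics cannot blow up over the horizon. With $c = 0$ (the
default) the largest mode of $A_{\mathrm{norm}}$ is exactly zero and the
system drifts toward its dominant eigenvector; with $c > 0$ every mode
decays. The alternate setting $c = 0.01\,\lambda_{\max}$ is accepted
everywhere the default is (`normalize_adjacency(x, c = "0.01lmax")`).

The transition cost from a source state $x_0$ to a target $x_T$ over
horizon $T$ is defined by the optimal control problem

$$u^* = \arg\min_u \int_0^T \big[(x_T - x(t))^\top (x_T - x(t))
      + \rho\, u(t)^\top u(t)\big]\,dt,$$

subject to the dynamics and the boundary conditions $x(0) = x_0$,
$x(T) = x_T$. The first term penalizes trajectories that wander far from
the target; $\rho$ prices the input. The reported **transition energy** is
$E = \sum_k \int_0^T u_k(t)^2\,dt$, the unweighted integral of squared
inputs summed over controlled regions (per-node integrals are retained in
`solve_optimal_control()` output for diagnostics). The cost functional
keeps $\rho\,u^\top u$ on the raw input even when $B$ is heterogeneous, so
higher-gain regions achieve more state change per unit cost — that is
exactly how receptor- or disease-derived weightings are meant to act.

Defaults are $T = 1$, $\rho = 1$, $c = 0$, uniform $B = I$; $T = 3$ is a
supported replication setting.

## How the solver works

The Hamiltonian of the problem gives the stationarity condition
$u^*(t) = -\tfrac{1}{2\rho} B^\top \lambda(t)$ and a linear two-point
boundary-value problem in the state and costate:

$$\frac{d}{dt}\begin{bmatrix} x \\ \lambda \end{bmatrix} =
\begin{bmatrix} A & -BB^\top/(2\rho) \\ -2I & -A^\top \end{bmatrix}
\begin{bmatrix} x \\ \lambda \end{bmatrix} +
\begin{bmatrix} 0 \\ 2 x_T \end{bmatrix}.$$

Because the affine term is constant, the target is appended as $N$ frozen
states, giving a $3N \times 3N$ generator whose matrix exponential evolves
the joint system *exactly* at the grid times — there is no ODE-stepper
truncation error, only quadrature error in the energy integral.
$\lambda(0)$ comes from the linear system enforcing $x(T) = x_T$; its
condition number is checked (warning above $10^{10}$, error above
$10^{14}$), and the terminal state is verified against `reach_tol`
(relative $10^{-6}$).

Two numerical parameters matter:

* `n_steps` (default 1000, minimum 100) — trapezoidal quadrature
  intervals for $\int u^2 dt$. The trajectory itself is exact at the grid
  points, so `n_steps` only controls quadrature resolution; against an
  independent direct-transcription solve of the same problem the default
  grid agrees to a few parts in $10^4$.
* `reach_tol` (default $10^{-6}$, relative) — terminal accuracy guard.

For all-pairs energy matrices the package exploits linearity: for a fixed
(system, $T$, $\rho$, $b$) configuration the energy is the quadratic form
$E(x_0 \to x_T) = [x_0; x_T]^\top W [x_0; x_T]$, with $W$ accumulated once
from the block exponential on the same grid. This is algebraically
identical to integrating $u^\top u$ along each pair's optimal trajectory
(the test suite asserts agreement with per-pair solves to $10^{-8}$) but
makes a $K \times K$ matrix cost $O(N^3\,n_{\text{steps}} + K^2 N)$
instead of $K^2$ full solves. Self-transitions (the diagonal) are
computed, not skipped: holding a non-equilibrium state costs energy, and
only the dominant eigenvector (under $c = 0$) is free to hold.

## Transition statistics

* **Asymmetry**: $\mathrm{asym}(i,j) = E(i \to j) - E(j \to i)$; a
  target's *net score* averages this over sources. Positive = harder to
  reach than to leave.
* **Source versus target variability**: the implementation names the two
  SD samples by what varies — `sd_across_targets` (row-wise: for each
  source, SD over its $K-1$ targets) and `sd_across_sources`
  (column-wise). The pooled two-sample $t$ (df $= 2K - 2$) is oriented so
  that a *positive* $t$ means the identity of the target drives
  cost variability more than the identity of the source, which is the
  direction of interest. When both SD samples are identically zero the
  result is flagged degenerate rather than reported.
* **Indirect transitions**: for each ordered pair, whether some
  intermediate state gives $E(i \to k) + E(k \to j) < E(i \to j)$.
* **Domain permutation test**: a domain's statistic is the median net
  score of its terms; the null permutes domain labels among labeled
  terms. One-sided $p$ with the $+1$ correction, so no finite run reports
  $p = 0$.

Where sidedness is not forced by the construction, every null comparison
is one-sided in the direction of the stated hypothesis (empirical energy
*below* nulls; domain medians *above* chance) and the z-score is reported
alongside so the magnitude is never hidden by the sidedness choice.

## Null models

**Degree-preserving rewiring** uses double-edge swaps; weights travel with
their edges, so the binary degree sequence and the weight multiset are
preserved *exactly* (both are asserted for every surrogate in the test
suite, 100 realizations per kind). Graphs admitting no valid swap (stars,
complete graphs) are returned unchanged with a warning rather than
spinning forever.

**Geometry-preserving rewiring** additionally constrains the binned
edge-length histogram: a swap is accepted only if every distance-bin count
stays within `bin_tolerance` (default 20%, with a one-edge slack for tiny
bins) of the original. Bins are length quantiles (default 10; merged with
a warning below 5 edges per bin). After the topology phase, the original
weight multiset is reassigned to the new edges by length rank and then
shuffled within bins — the global multiset is exact, the weight–length
relationship is preserved at bin resolution, and within-bin structure is
randomized. Bin count and tolerance are exposed because the cited
rewiring strategy fixes neither.

**Spin surrogates** rotate parcel positions on the sphere: one uniform
random rotation for the left hemisphere, its mirror image for the right,
then each original parcel takes the value of the nearest rotated parcel by
great-circle distance. This preserves the value distribution and the
spatial autocorrelation while destroying the anatomical alignment.
Nearest-neighbor assignment can repeat values; a bijective
(greedy closest-pair) variant is available where exact permutations are
needed. Surrogate ensembles accept an explicit rotation list, which makes
degenerate cases (identity rotation) testable.

## Heterogeneous control inputs

* Disease maps enter as gains $1 + d$ (Cohen's d of cortical-thickness
  abnormality): atrophied regions inject less, thickened regions more.
  Values $d \le -1$ are rejected. For maps in the envelope
  $d \in (-0.6, 0.9)$ the gains stay in $(0.4, 1.9)$.
* Receptor maps are min-max scaled and added to the uniform gains, so
  gains lie in $[1, 2]$ and are invariant to affine rescaling of the
  tracer units.

Each empirical map is compared against spin surrogates *of itself passed
through the same gain construction*, so the gain distribution is held
fixed and only the anatomical placement varies. Disease maps are
summarised as per-target z-scores of mean reach energy; receptor maps as
facilitation percentages. Whether "facilitated" should be judged against
each surrogate individually or against a null summary is not forced by
the analysis definition, so the per-(transition, surrogate) comparisons
are pooled within target *and* the full per-transition table is emitted —
either reading can be reproduced from the output.

## Network variance and predictors

Effective resistance
$\omega_{ij} = (e_i - e_j)^\top L^+ (e_i - e_j)$ is computed from the
eigendecomposition of the Laplacian with a relative eigenvalue cutoff of
$10^{-10}$ defining the null space — robust for nearly disconnected
graphs, and verified in tests against the Foster identity
($\sum_{\text{edges}} w_{ij}\omega_{ij} = N - 1$), the triangle
inequality, and closed forms on fixture graphs. Commute time
($\mathrm{vol}(G)\,\omega$) is provided as a cross-check and is tested
against mean first-passage times of the explicit random-walk chain.

The network variance of a map is
$\mathrm{var}(p) = \tfrac{1}{2}\sum_{ij} p(i)p(j)\,\omega_{ij}$ after the
map is shifted to minimum 0 and normalized to sum 1. The printed form of
this measure leaves open whether $\omega$ or $\omega^2$ plays the role of
squared distance; following the measure's originators, who recommend
resistance distance as the natural metric for distributions on graphs,
$\omega$ itself is used, and this convention is documented rather than
configurable.

**Dominance analysis** fits OLS on all $2^p - 1$ predictor subsets and
averages incremental $R^2$ size-stratified (Budescu): first within each
submodel size, then across sizes. Under this averaging the general
dominances sum *exactly* to the full model's unadjusted $R^2$ (asserted to
$10^{-10}$), which is why unadjusted $R^2$ is used internally; an
adjusted-$R^2$ rescaling is available for display with the documented
caveat that the exact identity applies to the unadjusted quantity. A
uniform average over all submodels is available behind a flag; the
one-line description "across all $2^p-1$ submodels" is ambiguous between
the two, and the size-stratified form was chosen because it alone carries
the sum identity. The predictor set entering the dominance model is
likewise configurable — the pipeline default uses map mean, map SD,
network variance, and the strength and participation correlations.

## The synthetic test bed

The generator produces the three data families the analysis consumes,
with the statistical structure the real data are known to have:

* `synth_connectome()` — 68 nodes (a whole-cortex parcellation scale) on
  two lateralized spherical caps of radius 70 mm, edge density 0.27, edge
  probability and weight decaying exponentially with distance
  (`decay_length` 35 mm, a typical wiring-cost scale), connectivity
  guaranteed by a distance-MST backbone. This yields the strong negative
  weight–length correlation and geometric clustering that the null-model
  comparisons depend on.
* `synth_state_maps()` — white noise diffused by a graph heat kernel
  (`smoothness` 2 by default; 0 gives i.i.d. maps), then rescaled to
  per-map means in $[0, 2]$ and SDs in $[0.5, 1.5]$, emulating the
  heterogeneous means/SDs of meta-analytic activation maps. Graph
  diffusion rather than Euclidean-kernel smoothing is used so spatial
  structure is defined even for abstract test graphs.
* `synth_annotation_maps()` — nonnegative receptor-like maps and
  disease-like Cohen's d maps clipped to $(-0.6, 0.9)$, with a
  hub-concentrated variant for spatial-specificity checks.

What the synthetic bed reproduces: the *directional* findings — energy
tracks state distance; variability is target-driven when target means are
heterogeneous; the geometric connectome supports cheaper transitions than
degree-preserving rewirings, with geometry-preserving nulls in between;
uniform gain increases always reduce energy. What it does not reproduce:
the magnitudes tied to the empirical connectome and map corpus (the
specific $t$, fold-range, or fraction values), hemispheric asymmetries,
community structure, or the heavy-tailed weight distribution of
streamline counts. Passing tests here validate the machinery and the
directions, not dataset-specific numbers.

## Problem sizes and runtime choices

Single solves default to `n_steps = 1000`. The repeated-ensemble runs
(null comparisons, spin sweeps) use `n_steps = 200` and 20-state sets:
the quadrature error this introduces is orders of magnitude below the
between-surrogate spread being measured, and it keeps a full
10-seed, 50-null directional study in the few-minute range on one core.
Ensemble sizes follow the same logic: 50 rewired nulls and 100 spin
rotations are pipeline defaults (study-scale analyses used 500 and
10 000; both are plain arguments). The domain permutation default stays
at 1000.

## Known limitations

* The dynamics are linear, noise-free, and time-invariant; the package
  deliberately does not implement stochastic or nonlinear extensions.
* Minimum-energy (Gramian-only) control without the trajectory-distance
  term is out of scope, as are directed connectomes.
* The spin test requires spherical coordinates and hemisphere labels; no
  variogram-matching surrogate fallback is provided — without spherical
  coordinates the error message points to the value-permutation
  alternative.
* Nearest-neighbor spin assignment resamples values, so ensemble means
  wander around the empirical map mean (the empirical mean sits well
  within the ensemble spread; exact mean preservation requires the
  bijective variant).
* Participation coefficients use weighted strengths, not binary degree,
  because the connectomes of interest are weighted; isolated nodes would
  get participation 0 with a flag, though the connectome constructor
  rejects disconnected graphs outright.
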