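---
title: "Minimum free energy paths with mfepath: models, estimators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum free energy paths with mfepath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfepath)
```

## The problem

Large conformational transitions — a protein domain closing over a ligand,
a molecule hopping between metastable states — are rare events on the
timescale of direct simulation.  A productive strategy is to describe the
transition in a small set of collective variables (CVs), locate the
*minimum free energy path* (MFEP) connecting the two end states on the free
energy surface over those CVs, and then characterize the thermodynamics
(potential of mean force, PMF) and mechanism (fluctuations, solvent
densities, committor probabilities) along that path.

`mfepath` implements this entire workflow for *linear* CV maps — orthonormal
projections of configuration space, such as principal components of Cα
coordinates — in an engine-agnostic way.  The sampling layer shipped with
the package is an overdamped Brownian integrator on analytic model
potentials; every estimator downstream consumes only configurations, CV
values and reduced potentials, so archives from any sampling engine can be
substituted.

## The string method in CV space

The path is discretized into $N$ images $z_\alpha \in \mathbb{R}^M$.  Each
image carries a persistent walker sampling the restrained Boltzmann density
$\propto \exp\{-\beta[U(x) + \tfrac{\kappa}{2}\lVert\theta(x) -
z_\alpha\rVert^2]\}$, where $\theta$ is the CV map and $\kappa$ a stiff
spring.  For stiff $\kappa$ the mean restraint force estimates the negative
free-energy gradient,
$\kappa\,(\langle\theta(x)\rangle_{z} - z) \approx -\nabla F(z)$,
and the images drift down that gradient:

$$ z \leftarrow z + \frac{\Delta t_z}{\gamma}\,\kappa\,(\bar\theta - z), $$

with $\gamma$ a friction that keeps the string slow relative to the
walkers.  After each update the images are redistributed to equal arc
length along their own polyline (endpoints fixed), which removes the
tangential component of the motion; the stationary state is a curve whose
perpendicular free-energy gradient vanishes — the MFEP.  Because the CV map
is an orthonormal linear transform, the metric tensor of the general
formalism is the identity and plain Euclidean geometry applies throughout
(`reparametrize()`, `assign_voronoi()`).

Numerical choices that matter:

* **Reparametrization.**  One redistribution pass per update, with a full
  fixed-point equalization (relative spacing spread below $10^{-8}$)
  whenever a snapshot is recorded.  Iterating the redistribution to its
  fixed point at *every* update systematically cuts corners on curved
  paths — on the Mueller–Brown surface it pulls the string off the upper
  saddle — while a single pass keeps the spacing near-equal without that
  bias.  Recorded snapshots always satisfy the equal-spacing invariant.
* **Restraint stiffness.**  Too soft a spring smears the mean-force
  estimate over a region where the true gradient varies, biasing the
  converged path; on Mueller–Brown, $\kappa = 500$ (in $kT$ per CV-unit²)
  leaves residual perpendicular gradients of order 100 while
  $\kappa = 2500$ brings the string within a few hundredths of a CV unit
  of both saddles.  The defaults in `string_config()` are exposed, not
  hard-wired: the appropriate stiffness scales with the curvature of the
  landscape under study.
* **Noise floor.**  The image positions fluctuate about the MFEP with
  variance approximately $\frac{\Delta t_z/\gamma}{k_\perp\,
  \Delta t_x\, n_x}$ per transverse direction ($k_\perp$ the transverse
  curvature, $n_x$ the walker steps per update).  Long force-averaging
  batches and a slow string are the levers; the 10-dimensional double-well
  check in the test suite runs with $n_x = 100$ and a drift rate of
  $2\times10^{-3}$ per update, giving a transverse noise floor near 0.06
  CV units, and averages the final snapshots in time.
* **Stopping.**  Either a fixed number of updates or an early stop when
  the RMSD between snapshots a configured window apart falls below
  `convergence_tol` — both supported, since production protocols in the
  field use both.

The initial path is a straight interpolation between the end states,
optionally relaxed by `targeted_initial_path()`, which drags a restrained
walker along the interpolation (a targeted-dynamics analogue) and replaces
each image by the mean CV of its equilibrated segment.

## Umbrella sampling and MBAR

`run_umbrella_windows()` places one harmonic window on every image — a
*weak* spring this time, chosen for phase-space overlap between neighbours
— discards an equilibration segment, subsamples each window by the
statistical inefficiency $g = 1 + 2\sum_t (1 - t/n)\,C(t)$ of its
potential-energy series (truncated at the first nonpositive
autocorrelation), and assembles the $K \times N$ matrix of *reduced*
potentials $u_k(x_n) = \beta U(x_n) + \tfrac{\beta\kappa_u}{2}\lVert
\theta(x_n) - z_k\rVert^2$.  All potentials are stored pre-divided by
$kT$; free energies are dimensionless with gauge $f_1 = 0$.

`solve_mbar()` solves the self-consistency equations

$$ f_k = -\log \sum_n \frac{\exp(-u_k(x_n))}{\sum_j N_j \exp(f_j - u_j(x_n))} $$

by self-consistent iteration, a damped Newton–Raphson on the equivalent
convex objective, or the default hybrid (warm start, then Newton).  Every
evaluation goes through log-sum-exp, so reduced potentials up to about
$\pm 700$ are safe.  States with zero samples are legitimate perturbation
targets and are excluded from the denominator.  Before iterating, the
solver builds a pairwise overlap graph (two states overlap when some pooled
sample is within 30 $kT$ of its best reduced potential in both) and refuses
disconnected problems, reporting the components — a disconnected MBAR
solve converges numerically to meaningless relative free energies.

Per-sample equilibrium weights
$W_n \propto \exp(-u_0(x_n)) / \sum_j N_j \exp(f_j - u_j(x_n))$
feed every reweighted observable: expectations with effective-sample-size
standard errors (`mbar_expectation()`), cell probabilities, structures,
densities and projections.  Asymptotic uncertainties of $f_i - f_j$ use
the standard large-sample covariance; only the $K \times K$ matrix
$W^\top W$ is ever formed.  In a 50-replicate study on the two-harmonic
benchmark the nominal 2-σ intervals covered the exact
$\Delta f = \tfrac12\ln 4$ in 90% of runs.

## Voronoi cells, volumes and the PMF along the path

Samples are binned by nearest string image (Euclidean distance, ties to
the lowest index); samples farther than a cutoff from every image are
excluded as outliers, and their weight is *not* renormalized away — the
PMF's additive constant absorbs it.  The PMF of cell $B$ is

$$ \mathrm{PMF}_B = -\ln\!\big(\hat p_B / V_B\big) + \text{const}, $$

where $V_B$, the relative cell volume, corrects for unequal cell sizes.
$V_B$ is approximated by an ellipsoid from the within-cell sample scatter:
the product over CV axes of the per-axis standard deviation.  Because the
wording "variance of the samples" is ambiguous in the field, both the
$\sigma$-product (default) and $\sigma^2$-product are implemented
(`sigma_power`), as is a full-covariance $\sqrt{\det\Sigma}$ variant; for
equal-dimensional cells the unit-ball constant cancels.

Two practical notes, both visible in the test suite:

* **Cutoff scale.**  The cutoff should be on the order of the image
  spacing.  A generous cutoff makes the two *terminal* cells much longer
  than interior ones; their within-cell density is then locally Gaussian
  while interior cells are near-uniform, and the $\sigma$-based volume
  acquires a geometry factor ($\sqrt{2\pi}$ vs $\sqrt{12}$, about 0.3 kT)
  that offsets the ends of the profile.  With the cutoff near the image
  spacing the geometry is uniform across cells and the volume-corrected
  cell PMF tracks the pointwise profile to well under 0.1 kT on the
  quartic benchmark.
* **Decomposition.**  With `shift_min = FALSE`, corrected and uncorrected
  profiles differ by exactly $\ln V_B$ per cell — the volume correction is
  purely additive, which the suite asserts to $10^{-10}$.  The pipeline
  also re-runs the assignment at 1.17× the cutoff and reports the maximum
  PMF change, mirroring the robustness practice of increasing a 6 Å cutoff
  to 7 Å.

Zero-probability cells are reported absent (`NA`), never imputed.  Per-cell
average structures and RMSF values use the weight-normalized within-cell
moments; grid densities average instantaneous per-voxel count densities
with the same weights and conserve the weighted mean point count exactly.

## Committor diagnostics

The defining property of a transition state is a committor probability of
one half.  Two estimators are provided:

* `committor_lite()` — the protocol feasible for expensive systems: draw
  initial configurations from the umbrella pool restricted to a candidate
  barrier cell (without replacement until exhausted), run unbiased
  trajectories for a fixed time, and bin the *endpoints* by nearest image
  with the same cutoff machinery (endpoints beyond the cutoff are counted
  as unassigned, never dropped).  The summary reports the endpoint
  histogram, the split of committed endpoints to the two sides of the
  start cell with a 95% binomial interval, and the signed median shift;
  the transition-state call is left to the user.
* `committor_estimate()` — the textbook first-passage estimator for cheap
  systems: trajectories run until they enter caller-defined disjoint basin
  regions, with timeouts counted separately.

On the symmetric quartic double well the barrier-top cell commits to the
product side with probability statistically indistinguishable from 1/2,
and the committed fraction increases monotonically across cells spanning
the barrier.

## What the model systems do and do not emulate

The bundled systems (`harmonic_nd`, `quartic_1d`, `double_well_nd`,
`mueller_brown`) provide analytic energies, gradients and — via
deterministic quadrature (`analytic_cv_pmf()`) — exact CV free-energy
profiles, so every stage of the pipeline can be validated against ground
truth.  The overdamped Euler–Maruyama sampler (reduced units, $kT = 1$ by
default) emulates the *statistics* of restrained equilibrium sampling:
configurations, CV values and reduced potentials, which is all the
estimators consume.

It does not emulate: inertial dynamics or thermostats (no momenta — the
optional Maxwell–Boltzmann machinery of inertial committor shots has no
analogue here), force-field detail, solvent, or the sheer dimensionality
of an all-atom system.  Passing tests on these systems therefore validate
the *estimators and their couplings* — they say nothing about force-field
accuracy or sampling convergence of any particular molecular system.  The
integrator's $O(\Delta t)$ stationary-distribution bias is real and
visible at loose step sizes (the effective variance of a harmonic mode is
inflated by roughly $k\,\Delta t/2$); the test suite sizes step sizes so
this bias is well below statistical resolution, and the same care applies
to any study built on the sampler.

## Reproducibility machinery

Every stochastic routine takes an explicit integer seed, scopes its RNG
state (the caller's stream is untouched), and derives per-window and
per-walker child seeds deterministically (`derive_seed()`), so parallel
windows are independently reproducible and a `(function, seed)` pair fully
specifies a result.  The pipeline driver (`run_pipeline()`) writes
plain-text artifacts plus a manifest with per-stage seeds and checksums;
re-running an unchanged configuration recomputes nothing, and deleting an
intermediate artifact recomputes exactly that stage and its downstream
dependents.  Statistical test sizes in the suite (window counts, step
counts, replicate counts) were chosen once from the noise analyses above
so that true-null checks sit several standard errors inside their bounds.

## Known limitations

* CV maps are strictly linear (orthonormal); internal-coordinate or
  dihedral CVs would reintroduce a nontrivial metric tensor and are out of
  scope.
* The ellipsoidal volume estimate assumes the within-cell scatter
  reasonably fills the (truncated) cell; strongly non-convex cells or
  cutoffs far from the image-spacing scale distort it.
* The sampler is overdamped; rate-related quantities (first-passage times
  in `committor_estimate()`) are meaningful only relative to the
  overdamped time scale.
* MBAR asymptotic uncertainties assume effectively independent
  post-subsampling samples; with very short windows they are optimistic.
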