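---
title: "Bounded random walks and boundary-bias correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bounded random walks and boundary-bias correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boundedwalk)
```

## The model

`boundedwalk` implements a null model of intermittent locomotion: an
organism that moves in bursts separated by stops is reduced to the ordered
sequence of its stopping locations, and the displacements between
consecutive stops ("steps") are modelled as an uncorrelated, symmetric
random walk confined to a bounded convex domain. The walk is governed by
an *intrinsic* step density $f_i$ — the step law that would be observed in
unbounded space, assumed symmetric in 1D and rotationally symmetric in 2D
— and by a boundary condition that resolves proposed steps ending outside
the domain:

* **no-go**: the proposal is rejected and redrawn until it lands inside;
* **stop-go**: the proposal is truncated at the first boundary crossing
  and the walker stops on the boundary (1D here);
* **reflecting**: the portion of the step beyond the boundary is
  specularly reflected back inside, possibly repeatedly (1D here).

Because the temporal aspect of locomotion is ignored, the observables are
static: the steady-state stopping-location density $g$ and the
*transformed* (empirical) step density $f_t$, the limiting histogram of
observed steps in bounded space. Both differ from their unbounded
counterparts in a geometry-specific way, which is the bias this package
quantifies and removes.

## Shaper functions

Under no-go boundaries the stationary equation
$g(x) = \int g(x')\,P(x - x' \mid x')\,dx'$ is solved by
$g \propto \mathcal N$, where $\mathcal N(r)$ is the probability that an
unconstrained step from $r$ lands inside the domain
(`step_normalisation()`). Substituting this ansatz collapses the
transformed density to a purely multiplicative relation

$$f_t(\ell) \;\propto\; f_i(\ell)\, h(\ell),$$

where the *shaper function* $h$ is the set covariance of the domain
$\Omega$: $h(\ell) = \mathrm{measure}\big(\Omega \cap (\Omega -
\ell)\big)$. It depends only on the geometry, takes the value
$|\Omega|$ at $\ell = 0$, decreases monotonically along every ray, and
vanishes at the domain diameter. Closed forms are shipped for the
interval ($h(\ell) = (L - |\ell|)_+$), axis-aligned rectangles (a product
of interval shapers — note this breaks rotational symmetry), and the disk
(the lens-overlap area, cutoff at $2R$); every other convex polygon is
handled exactly by Sutherland–Hodgman clipping of the polygon against its
own translate (`shaper_polygon()`), with a brute-force grid-integration
oracle (`shaper_grid_oracle()`) retained for testing. For magnitude-only
data the angle-averaged form
$\tilde h(\ell) = \int_0^{2\pi} h(\ell\cos\theta, \ell\sin\theta)\,
d\theta$ plays the same multiplicative role against the magnitude density
$\tilde f_i(\ell) = 2\pi\ell f_i(\ell, 0)$.

Shapers are exposed un-normalised (as overlap measures) because every use
divides by an explicit normalisation constant.

## Stationary densities and the Nyström solver

`stopping_density_nogo()` evaluates the no-go ansatz directly: by the
intrinsic CDF on intervals, by a radial quadrature with the angular
overlap fraction $\gamma$ on disks, and by two-dimensional quadrature on
general convex polygons. Independently, `fredholm_stationary()`
discretises the stationary equation on a trapezoid grid (Nyström) and
power-iterates to the eigenvalue-one density, which is how the package
*verifies* the ansatz rather than assuming it: the two code paths agree
to a sup-norm far below the `1e-3` documentation tolerance at 201 nodes.
For reflecting boundaries the solver recovers the uniform stationary
density; for stop-go — where no closed form exists — it is offered as a
numerical extra, with the boundary probability atoms carried by two extra
point-mass nodes at the interval ends.

Three numerical conventions matter here:

* transition-matrix rows are renormalised to sum exactly to one, which
  removes the quadrature error from the row sums while preserving the
  stationary structure;
* densities with jump discontinuities (the uniform family) take the
  mid-value at the jump, the convention under which trapezoid quadrature
  stays second order when the jump falls on a node;
* kernel rows belonging to the integration endpoints use the one-sided
  limit from inside the domain, since a jump falling exactly on an
  endpoint has no adjacent interval to cancel against.

Without the last two, the uniform family shows isolated $O(h)$ error
spikes at the kink nodes of $g$.

## Transformed step densities

* `transformed_pdf_nogo()` returns the normalised $f_i h$ (1D) or
  $f_i(\ell,0)\,\ell\,\tilde h(\ell)$ (2D magnitude) density. A direct
  corollary of the monotone shaper is variance reduction: the mean-square
  step under $f_t$ is strictly smaller than under $f_i$, for every family
  and geometry — confinement alone produces shorter observed steps, with
  no behavioural change.
* `transformed_pdf_stopgo()` evaluates the uniform-start closed form
  $f_i(\ell)h(\ell) + (1 - F_i(|\ell|))$ on $|\ell| < L$, where the
  second term is the boundary-truncation atoms integrated over a uniform
  start.
* `transformed_pdf_reflecting()` sums reflection images. Each image
  contributes in closed form through the intrinsic CDF, so no quadrature
  is involved; the sum is exact once $2\,n_\mathrm{images}\,L$ exceeds
  the support radius (the default picks this automatically). The
  simulator, by contrast, *folds* landing points, so the analytic image
  sum and the simulation are genuinely independent mechanisms and their
  agreement is a meaningful test.

## Reconstruction

`reconstruct_intrinsic()` inverts the multiplicative bias bin-wise:
$\hat f_i \propto \hat f_t / h$ at the bin centres, with the ensemble
standard deviation scaled identically. Division at bin centres (rather
than bin-averaged shapers) biases at second order in the bin width; the
default 60 bins over the diameter keep the width at or below 1/50 of the
cutoff except within a few bins of zero. Bins where $h$ falls below
`shaper_floor` (default 1% of $h(0)$) or that lie at or beyond the
diameter are reported as `NA`, never zero: information about steps larger
than the enclosure is destroyed, not merely attenuated, and near the
cutoff the reciprocal of the shaper amplifies noise without bound — which
is also why the reconstruction envelope widens toward the diameter. No
smoothing or regularised deconvolution is applied; the estimator is the
plain bin-wise quotient, left un-normalised by default because the
relation only determines $f_i$ up to a constant. Per-bin envelopes are
propagated by linear scaling only; covariance between bins is not
modelled.

## Simulation design and study conditions

`simulate_walk()` starts each run uniformly in the domain and advances
all `n_runs` walkers in lockstep from a single seeded RNG stream, which
makes the whole ensemble reproducible from one seed and keeps the
step-level loop vectorised across runs. No-go resampling redraws the full
step vector (direction and magnitude) and counts rejections per run; a
`max_attempts` guard (default $10^6$) converts a walker stuck where
$\mathcal N(r)$ is vanishingly small into an informative error instead of
a hang. Stop-go places the walker exactly on the boundary at the nearer
crossing; reflecting uses the periodic fold map, equivalent to the full
image sum including multiple reflections.

Samplers use a cached 4096-point inverse-CDF grid (exact closed-form
samplers for the Gaussian and uniform families); the interpolation error
is far below Monte-Carlo error at the sample sizes used anywhere in the
package.

The reference experiment — the basis of the end-to-end test — is the
unit square with the parabolic intrinsic kernel
$f_i(\ell) = 3(a^2 - \ell^2)_+/(4a^3)$, half-support $a = 0.75$, under
no-go boundaries. The test suite runs it at a reduced scale of $M = 200$
runs of $N = 10^4$ steps with a burn-in of $10^2$ (1% of the run length,
the package default ratio), which resolves a 60-bin magnitude histogram
with per-bin standard errors a few percent of the density. Where a family
parameter is not pinned by the reference experiment the package tests use
scales a movement ecologist would call realistic for an arena of unit
size: Gaussian $\sigma = 0.25$ (a quarter of the system size, so boundary
effects are strong but not overwhelming) and uniform half-support $0.75$
matching the parabolic case.

What the generator emulates — and what it does not: draws are i.i.d.
between stops, so the synthetic data contain no step–step correlation,
no temporal structure, no heavy-tailed dispersal, and no behavioural
response to the wall. Passing tests therefore certify the boundary-bias
machinery under the null model, not the realism of the null model for
any particular organism.

## Known limitations

* Only convex domains: for non-convex $\Omega$ a step between two
  interior points can cross the boundary and the kernel is no longer
  $f_i I_\Omega$.
* Stop-go and reflecting boundaries are treated in 1D only, and the
  multiplicative reconstruction applies to no-go boundaries only — the
  other two transformed densities lack the product structure.
* Dimensions $d \ge 3$ are not implemented, although the set-covariance
  relation extends verbatim.
* The reconstruction is a bin-wise quotient with independent per-bin
  envelopes; correlated errors and occupancy differences between runs
  are not modelled.
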