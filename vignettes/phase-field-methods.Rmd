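---
title: "Phase-field modelling of mitochondrial inner-membrane morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-field modelling of mitochondrial inner-membrane morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chmito)
```

## The model

`chmito` simulates phase separation of the mitochondrial inner membrane and
the fluid matrix with the dimensionless Cahn–Hilliard equation

$$\partial_t \Psi \;=\; \tfrac12 \nabla^2\!\left(\Psi^3 - \Psi - \gamma \nabla^2 \Psi\right),$$

where the order parameter $\Psi$ is the difference of the local densities of
the two compartments: $\Psi = -1$ is pure inner membrane, $\Psi = +1$ pure
fluid matrix, and $\Psi = 0$ the homogeneous mixture. Equivalently, the
dynamics are the conserved gradient flow $\partial_t \Psi = -\nabla\cdot J$
with flux $J = -M\nabla\mu$, mobility $M = \tfrac12$, and chemical potential
$\mu = \Psi^3 - \Psi - \gamma\nabla^2\Psi$, which is the variational
derivative of the Ginzburg–Landau free energy

$$F(\Psi) = \int_\Omega \left[\tfrac14(\Psi^2-1)^2 +
  \tfrac{\gamma}{2}|\nabla\Psi|^2\right] dr,
\qquad \frac{dF}{dt} = -\int_\Omega |\nabla\mu|^2\,dr \le 0 .$$

$\gamma$ (default 1, dimensionless) sets the interface width: the 1D
equilibrium profile is $\tanh(x/\sqrt{2\gamma})$, of width
$O(\sqrt{2\gamma})$, with excess energy $\tfrac23\sqrt{2\gamma}$ per unit
interface measure (`equilibrium_profile()`, `interface_energy()`).

The outer boundary $\Gamma$ carries zero-flux conditions on both $\Psi$ and
$\mu$, so total mass $\int_\Omega \Psi$ is conserved. Calcium phosphate
granules are volume-excluded balls: their surfaces $\Gamma'$ pin
$\Psi = C$ (a constant, $+1$ by default — the granule surface recruits fluid
matrix) while $\mu$ keeps its zero-flux condition. With a pinned boundary the
discrete dynamics are *not* mass-conserving; the injected mass is exactly the
matrix halo that grows around the granule, and the drift is monitored in the
time series rather than asserted away.

## Linear stability

Linearizing about $\Psi = 0$ with $\Psi = \Psi_0 e^{\omega t + i k\cdot r}$
gives the dispersion relation

$$\omega(k) = \tfrac12\left(k^2 - \gamma k^4\right),$$

positive exactly for $0 < k < 1/\sqrt{\gamma}$: long wavelengths grow
(spinodal decomposition), short wavelengths decay, and the fastest-growing
mode $k = 1/\sqrt{2\gamma}$ grows at rate $1/(8\gamma)$. The uniform states
$\Psi = \pm 1$ are linearly stable (their perturbations decay at rate
$-\tfrac12 k^2(2 + \gamma k^2)$); only the mixture $\Psi = 0$ is unstable.
`dispersion_rate()` and `critical_wavenumber()` are the closed forms;
`measure_growth_rate_1d()` is a deliberately *independent* numerical check —
a uniform periodic grid, standard second-difference Laplacian, and
semi-implicit stepping that share no code with the finite-element solver, so
a disagreement between the two localizes a bug instead of cancelling it. The
growth-rate fit excludes the first 10 steps (discrete-initialization
transient) and rejects fits with $R^2 < 0.999$ as nonlinearly contaminated.

An important timescale consequence: the fastest growth rate at $\gamma = 1$
is $1/8$, so amplifying small noise into a fully separated pattern takes
$t \approx \ln(0.5/0.005)/0.125 \approx 25$ time units. The bundled disk
protocols end at $t \le 11.25$; over those horizons the field is the
*linearly filtered* initial noise — high wavenumbers annihilated, the
unstable band amplified — which already shows the merging/splitting pattern
dynamics and monotone coarsening, while the amplitude is still growing
towards saturation. Rendering such fields with a data-scaled diverging
colormap produces the familiar red/blue lobes with white rims. Morphometrics
whose meaning depends on full saturation (notably the sign-area fractions,
see below) should be interpreted with this in mind.

## Discretization

The fourth-order equation is rewritten as two coupled second-order equations
in $(\Psi, \mu)$ so standard piecewise-linear (P1) Lagrange elements apply.
With $(u,v)$ the $L_2$ inner product and $a(u,v) = (\nabla u, \nabla v)$, a
step solves, for all test functions $u, v$:

$$\left(\frac{\Psi^{n+1}-\Psi^n}{\Delta t}, u\right)
  + M\, a(\mu_{n+\theta}, u) = 0,
\qquad
(\mu^{n+1}, v) - (f'(\Psi^{n+1}), v) - \gamma\, a(\Psi^{n+1}, v) = 0,$$

with $\mu_{n+\theta} = (1-\theta)\mu^{n+1} + \theta\mu^n$. Note the weighting
convention: the *implicit* level is weighted by $1-\theta$, so $\theta = 0.5$
is the trapezoidal member and $\theta = 0$ fully implicit. The default is
$\theta = 0.5$. The cubic $f'(\Psi^{n+1}) = (\Psi^{n+1})^3 - \Psi^{n+1}$ is
fully implicit and the coupled system is solved by exact Newton iteration
(analytic Jacobian; stop when the residual 2-norm falls below
$\max(10^{-10},\ 10^{-8}\,r_0)$, at most 25 iterations; typical steps need
2–3). Linear solves use a sparse direct factorization (`Matrix`), appropriate
for the $\lesssim 10^4$-unknown meshes of the bundled protocols.

Because the $\Psi$-equation holds in particular for the constant test
function and $a(\cdot, 1) = 0$, discrete mass conservation on granule-free
domains is exact up to the Newton tolerance — measured drift is
$\sim 10^{-11}$ relative over 2250 steps. Granule pinning is imposed by
eliminating the granule-tagged $\Psi$ degrees of freedom at their pinned
value; the zero-flux $\mu$ condition on $\Gamma'$ is natural in the weak
form.

Energy quadrature: the gradient term of $F$ is integrated exactly
($\Psi^\top K \Psi$ with the assembled stiffness matrix, since P1 gradients
are element-wise constant); the quartic bulk term uses edge-midpoint (2D),
4-point (3D) and 3-point Gauss (1D) rules — a one-point rule visibly biases
$F$ for a quartic integrand.

## Meshing

No unstructured mesh generator exists in the R stack the package targets, so
domains are meshed directly: a background grid of squares (alternating-
diagonal split) or cubes (six-tetrahedra Kuhn split) covers the bounding
box; simplices whose centroid lies inside the domain (and outside every
granule) are kept; boundary nodes are then snapped onto the analytic
surface by radial projection with per-node damping — a node moves as far
toward the surface as its incident elements allow without inverting — and
interior nodes are relaxed by a few Laplacian smoothing sweeps. Boundary
facets are tagged outer or by granule index by nearest surface. Measured
areas/volumes are within 0.1% (2D) and about 1% (3D) of the analytic values
at the default resolutions, converging under refinement. The damped snap can
leave rare near-degenerate slivers; the direct solver tolerates them, and
element measures are checked positive after construction.

Ellipse/ellipsoid sizes are read as **full axis lengths** ("major axis of
10" means semi-axis 5), which keeps the axes-10/8 ellipse comparable to the
radius-5 disk; the convention is echoed in every config so the alternative
reading is a one-line change. The third ellipsoid axis, not fixed by the 2D
protocol, is set equal to the minor axis (10/8/8). Granule positions for the
one- and two-granule protocols are likewise not fixed by the protocols
beyond "first/fourth quadrant"; the bundled configs use radius 1.0 at
$(\pm 2.5, \pm 2.5)$, and both are ordinary config fields.

The default mesh pitch `h_target = 0.15` resolves the interface width
$\sqrt{2\gamma} \approx 1.41$ with roughly nine elements. 3D protocols use
`h_target = 0.4` — coarse, adequate for the smoke-level 3D checks; granule
clearance to other surfaces must exceed `h_target` for the mesh to separate
them.

## Initial conditions and what the generator emulates

`initialize_random()` draws i.i.d. nodal values uniform on
$[\text{mean}-a, \text{mean}+a]$ (default mean 0, amplitude 0.05), emulating
a randomly and uniformly mixed membrane/matrix interior, then overwrites
granule-tagged nodes with their pinned value. Worth knowing: nodal i.i.d.
noise is *white at the grid scale*, so its projection onto the smooth
unstable band has amplitude $\sim a/\sqrt{N_\text{patch}}$ — increasing $a$
barely accelerates pattern formation while inflating the gradient energy of
the start-up transient (and, at $a \to 1$, briefly overshooting the
double-well range). The default small amplitude keeps the transient clean;
what the generator does *not* emulate is spatially correlated noise or any
biological heterogeneity of a real mitochondrion.

## Morphometrics

* `phase_fractions()` splits every element exactly by the linear interpolant
  at the $\Psi = 0$ midpoint threshold (nodes exactly at 0 belong to neither
  phase), so matrix + membrane fractions partition the domain to machine
  precision. In the pre-saturation regime the sign-area fraction of a
  near-zero-mean field is a large-fluctuation statistic — a radius-4 disk
  holds only about two unstable wavelengths ($\lambda_{max} = 2\pi\sqrt{2}$)
  — and is *not* pinned near 0.5 by mass conservation until interfaces
  sharpen.
* `interface_measure()` extracts the $\Psi = 0$ level set by marching
  segments (2D) / marching tetrahedra (3D); nodes exactly on the level are
  nudged consistently to one side so node-aligned interfaces are not lost.
* `count_phase_components()` counts connected components over facet
  adjacency (edge-sharing in 2D, face-sharing in 3D) — vertex-touching blobs
  do not bridge.
* `characteristic_length()` is $2\pi/\langle k\rangle$ with
  $\langle k\rangle$ the first moment of the radially averaged power
  spectrum of the mean-subtracted field, resampled on a $128^2$ (2D) or
  $64^3$ (3D) grid over the bounding box with the exterior masked to the
  field mean. It recovers $2\pi/k$ for a single mode and grows monotonically
  under coarsening.
* `granule_halo_mean()` / `granule_halo_report()` average $\Psi$ over
  elements whose centroids lie within a shell of width 0.5 (about a third of
  the interface width — inside the wetting layer) outside the granule
  surface; the halo report also gives the shell's membrane fraction, the
  quantitative counterpart of matrix fluid displacing membrane near a
  granule.

## Numerical choices and degenerate inputs

* $\theta = 0.5$ keeps second-order accuracy; it is not L-stable, so
  grid-scale components of rough initial data ring with slowly shrinking
  amplitude. With the default small-amplitude initialization the measured
  free energy is monotone non-increasing to $10^{-10}$ per step over the
  full 2250-step disk protocol.
* Newton non-convergence (e.g. $\Delta t$ far above the protocol values)
  raises an error carrying the residual and step index rather than
  continuing silently.
* Uniform fields: stationary under the solver to machine precision;
  `characteristic_length()` refuses spectrally flat fields;
  `interface_measure()` returns 0.
* Granule placement is validated before meshing (inside the outer shape and
  pairwise disjoint with clearance $\ge$ `h_target`); violations are
  reported per granule. `h_target` larger than the smallest granule radius
  is a resolution error.
* Determinism: the only randomness is the seeded initial field; stepping is
  deterministic, so checkpoint-resumed trajectories are bit-identical to
  uninterrupted ones and identical config+seed reproduce byte-identical
  time-series CSVs.

## Problem sizes of the bundled protocols

The disk protocols run at `h_target = 0.15` (about 2200 nodes for radius 4,
3400 for radius 5 with one granule; 4500–9000 Newton solves per run); the 3D
sphere smoke protocol runs 200 steps at `h_target = 0.4` (about 1000 nodes).
These sizes complete in minutes on one core while leaving the interface
resolved; refining `h_target` tightens the measure and interface tolerances
roughly quadratically at cubically growing cost.

## Known limitations

* The theta scheme is not energy-stable by construction; energy decay is a
  measured property at the protocol step sizes, not a theorem.
* The background-grid mesher handles the analytic shapes of this model
  (disk/ellipse/sphere/ellipsoid with spherical holes), not image-derived
  boundaries, and does no adaptive refinement.
* No electrostatics, reaction–diffusion coupling, or protein-level cristae
  regulators — the model treats membrane/matrix demixing only.
* Logarithmic (Flory–Huggins) free energies and multicomponent mixtures are
  out of scope; the potential is the polynomial double well.
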