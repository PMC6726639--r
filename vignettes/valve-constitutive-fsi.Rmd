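---
title: "Constitutive laws, inverse fitting, and a 2D valve FSI demonstrator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constitutive laws, inverse fitting, and a 2D valve FSI demonstrator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valvefsi)
```

## The modelling problem

Mitral-valve leaflets are fiber-reinforced soft tissue: a compliant
elastin/collagen matrix with collagen fibers that straighten and stiffen
as the valve loads up during systole.  The chordae tendineae that tether
the leaflet edges are stiffer, nearly one-dimensional cords.  This package
implements a complete, testable pipeline for a recurring workflow in valve
biomechanics:

1. **Constitutive models.**  Transversely isotropic, incompressible
   hyperelastic laws written in the strain invariants
   $I_1 = \operatorname{tr}\mathbf{C}$ and
   $I_4 = \mathbf{a}_0\cdot(\mathbf{C}\mathbf{a}_0)$ of the right
   Cauchy–Green tensor $\mathbf{C}=\mathbf{F}^T\mathbf{F}$, where
   $\mathbf{a}_0$ is the reference fiber direction.  Three leaflet laws
   (M1–M3) and two chordae laws (neo-Hookean, exponential) are provided.
2. **Inverse fitting.**  Estimating law parameters from biaxial
   (leaflet) or uniaxial (chordae) stretch–stress data by bounded
   least squares, with $R^2$ and average-error reporting.
3. **A synthetic-experiment generator** emulating the tensile rigs, so
   every pipeline stage is testable without proprietary data.
4. **A 2D immersed-boundary/finite-element (IB/FE) demonstrator** of a
   flexible two-leaflet valve in a pressure-driven channel, with the
   hemodynamic metrics used to compare material laws (flow rate, closure
   regurgitation, orifice opening, peak jet velocity).

## The five constitutive laws

With $I_4^* = \max(I_4, 1)$ (collagen fibers bear load only in tension),
the strain energies (kPa) are

$$
\begin{aligned}
\text{M1:}\quad \Psi &= c\,(I_1-3)+\frac{a}{2b}\left(e^{b(I_4^*-1)^2}-1\right),\\
\text{M2:}\quad \Psi &= c_0\left(e^{c_1(I_1-3)^2 + c_2(\sqrt{I_4^*}-1)^4}-1\right),\\
\text{M3:}\quad \Psi &= c_0\left(e^{c_1(I_1-3)^2 + c_2(I_4^*-1)^2}-1\right),\\
\text{chordae (linear):}\quad \Psi &= C\,(I_1-3),\\
\text{chordae (exponential):}\quad \Psi &= a_1\left(e^{a_2(I_1-3)}-1\right).
\end{aligned}
$$

The Cauchy stress of an incompressible material is
$\sigma = -\lambda_m\mathbf{I} + 2\mathbf{F}\,\partial_\mathbf{C}\Psi\,\mathbf{F}^T$,
where the Lagrange pressure $\lambda_m$ is eliminated in closed form from
the zero-stress condition of the test: plane stress
($\sigma_{33}=0$) for leaflet sheets, uniaxial
($\sigma_{22}=\sigma_{33}=0$) for chordae.  Because $\lambda_m$ enters
linearly this is always solvable.

**Energy consistency.**  Published closed-form stress expressions for
these laws circulate in several variants that are not the derivative of
the stated energy: an M1 fiber factor $2a I_4 e^{b(I_4-1)^2}$ in place of
$2a(I_4-1)e^{b(I_4-1)^2}$, a linear-chordae stress $C\mathbf{B}$ in place
of $2C\mathbf{B}$, and an exponential-chordae stress missing the factor
$a_2$.  This package implements the exact energy derivatives — a
hyperelastic stress must satisfy
$\mathbf{P} = \partial\Psi/\partial\mathbf{F}$ — and verifies them against
central-difference differentiation of $\Psi$ in the test suite.  The
non-consistent variants remain available via
`cauchy_stress(..., as_printed = TRUE)` for comparison only.

**Units.**  The exponential constants of M2/M3 multiply powers of
dimensionless invariants; they are treated as dimensionless even where
published parameter tables print kPa against them.  Only the leading constants carry
stress units.  Pressures convert as 1 mmHg = 0.1333 kPa = 1333.22
dyn/cm².

## Kinematics of the tests

Test protocols are stretch-controlled and loading-only.  Sheet (biaxial)
kinematics place the fiber along test axis 1 and complete the out-of-plane
stretch by exact incompressibility,
$\mathbf{F} = \mathrm{diag}(\lambda_1, \lambda_2, 1/(\lambda_1\lambda_2))$;
uniaxial kinematics use
$\mathbf{F} = \mathrm{diag}(\lambda, \lambda^{-1/2}, \lambda^{-1/2})$.
Exact incompressibility (rather than a penalty) matches the continuum
formulation of the laws and keeps $\det\mathbf{F} = 1$ to machine
precision, which the tests assert.

## The inverse problem

Parameters are estimated by minimising the summed squared Cauchy-stress
residual

$$\min_{c_i > g_i}\ \sum_k\left[(\sigma_{11}^{\mathrm{model}}-\sigma_{11}^{\mathrm{exp}})^2
+ (\sigma_{22}^{\mathrm{model}}-\sigma_{22}^{\mathrm{exp}})^2\right]_k,$$

with the second term absent for uniaxial data and lower bounds
$g_i = 10^{-6}$ enforcing non-negative parameters.  The solver is bounded
Levenberg–Marquardt (`minpack.lm::nls.lm`) restarted from 20 seeded
log-uniform points in $[10^{-2}, 10^{3}]$; the exponential laws make the
objective non-convex, and multi-start materially reduces the risk of
returning a local minimum.  Fits are deterministic given the dataset and
seed.  Goodness of fit is reported per stress component as
$R^2 = 1-\mathrm{SSE}/\mathrm{SST}$, alongside an *average error* defined
here as the mean absolute stress residual in kPa — a declared
interpretation of a conventionally reported but rarely defined summary —
which is never used as a pass/fail quantity.

### The pseudo-biaxial calibration protocol

The M2 and M3 leaflet laws are calibrated against noiseless
"pseudo-experimental" stress–stretch data generated from the M1 law at
its published per-leaflet parameters (anterior: $c = 17.43$ kPa,
$a = 1.35$ kPa, $b = 5.93$).  The underlying experimental stretch
protocols behind such calibrations are typically published only as
figures, so the default here is a declared choice: three
stretch-controlled paths (equibiaxial; fiber-only, $\lambda_2 = 1$;
cross-fiber-only, $\lambda_1 = 1$) with 30 points per path over
$\lambda \in [1.0, 1.30]$.  The upper end covers the strongly fiber-
stiffened regime of M1; physiological leaflet fiber strains (~0.1) sit in
the lower half of the range.  Because M2 and M3 have identically zero
initial tangent modulus (their stresses scale with $(I_1-3)e^{(\cdot)}$)
while M1 has the finite initial modulus $2c$ of its neo-Hookean matrix,
the cross-law calibration is structurally imperfect at small strain
whatever the optimizer does; the wide stretch range weights the fit
toward the collagen-dominated regime where the three laws agree best.

### Identifiability and recovery truths

Self-consistency (fitting a law to its own noiseless data) is tested for
all five laws.  The ground truths are the published M1 anterior and M3
anterior parameter sets, and — because a published M2 fiber coefficient of
$c_2 = 8\times10^{-4}$ contributes stresses below numerical noise over
this protocol, making it unidentifiable by construction — a synthetic,
identifiable M2 truth $(c_0, c_1, c_2) = (10, 15, 20)$.  Chordae truths
are $C = 2000$ kPa (linear) and $(a_1, a_2) = (10\ \text{kPa}, 30)$
(exponential), chosen to give MPa-scale chordae stresses at
$\lambda = 1.1$, the stiffness scale reported for porcine chordae.

## The synthetic-experiment generator

`generate_leaflet_experiment()` / `generate_chordae_experiment()` emulate
the tensile rigs in stress–stretch space: the ground-truth law is
evaluated over the protocol and a declared noise model is applied to the
stresses only — stretch is the controlled variable in such rigs.  Noise is
either absent, additive Gaussian (sd in kPa), or proportional Gaussian
(coefficient of variation).  Chordae protocols default to
$\lambda\in[1.0, 1.10]$ with 50 points (chordae are stiff; larger
stretches are unphysiological).  What the generator deliberately does
*not* emulate: preconditioning cycles (only the post-preconditioned
loading curve is produced), force/geometry-level effects (load cells,
thickness measurement), specimen-to-specimen biological variability, and
any stretch-axis error.  Passing recovery tests on these data therefore
demonstrates correctness of the fitting machinery, not robustness to all
features of real experiments.

## The 2D IB/FE demonstrator

The fluid is incompressible Navier–Stokes on a staggered MAC grid, with
density 1 g/cm³ and viscosity 0.04 g/(cm·s) — typical blood values,
declared as assumptions.  The scheme is explicit first-order upwind
advection, explicit diffusion, and an exact pressure projection: the
pressure Poisson equation (Dirichlet pressure at the inlet/outlet,
homogeneous Neumann at the no-slip walls) is solved by a cached sparse
Cholesky factorisation, so the post-projection discrete divergence is at
solver precision (asserted at ≤ 1e−10 relative).  The time step honours
advective and viscous stability bounds with a 0.5 safety factor, plus a
structural bound described below.

The structure is a pair of fiber-aligned elastic curves (the leaflets)
attached at opposite channel walls, tethered near their free edges to
fixed downstream anchor points by chordae-law cords that go slack in
compression (papillary-muscle motion is out of scope).  Each line element
carries a 3D constitutive law through a plane-strain completion: element
stretch $\lambda$ gives $I_4=\lambda^2$ and, with out-of-plane stretch 1,
$I_1=\lambda^2+\lambda^{-2}+1$, so the kPa parameterisations plug in
unchanged.  A small discrete bending energy regularises the otherwise
tension-only chain.  Internal forces are the exact analytic negative
gradient of the assembled energy (verified against central differences in
the tests), so a free structure carries zero net force and torque by
frame indifference.

Four boundary devices keep the analogue well posed.  The two attachment
nodes of each leaflet are *kinematically pinned* target points whose
elastic reaction is absorbed by the wall rather than spread into the
fluid — spreading the unbalanced root tension injects spurious momentum
at the attachment and was observed to destabilise the loaded phase.  A
smooth quadratic *wall-contact penalty* (the housing) repels nodes that
approach either channel wall within half a grid cell, standing in for the
leaflet–housing contact that is not otherwise modelled; it is part of the
elastic energy, so force consistency is preserved.  A *coaptation-plane
penalty* at the channel midline similarly stands in for leaflet–leaflet
contact in this symmetric geometry, preventing interpenetration at
closure.  And the *effective leaflet cross-section* defaults to 0.2 cm: in the 3D valve the systolic
load is shared by double-curvature membrane action and tens of chordae,
which a single 2D fiber pair lacks, and a thinner 2D leaflet is driven
into extreme fiber stretches (and hence extreme tangent stiffness) that
the real valve never reaches.

The default geometry: a 4 × 2 cm channel, leaflets of length 1.05 cm
attached at `x = 1.5` cm with an initial 30° downstream tilt (tips nearly
meeting at the centreline, the mid-diastole configuration), and tether
anchors 0.9 cm downstream at 0.4 of the channel height from each wall.
With these choices the valve opens wide under the +10 mmHg forward
phase, snaps shut at pressure reversal with a closure-regurgitation
spike, and holds the −80 to −150 mmHg load with a small residual leak
(leaflet–leaflet contact is not modelled).

Fluid–structure coupling uses the standard 4-point regularised delta
kernel: force spreading and velocity interpolation share the same
weights, making them exact adjoints; the kernel's partition of unity
makes spreading conservative.  Near the walls, stencil contributions
beyond the domain are clipped — attachment nodes sit on the wall — which
sacrifices exact conservation only there.

The driving transvalvular pressure difference is piecewise linear through
the characteristic phase anchors of a valve cycle: +10 mmHg at full
opening (t = 0.1 s), reversal during closure, −80 mmHg just after closure
(t = 0.22 s), −150 mmHg fully loaded (t = 0.35 s).

**Time stepping and stability.**  Explicit IB coupling of a stiff fiber
to a fluid is stability-limited by the stiffest element spring against
the local fluid added mass ($\rho h^2$ per unit depth).  The demonstrator
probes the tangent stiffness of the elements up to the currently reached
stretch (plus a margin) and recomputes this bound every 25 steps, so the
step adapts as the leaflets load up instead of always assuming the
stiffest state.  Default runs use a 1e−5 s cap.

**What the demonstrator is.**  A desk-scale, qualitative 2D analogue for
exercising the governing equations and the metric definitions: sign
patterns (forward flux while the pressure is forward, a transient
negative-flux closure-regurgitation interval after reversal) and
orderings (stiffer leaflets open less) are meaningful; absolute values
are per-unit-depth 2D quantities and are deliberately unit-tagged
(cm²/s) so they cannot be confused with 3D mL/s results from
patient-specific simulations, which are out of scope here.

## Hemodynamic metrics

* `flow_rate()` — signed integral of the streamwise velocity over a fixed
  downstream section (the section choice is free; any fixed section works
  in an incompressible channel).
* `regurgitation_volume()` — trapezoidal $\int \max(-Q,0)\,dt$ over the
  closure window, by default from the first sign reversal of the driving
  pressure to the end of the trace.
* `orifice_area()` — the free-edge boundary projected onto the annular
  plane, enclosed area by the shoelace formula; self-intersecting
  projections warn and return the absolute value.  (This 3D geometry
  utility is exercised on constructed polygons; the demonstrator itself
  uses the 2D analogue `gap_opening()`, the tip-to-tip distance.)
* `peak_velocity()` — max of $|u|$ over space and time.

## Numerical choices and edge cases

* Tension-only switch inside both energy and stress: the fiber term and
  its derivative vanish identically for $I_4 \le 1$; random-deformation
  tests sample both sides of the switch but not its neighbourhood, where
  the energy is $C^1$ but not $C^2$.
* `exp()` overflow in badly scaled optimizer iterates is mapped to large
  finite residuals so Levenberg–Marquardt backs away instead of failing.
* The $b \to 0$ limit of M1's fiber energy is handled analytically.
* Degenerate fits (fewer observations than parameters), constant
  observations (SST = 0), inverted elements, nodes leaving the domain,
  and CFL violations raise informative errors rather than propagating
  NaNs.

## Problem sizes used in the shipped checks

The routine test suite runs the channel-flow benchmark at 32 cells across
the channel and the valve demonstrator in smoke form; the acceptance
checks run the Poiseuille benchmark at 64 cells across the channel
(within 2% of the closed form), the cross-law calibration at the full
three-path protocol, the chordae-law discrimination over 100 seeded
replicates, and the valve demonstrator at 64 × 32 over a 0.30 s cycle
with a 10× stiffness comparison truncated after the opening phase.  These
sizes are the package's declared study conditions; the scaling behaviour
(grid refinement, longer cycles) is exposed through the configuration
objects.

## Known limitations

* The demonstrator is 2D and desk-scale: no 3D geometry, no adaptive
  meshing, no valve–ventricle interaction, no measured papillary-muscle
  boundary conditions.
* First-order upwind advection is dissipative; it is robust at the
  moderate Reynolds numbers reached here but smooths jet structures.
* True leaflet–leaflet contact is only approximated (by the
  coaptation-plane penalty), and an immersed curve always leaks over the
  ~2-cell width of the regularised kernel, so the closed valve retains a
  small residual gap and leak, and the late loaded phase shows a
  jet-driven leaflet flutter around the coaptation point.
* The fitting module assumes stress–stretch data; force–displacement
  records and parameter uncertainty quantification are out of scope.
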