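---
title: "Curvature-coupled morphogen patterning: model, discretization, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvature-coupled morphogen patterning: model, discretization, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphomech)
```

## The model

`morphomech` couples two fields on a closed tissue surface $\Gamma$: the shape
$X$ and a morphogen concentration $\varphi$ carried by the tissue (Lagrangian
transport: each material point keeps its $\varphi$ value as it moves).

**Mechanics.** The elastic energy is a modified Helfrich bending energy with
morphogen-dependent moduli,
$$
F[X,\varphi] \;=\; \int_\Gamma \tfrac12\,\kappa(\varphi)\,
  \bigl(H - H_0(\varphi)\bigr)^2\, dS,
\qquad
\kappa(\varphi)=\kappa_0+\kappa_1\varphi,\quad
H_0(\varphi)=h_0+\beta\varphi,
$$
with $H=\kappa_1+\kappa_2$ the (sum-convention) mean curvature, positive for
outward bending; the unit sphere has $H=2$, a circle of radius $R$ has
$H=1/R$. The spontaneous curvature $H_0$ encodes preferred local bending
(wedge-shaped cells curve the sheet); the morphogen raises it through the
coupling $\beta>0$. The shape evolves by an overdamped gradient flow,
$$
\xi\,\partial_t X \;=\; -\,\frac{\delta}{\delta X}\Bigl(F + E_{\text{area}}\Bigr),
$$
under **local area incompressibility**: every material patch must keep its
reference measure. We enforce this with a stiff quadratic penalty
$E_{\text{area}} = \sum_v \tfrac12 k_a (a_v - a_v^{\mathrm{ref}})^2 /
a_v^{\mathrm{ref}}$ whose derivative $\lambda_v = k_a (a_v -
a_v^{\mathrm{ref}})/a_v^{\mathrm{ref}}$ is reported as the local
pressure-like multiplier. A true saddle-point (exact Lagrange multiplier)
formulation is recovered in the stiff limit; the penalty is far easier to make
robust, keeps the flow an unconstrained gradient flow of a single energy (so
energy descent is exactly testable), and leaves $\lambda$ observable. The
enclosed volume is deliberately *not* constrained: tissue spheres exchange
fluid with their surroundings. Drag is per unit measure, so the discrete
mobility is $1/(\xi a_v)$ per vertex; $\xi$ rescales time only and steady
states do not depend on it.

**Morphogen.** On the moving surface,
$$
\partial_t\varphi \;=\; D\,\Delta_\Gamma \varphi \;-\; k\,\varphi
\;+\; v_{\max}\,\frac{H^+}{K + H^+},
\qquad H^+ = \max(H - H_{\mathrm{ref}},\,0),
$$
diffusion, linear degradation, and Michaelis–Menten production switched on
only where curvature exceeds the relaxed reference $H_{\mathrm{ref}}$
(one-sided gating: if both bending directions induced expression, the feedback
would oscillate rather than lock in patches). Because local incompressibility
holds, no dilution/concentration term is added to the transport; the recorded
relative local-area drift (kept below 1%) bounds the error of this
approximation and is logged so it can be audited.

**Feedback loop.** $\varphi\uparrow \Rightarrow H_0\uparrow \Rightarrow$
outward bending $\Rightarrow H^+ > 0 \Rightarrow$ production
$\Rightarrow \varphi\uparrow$. The inhibition that a Turing pair would get
from a fast inhibitor comes from mechanics: a bulging patch bends its rim
inward, and inward-bent tissue only degrades morphogen.

## Reduced parameters

With lengths in units of the initial radius $R_0$, energies in units of
$\kappa_0$, and time in units of the morphogen lifetime $1/k$, three constants
remain (`dimensionless_params`):
$$
d^\* = \frac{D}{k R_0^2},\qquad
p^\* = \frac{v_{\max}\,\beta\,R_0}{k},\qquad
m^\* = K R_0 .
$$
This particular reduction is this package's own construction (chosen so that
each headline claim maps onto exactly one knob — $d^\*$ sets patch size,
$p^\*$ patch number, $m^\*$ the gate's saturation scale); the split of
$p^\*$ between $v_{\max}$ and $\beta$ is a gauge freedom absorbed by rescaling
$\varphi$, fixed as $\beta = 1$. Whether the "third constant" of the original
three-parameter description is the Michaelis constant or a curvature scale
cannot be decided from the surviving description; we take it to be the
(scaled) Michaelis constant and flag the choice here. Defaults follow the
source model's restrictions: $\kappa_1 = 0$ (morphogens set curvature, not
stiffness — implemented and tested, but off in all headline experiments),
$H_{\mathrm{ref}}$ and $h_0$ equal to the curvature of the relaxed initial
shape, unit initial radius.

## Spatial discretization

Two backends share one interface:

* **curve2d** — a closed polygon. Curvature is the turning angle divided by
  the dual segment length $a_i = (l_{i-1}+l_i)/2$ (exact $1/R$ limit on the
  circle); the Laplacian is the standard 1D linear-FEM stiffness matrix with
  lumped mass. Used for everything dynamics-heavy: it is two orders of
  magnitude cheaper and has no irregular vertices.
* **surface3d** — a subdivided-icosahedron triangle mesh with cotangent
  stiffness weights and barycentric vertex areas. The signed mean curvature
  comes from the integrated mean-curvature vector
  $K_v = \sum_j \tfrac12(\cot\alpha_{ij}+\cot\beta_{ij})(x_v-x_j)
  = a_v H_v \hat n_v$, with the sign recovered from the area-weighted outward
  vertex normal: $H_v = \operatorname{sign}(K_v\cdot N_v)\,|K_v|/a_v$.

Forces are the **exact gradients of the discrete energy** (not a
discretization of the continuum variation): the chain rule is carried through
the cotangents, triangle areas, turning angles and segment lengths
analytically (compiled in C++ for the surface). This guarantees a true
Lyapunov structure for the discrete flow and is verified against central
finite differences to $10^{-6}$ relative in the tests. The only
non-differentiable points are $|K_v| = 0$ (where the sign convention has a
kink); the sign factor is treated as locally constant, which is exact almost
everywhere.

Two discretization facts shape the defaults:

* On the icosphere the discrete curvature of the *exact* sphere is not
  uniform — the 12 valence-5 vertices read ~14% high, and this bias does not
  vanish pointwise under refinement (the area-weighted $L_2$ error does halve
  per level, which is what the convergence tests assert). The production
  reference and spontaneous curvature are therefore anchored **per vertex** at
  the initial discrete curvature, so the relaxed sphere is an exact
  homogeneous steady state and production is not spuriously switched on at the
  icosahedral vertices.
* There is no remeshing. When element quality (curve: length ratio and
  turning-angle fold guard; surface: $4\sqrt3 A/\sum l^2$) degrades below
  `quality_min`, steps are rejected and the run ends with a recorded terminal
  event once the step size underflows. This is the operational definition of
  **budding**: the scheme is designed for the moderate-deformation regime, and
  runaway outward growth is reported, not silently mangled.

## Time stepping

Operator splitting per step:

1. **Shape, explicit:** $X' = X + \Delta t\,F_{\text{tot}}/(\xi a_v)$ with
   $F_{\text{tot}}$ = bending + penalty (+ external forcing). Explicit rather
   than monolithic-implicit so that each half of the physics is testable
   against closed forms; the stiff fourth-order term then limits $\Delta t$,
   which the controller below handles.
2. **Morphogen, semi-implicit on the updated geometry:** diffusion and decay
   implicit, production explicit at the start-of-step curvature:
   $(M + \Delta t(DK + kM))\,\varphi' = M\varphi + \Delta t\,M\,r$. With the
   lumped mass matrix the system matrix is an M-matrix, so nonnegativity is
   preserved up to roundoff (clamped below $-10^{-12}\times$scale, counted,
   and required rare); a uniform field on a uniform-curvature mesh stays
   uniform to machine precision.

**Adaptive controller.** A step is rejected and $\Delta t$ halved when mesh
quality fails or the mechanical energy rises by more than
`energy_increase_tol`; accepted steps grow $\Delta t$ by 1.2 up to `dt_max`
(rejection wins ties). When external forcing acts, the admissible energy
increase is the work done by the forcing during the step,
$\Delta t\,\langle F_{\text{ext}}, v\rangle^+$, so the internal dynamics must
remain dissipative even in forced runs. Step-size underflow below `dt_min` is
a terminal event, not an error to hide.

Because the controller parks $\Delta t$ at the explicit stability boundary,
the stiffest mesh mode oscillates with small amplitude but finite
*instantaneous* velocity even at mechanical equilibrium. **Equilibrium
detection** therefore uses the displacement over a trailing window of 20
accepted steps divided by the elapsed time (plus the relative total-morphogen
drift rate, with a small absolute floor so fully decayed states register);
window displacement cancels the parked oscillation while genuine creep
survives it.

The curve2d inner loop is compiled (C++, cyclic-tridiagonal solver for the
morphogen step); the R-level `coupled_step` is the reference implementation
and the tests assert the two paths agree.

## Linear-stability oracle and its anchoring

`jacobian_growth_rates` builds the Jacobian of the full semi-discrete system
(positions + morphogen) at a homogeneous steady state by forward finite
differences (step $10^{-6}\times$ state scale — independent of the force
implementation by construction) and reports the leading eigenvalue per
symmetry mode (Fourier index on the circle; spherical-harmonic degree by
projection on the sphere).

The headline model gates production exactly at the relaxed curvature, which
puts the homogeneous state on the *kink* of $H^+$ — not differentiable. For
stability analysis, `homogeneous_state(ref_offset = δ)` shifts
$H_{\mathrm{ref}}$ a distance $\delta$ below the relaxed curvature, so the
base state ($\varphi^\* = p^\*\delta/((m^\*+\delta)k)$, uniform) sits on the
smooth branch, and adjusts $h_0$ so the relaxed shape is *exactly* stationary
for the discrete operators. Measured growth of a seeded single Fourier mode in
the full nonlinear simulator then matches the Jacobian eigenvalue to within a
few tenths of a percent (the tests demand 5%); slow modes need a longer fit
window because the mechanical relaxation rate of mode $m$ scales like
$(m^2-1)^2/\xi$ and the eigenpair separation is poor when that rate is
comparable to the chemical gain.

## Pattern quantification

A **patch** is a connected component (mesh adjacency) of
$\{v: \varphi_v > \theta\}$ with at least 3 vertices; the default threshold
$\theta = \bar\varphi + 0.5(\max\varphi - \bar\varphi)$ is halfway between
mean and maximum (no threshold is inherited from the source; this one is
scale-free and configurable). Runs are classified homogeneous (no patches, or
a field below $10^{-2}$ on the unit concentration scale — i.e. decayed),
patterned, or budding (terminal event before equilibrium).

## Study conditions and problem sizes

The shipped experiments run on the curve backend with $n=64$ nodes,
$\xi^\*=20$, penalty stiffness 1000 (auto-raised with a logged warning if the
area drift ever exceeds 1%), initial morphogen uniform in
$[0.25, 0.75]$, horizon $t_{\mathrm{end}}=150$ with early stopping at
equilibrium; these sizes resolve patch modes up to $m\approx 6$ while keeping
a five-seed sweep under two minutes. Sweep grids were located with the
stability oracle, not transcribed from any source: $d^\*\in\{0.01,0.1,0.6\}$
at $p^\*=6$ spans the transition from a many-patch band to the two-patch
minimum and toward homogeneity, and $p^\*\in\{2.5,7,10\}$ at $d^\*=0.1$ spans
the widening of the unstable band with coupling strength. The virtual
pull/press experiments force a cap of angular radius 0.6 rad with magnitude
0.5 (cosine-tapered, along the local outward normal), seed-matched across the
three arms so differences are attributable to the forcing alone.

## What the synthetic data does and does not emulate

All inputs are generated internally: the relaxed sphere/circle geometry, the
per-vertex uniform initial morphogen (a documented Mersenne-Twister stream
driven by one config seed; the distributional spec, not any particular
generator's stream, is what matters), and optional smoothed random radial
geometry perturbations. This emulates a mechanically relaxed tissue sphere
with molecular-level concentration noise. It does **not** emulate:
viscoelastic or plastic tissue response, cell rearrangement and topology
change, anisotropic or compressible tissue, in-surface advective flows,
reaction noise, or the fully budded limit. Passing tests therefore demonstrate the
mechanism and its parameter controls in the stated regime; they do not
calibrate the model to any measured tissue.

## Known limitations

* Moderate deformations only; budding is detected, not followed.
* The penalty formulation bounds, but does not eliminate, local area drift
  (≤1% by default, with automatic stiffening).
* Max-norm curvature convergence fails at the 12 irregular icosphere vertices
  (mitigated by per-vertex reference anchoring); quantitative surface studies
  should check refinement in the $L_2$ sense.
* At a fixed triple the system is multistable between neighboring patch
  counts: the attractor reached depends on the transient, so for some noise
  realizations two runs differing only in drag (or seed) can settle on counts
  differing by one, with correspondingly different total morphogen. The
  invariance statements in the tests hold under the shipped conditions; they
  are statements about typical behavior, not about every realization.
* The homogeneous-state linearization is one-sided at the headline gate
  (`ref_offset = 0`); the oracle is quantitative on the smooth branch and
  qualitative (onset prediction ≥90% of grid points in the tests) at the kink,
  where rectified dynamics can stabilize marginally unstable points.
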