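# morphomech

Mechanochemical pattern formation on deforming tissue surfaces.

## The problem

During early development, closed epithelial sheets (the blastula, or
reaggregated *Hydra* spheres) break symmetry and form localized structures
without any chemical prepattern. Classical Turing models need a fast-diffusing
long-range inhibitor, which is hard to reconcile with the small, similar
diffusivities measured for real morphogens. `morphomech` simulates an
alternative mechanism: a **positive feedback loop between tissue curvature and
morphogen expression**, in which tissue mechanics itself supplies the
long-range inhibition — a locally bulged-out patch necessarily bends its
surroundings inward, and inward-bent tissue expresses nothing.

The package is for quantitative biologists and modelers who want a tested,
scriptable implementation of this mechanism: to explore its parameter space,
compute where the homogeneous tissue loses stability, and run virtual
micropipette experiments.

## The model

The tissue is a closed surface Γ (or closed planar curve, the fast reduced
backend) carrying a morphogen concentration φ. Its elastic energy is a
modified Helfrich bending energy with morphogen-dependent moduli,

    F[X, φ] = ∫_Γ ½ κ(φ) (H − H₀(φ))² dS,
    κ(φ)  = κ₀ + κ₁ φ          (bending rigidity)
    H₀(φ) = h₀ + β φ           (spontaneous curvature)

where H = κ₁+κ₂ is the mean curvature (unit sphere: H = 2). The shape follows
an overdamped gradient flow of F under **local area incompressibility**
(enforced by a stiff quadratic penalty whose per-vertex multiplier is the
tissue pressure λ); enclosed volume is not constrained. The morphogen obeys a
reaction–diffusion equation on the moving surface,

    ∂φ/∂t = D Δ_Γ φ − k φ + v_max · H⁺ / (K + H⁺),   H⁺ = max(H − H_ref, 0),

i.e. diffusion, linear degradation, and Michaelis–Menten production gated by
*positive* curvature excess over the relaxed reference curvature H_ref.
Because β > 0, high φ raises the preferred curvature, outward bending raises
production — a positive feedback that, combined with the mechanical inhibition
at patch edges, produces stable patches from stochastic initial data.

After nondimensionalization (initial radius = 1, κ₀ = 1, time in units of the
morphogen lifetime 1/k) three constants remain:

| constant | meaning | controls |
|---|---|---|
| `d_star = D/(k R₀²)` | scaled diffusion | patch **size** |
| `p_star = v_max β R₀ / k` | curvature–expression coupling | patch **number** |
| `m_star = K R₀` | half-saturation curvature excess | gate sharpness |

The drag ξ only reparameterizes time: steady states are independent of it.

## Worked example

Spontaneous patterning on the unit circle from uniformly random initial
morphogen (φ₀ ~ U[0.25, 0.75]):

```r
library(morphomech)

cfg <- simulation_config(backend = "curve2d", n = 64,
                         d_star = 0.1, p_star = 6, m_star = 0.3,
                         xi_star = 20, t_end = 150, seed = 1)
tr <- run_simulation(cfg)
tr
#> <trajectory curve2d  steps=135200  t=32.88  status=equilibrium  patches=3  total morphogen=12.624>

count_patches(tr$final$mesh, tr$final$phi)
#> <pattern_summary patches=3  areas=0.682, 0.78, 0.682  threshold=2.903>
```

The run stops at t ≈ 32.9 when the equilibrium detector fires (trailing-window
vertex displacement and total-morphogen drift below tolerance). The final
state has three morphogen patches of nearly equal arc length ≈ 0.7 (the
perimeter is 2π), carrying a total morphogen content Σ φ·a ≈ 12.62.

Where does patterning start? The numerical linear-stability oracle assembles
the Jacobian of the full coupled system at the homogeneous state and reports
the leading growth rate per Fourier mode:

```r
st <- homogeneous_state(build_circle_curve(48), d_star = 0.1, p_star = 6,
                        m_star = 0.3, xi_star = 20, ref_offset = 0.05)
jacobian_growth_rates(st, n_modes = 6)
#>   mode growth_rate
#> 1    0    2.20e-07
#> 2    1   -1.01e+00
#> 3    2    1.48e+00
#> 4    3    4.10e+00
#> 5    4    6.44e+00
#> 6    5    7.86e+00
#> 7    6    8.31e+00
```

Modes 2–6 are unstable (the rigid motions are neutral and uniform
perturbations decay), so the homogeneous
circle spontaneously patterns; nonlinear competition and coarsening select the
three-patch equilibrium seen above.

Virtual experiments (`run_experiment`) run seed-matched control / outward-pull
/ inward-press arms; `parameter_sweep` maps the reduced parameter space. A
command-line wrapper is installed at `inst/cli/morphomech`
(`simulate`, `sweep`, `stability`, `analyze`, `experiment` subcommands).

## Scope and limitations

The discretization handles moderate deformations only: runaway budding ends a
run with a recorded terminal event (step-size underflow / mesh degeneration)
rather than a remeshed budded shape. Tissue compressibility and
morphogen-dependent rigidity (κ₁ ≠ 0) are implemented but off by default. See
the methods vignette (`vignettes/mechanochemical-patterning.Rmd`) for the
numerical design and its rationale.
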