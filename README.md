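# neurostimfem

Finite-element and cable-equation modeling of extracellular neural
microstimulation, self-contained in R.

Microelectrode arrays (MEAs) activate neurons through the potential field
that a current-driven electrode creates in the surrounding medium. Designing
focal stimulation devices — and understanding what they do to nearby cells —
requires two coupled computations: the stimulating field, and the membrane
response of a target neuron inside it. This package implements both of the
standard modeling paradigms for users in neural engineering and
computational neuroscience, with no external FEM or neural-simulation
software:

* **Field solver** — the quasi-static Poisson equation
  `-div(sigma grad V) = 0` on tetrahedral meshes of an in-vitro MEA chamber
  (60 electrodes of 10 µm at 100 µm pitch, with an optional ground-surface
  return), with Robin electrode boundary conditions
  `sigma grad(V).n + g V = g V0` modeling the finite surface conductance `g`
  of the electrode–electrolyte interface, plus two-pass calibration of `V0`
  to a nominal stimulation current.
* **Hybrid pathway** — compartmental cable-equation integration of a neuron
  embedded in the precomputed field (backward Euler, extracellular mechanism
  through axial neighbor differences, Hodgkin–Huxley or passive membranes,
  bisection threshold search).
* **Whole-FEM (thin-film) pathway** — simultaneous solution of the
  extracellular and intracellular potentials with the neuron geometry
  embedded in the mesh and the membrane treated as a zero-thickness
  interface carrying capacitive, leak and ionic current densities
  `Im = cm dVm/dt + gl (Vm - El) [+ IK + INa]`, `Vm = Vint - V`. This
  resolves sub-compartment membrane polarization (electrode-facing vs
  opposite side) that the 1-D cable model cannot represent.

A structured tetrahedral mesh generator (exact cylinder, sphere and capsule
surfaces; tagged electrodes, ground plane, membrane), Gmsh MSH v2.2/v4.1
import/export, SWC morphology reading, analytic validation geometries, and
end-to-end scenario drivers are included. Everything is deterministic.

## Worked example: field focality of the ground-surface configuration

The ground-surface MEA design uses a conductive layer covering the substrate
(except a 10 µm annulus around each electrode) as the current return, which
focalizes the stimulating field. The effect depends on the surface
conductance `g` of that layer — visible only with Robin (not Dirichlet)
boundary conditions:

```r
library(neurostimfem)

params <- mea_params()                       # 60-electrode chamber defaults
mesh   <- build_mea_chamber(params, "full")  # ~0.4 M tetrahedra, ~1 s
foc    <- run_focality(params, g_sweep = c(500, 5e3, 5e4), mesh = mesh)
foc                                          # ~1 min on one CPU
#> <focality_result> profile line at z = 50 um over electrode_4_4
#>                    config fwhm_um
#>                 monopolar  173.05
#>       ground_surface_g500  142.13
#>      ground_surface_g5000  103.52
#>     ground_surface_g50000   79.99
#>  ground_surface_dirichlet   75.31
```

The full width at half maximum of the (normalized) potential profile 50 µm
above the stimulation electrode shrinks from 173 µm (monopolar, distant
ground) to 142 µm with a platinum-like ground surface (`g` = 500 S/m²), and
monotonically further as `g` grows toward the Dirichlet limit.

The hybrid pipeline — calibrate a −1 µA cathodic pulse, sample the field at
the 260 compartment centers of a passive fiber at z = 50 µm, integrate the
cable equation through a 1 ms pulse — reproduces the mirror-image law: the
end-of-pulse membrane polarization is the negated extracellular profile
centered on its spatial average:

```r
mir <- run_mirror_fiber(params, mesh = mesh)
mir
#> <mirror_report> 260 compartments; Ve peak-to-peak 9.267 mV
#>   mirror error: 5.57e-06  correlation: 1  spatial mean dev: -2.28e-11
plot_mirror(mir)
```

`run_comparison()` runs both pathways on the same geometry (a fiber, and a
fiber with a 20 µm soma) and reports the membrane profiles on the
electrode-facing and opposite sides; with the soma, the electrode-facing
pole polarizes several-fold more than the opposite one — the
sub-compartment effect that motivates the whole-FEM pathway.

A thin command-line wrapper is installed with the package
(`inst/exec/neurostimfem`): `neurostimfem run focality --out results/`,
`neurostimfem mesh fiber --out fiber.msh`, with YAML configuration files
accepted via `--config` (see `?read_scenario_config`).

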