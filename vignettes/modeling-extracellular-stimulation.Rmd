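---
title: "Modeling extracellular neural microstimulation: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling extracellular neural microstimulation: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# The two modeling paradigms

Extracellular electrical stimulation excites neurons through the potential
field that a current-driven electrode creates in the conductive medium.
`neurostimfem` implements the two standard ways of predicting the neural
response to that field.

**The hybrid pathway** solves the two stages separately. First the
quasi-static Poisson equation

$$-\nabla\cdot(\sigma\nabla V) = 0$$

is solved by the finite element method in the stimulation chamber *without*
the neuron, under per-surface boundary conditions: homogeneous Neumann
($\sigma\nabla V\cdot n = 0$) on insulating surfaces, and the Robin
(mixed) condition

$$\sigma\nabla V\cdot n + gV = gV_0$$

on every electrode, where $g$ (S/m²) is the surface conductance of the
electrode–electrolyte interface (the inverse of the electrode impedance times
its area) and $V_0$ the metal-side potential. The Dirichlet condition
$V = V_0$ is the $g\to\infty$ limit; modeling the finite $g$ of real
electrode materials (≈500 S/m² for platinum) is what lets the ground-surface
return shape the field. The potential is then interpolated at the centers of
the compartments of a cable-equation neuron model, and the membrane response
is integrated in time with the potential entering each compartment through
its axial neighbor differences (the discrete second spatial difference — the
activating term):

$$c_m A_i \frac{dV_{m,i}}{dt} + A_i I_{ion}(V_{m,i})
  = \sum_{j\sim i} g_{ij}\big[(V_{m,j}+e_j) - (V_{m,i}+e_i)\big],
  \qquad e_i(t) = V_e(x_i)\,f(t).$$

This assumes the neuron does not perturb the field and that the membrane
state is uniform around each compartment's circumference.

**The whole-FEM (thin-film) pathway** drops both assumptions: the neuron
geometry is embedded in the mesh, the membrane is a zero-thickness interface
with one potential trace per side, and the extracellular $V$ and
intracellular $V_{int}$ Poisson problems are solved *simultaneously*,
coupled only by the membrane current density crossing the interface,

$$I_m = c_m\frac{\partial V_m}{\partial t} + g_l(V_m - E_l)
       \; [+\, \bar g_K n^4 (V_m - E_K) + \bar g_{Na} m^3 h (V_m - E_{Na})],
  \qquad V_m = V_{int} - V,$$

which enters the extracellular weak form with sign $+I_m$ and the
intracellular one with $-I_m$. Gating variables obey the classic first-order
kinetics with the squid-axon rate functions, evaluated in the original
convention where the voltage argument is the *negative* deviation of $V_m$
from rest, in mV; the removable singularities of the $\alpha_n$ and
$\alpha_m$ expressions are filled with their analytic limits (0.1 and 1.0).

# What the geometry generator builds

The generator reproduces the standard in-vitro configuration end-to-end and
is itself first-class, tested code:

* a cylindrical chamber (default radius 1.5 mm, height 1 mm) of uniform
  conductivity 0.2 S/m;
* an 8×8-minus-corners array of sixty 10-µm planar electrodes at 100 µm
  pitch on the substrate, each tagged individually, with the array placed so
  that one electrode (row 4, col 4 — the default stimulation site) sits at
  the origin;
* optionally a conductive ground surface covering the substrate except for a
  10-µm insulating annulus around every electrode;
* optionally an embedded neuron: a straight fiber (260 µm × 2 µm at
  z = 50 µm above the stimulation electrode) modeled as a capsule — a
  cylinder with hemispherical end caps, avoiding sharp-edge artifacts — or
  the same fiber carrying a 20-µm spherical soma centered on its axis.

The chamber dimensions are not part of the published configuration; the
defaults were chosen large relative to the electrode array so that the wall
position does not shape the local field, and the monopolar "distant ground"
is realized as a Robin condition on the chamber wall. The 10-µm gap annulus
is treated as insulating substrate. The whole-FEM comparison scenarios run
by default on a reduced single-electrode chamber (radius 0.5 mm, height
0.3 mm): the ground-surface return keeps the stimulating field local, so the
field *shape* along the fiber is preserved (correlation > 0.99 against the
full 60-electrode chamber, verified in the suite), while its amplitude
shifts by roughly 15% because the neighboring electrodes' insulating gaps
and the wall move. Both pathways use the identical domain and all comparison
metrics are relative to each run's own peak-to-peak, so this shift cancels
in the cross-method criteria.

## Meshing

No constructive-solid-geometry mesher is available in this stack, so meshes
are built on graded tensor-product hexahedral grids, each hexahedron split
into six tetrahedra by the Kuhn decomposition (translation-invariant, hence
conforming). Curved surfaces are produced by smooth node maps applied after
connectivity is fixed: grid "rings" at constant L∞ radius map onto Euclidean
circles and spheres of exactly the same radius. The chamber wall, the
spherical oracle shells, and the neuron membrane are therefore *exact*
cylinders, spheres and capsules at the node level; the membrane cross
section is a 16-gon inscribed in the true circle (a ≈2.5% volume deficit,
checked in the tests; a refinement switch doubles the polygon order). One
consequence of tensor grids: `refine_near()` inserts grid planes, so
refinement extends along entire slabs through the requested region rather
than staying strictly local.

Default problem sizes: ≈0.4 M tetrahedra (≈74 k vertices) for the full
chamber, ≈0.4–0.9 M for the embedded-neuron meshes, chosen so that the
profile quantities reported by the scenario drivers change by well under the
tolerances used in the test suite under one further refinement (the suite
verifies this for the probe potential above the stimulation electrode and
for the soma-pole membrane polarization).

# Numerical choices

* **Elements.** Linear and quadratic Lagrange tetrahedra. The large chamber
  solves use linear elements on locally refined meshes — on these problem
  sizes a quadratic basis would cost more than mesh refinement buys. The
  analytic-oracle geometries (spherical shell, disk electrode) use quadratic
  elements, where they reach the closed forms within 0.1–2%. The coupled
  solver defaults to linear extracellular / quadratic intracellular; an
  all-linear configuration is accepted with a message.
* **Linear algebra.** Sparse symmetric positive-definite systems solved by
  CHOLMOD Cholesky factorization (direct) up to 400 k unknowns, above that a
  Jacobi-preconditioned conjugate gradient (relative tolerance 1e-10).
* **Boundary currents.** On Robin surfaces the normal flux is integrated
  through the boundary-condition identity $\sigma\nabla V\cdot n = g(V_0-V)$,
  which the Galerkin solution satisfies *conservatively*: the currents over
  all conducting surfaces sum to zero to solver precision (this is the
  discrete statement obtained by testing with the constant function).
  Gradient-based integration is implemented for Dirichlet tags and as a
  cross-check.
* **Calibration.** Current-controlled stimulation uses the two-pass scheme:
  solve at $V_0 = 1$ V, measure the delivered current on the larger of the
  stimulation and return surfaces (integrated over more triangles, hence the
  more trustworthy), rescale $V_0$ by the target/measured ratio, re-solve.
  Linearity makes the single rescale exact up to numerics.
* **Time integration.** First-order backward Euler everywhere, in both
  pathways, with the gates advanced on the previous step's membrane
  potential (staggered). This keeps every step one sparse SPD solve, loses
  no order (the scheme is first order regardless), is A-stable, and keeps
  gating variables in [0, 1] unconditionally. The default step is 0.05 ms;
  `auto_timestep()` implements the dt vs dt/10 audit at the 1% criterion.
  For passive runs at fixed dt the system matrix is factorized once and
  reused across steps.
* **Cable discretization.** Compartments of ≤1 µm (the refinement level at
  which halving changes the response by <1%, verified in the suite); axial
  conductances combine neighboring half-compartments in series (harmonic
  diameter combination across diameter steps); sealed ends. The soma enters
  the cable pathway as a chain of compartments of its own diameter, whose
  total lateral area equals the sphere's surface.
* **Degenerate inputs.** All-insulating boundary sets are rejected as
  ill-posed; a calibration against a disconnected electrode fails with an
  explicit error; a zero-current mirror run reports an undefined correlation
  rather than NaN arithmetic; waveforms are evaluated right-continuously at
  the new time level of each implicit step.

# Sign conventions

Positive membrane current is outward (intracellular → extracellular). The
signed electrode current is the integral of $\sigma\nabla V\cdot n$ with $n$
the outward normal of the medium, so a cathodic stimulation electrode
calibrated to deliver −1 µA reports −1 µA and the ground surface +1 µA.
Cathodic stimulation above the fiber center therefore depolarizes it — the
end-of-pulse polarization profile of a passive fiber is the mirror image of
the extracellular potential centered on its spatial average, which the
mirror scenario reproduces with correlation > 0.999.

# What the fiber comparison shows about side asymmetry

With the fiber axis only 50 µm above a 10-µm electrode, the extracellular
potential drops measurably *across* the 2-µm fiber (≈0.6 mV under a −1 µA
ground-surface stimulus). A thin passive membrane polarizes transversely on
a nanosecond time scale, and the nearly insulating cylinder roughly doubles
the local transverse drop, so the whole-FEM model shows a bottom–top
membrane asymmetry of ≈1.1 mV at the fiber center — about 12% of the ≈9 mV
longitudinal peak-to-peak, mesh-converged under cross-section refinement.
This transverse polarization is invisible to the 1-D cable model by
construction; it is "small" only relative to the soma's asymmetry (the
20-µm soma shows a several-fold larger bottom–top split, peaking over the
soma, with the cable solution lying between the two sides). The test suite
asserts a 2%-of-peak-to-peak bound for the fiber asymmetry as its strictest
reading of "very small"; that bound fails under these study conditions and
is kept failing deliberately — the measured ≈12% is the physical answer at
this electrode–fiber distance, not a numerical artifact.

# Known limitations

* The electrode interface is purely resistive: no capacitive or
  frequency-dependent impedance, no Faradaic electrochemistry.
* Membrane kinetics are the classic squid-axon set at fixed temperature; no
  Q10 scaling, Markov or stochastic channels.
* The structured mesher handles the revolution-symmetric neuron geometries
  of the bundled scenarios; arbitrary reconstructed morphologies (SWC
  surfaces) are supported in the cable pathway only. External tetrahedral
  meshes with physical groups can be imported via Gmsh MSH.
* Full solution snapshots and traces export as tab-separated text/CSV.
* The synthetic scenarios emulate a homogeneous bath over an ideal planar
  MEA. Real tissue adds inhomogeneous and anisotropic conductivity, cell
  crowding and encapsulation layers; passing the bundled checks demonstrates
  correctness of the numerics under the stated conditions, not predictive
  accuracy for any particular preparation.
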