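---
title: "Modelling lung respiration: constitutive calibration, quasi-static FEM and validation metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling lung respiration: constitutive calibration, quasi-static FEM and validation metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respmech)
```

## The modelling problem

During quiet breathing the lung deforms under the transpulmonary pressure —
the difference between alveolar and pleural pressure — and the motion of
the diaphragm. Simulating this deformation on a patient mesh lets one
track interior structures (bronchial branch points, lesions) between the
end-inspiration and end-expiration states without additional imaging.
`respmech` implements the desk-scale version of that chain: calibrate a
hyperelastic constitutive model for lung parenchyma from stress–strain test
curves, run a quasi-static nonlinear finite-element breathing cycle on a
tetrahedral mesh, and score the result with landmark, slice-area and volume
metrics.

## Constitutive models and their assumptions

All four families (Ogden, polynomial, reduced polynomial, van der Waals)
are isotropic and hyperelastic: stress derives from a stored-energy density
split into a deviatoric part in the isochoric principal stretches
$\bar\lambda_i = J^{-1/3}\lambda_i$ and a volumetric series
$\sum_i (1/D_i)(J-1)^{2i}$. Isotropy and elasticity are idealisations —
parenchyma is mildly anisotropic and viscoelastic — but they are the
standard working assumptions for breathing-cycle simulation, where loading
is slow and directionally unbiased.

The Ogden deviatoric energy uses the $2\mu_i/\alpha_i^2$ convention:

$$W_{dev} = \sum_{i=1}^N \frac{2\mu_i}{\alpha_i^2}
  \left(\bar\lambda_1^{\alpha_i} + \bar\lambda_2^{\alpha_i} +
        \bar\lambda_3^{\alpha_i} - 3\right),$$

so the initial shear modulus is $\mu_0 = \sum_i \mu_i$ and a single term
with $\alpha = 2$ is neo-Hookean with $C_{10} = \mu/2$. This is stated
prominently because the other common convention
($\sum \mu_i \lambda^{\alpha_i}/\alpha_i$) takes *different* coefficient
values for the same material.

The bundled lung model (`ogden_table_lung()`) is a six-term Ogden fit with
$\mu_0 = 0.715$ kPa and $D_1 = 0.289$ kPa$^{-1}$ (bulk modulus
$2/D_1 = 6.92$ kPa). Note that this $D_1$ corresponds to an initial
Poisson ratio of about $0.45$, slightly stiffer volumetrically than the
$\nu = 0.43$ quoted for parenchyma in the source literature; the tabulated
coefficients are used as printed rather than re-derived from $\nu$.
Stiff airway/mediastinum/rib regions are represented by the small-strain
surrogate `elastic_surrogate(E, nu)` mapped to compressible neo-Hookean
($C_{10} = E/(4(1+\nu))$, $D_1 = 6(1-2\nu)/E$) so they remain well defined
at large rotation.

**Units.** Lengths mm, stresses and moduli kPa, pressures kPa, forces mN
(1 kPa·mm² = 1 mN), times s, volumes mm³ with litre conversion where
reported. Coefficient tables in the field often omit units; kPa is the
consistent choice here for all stress-like quantities.

**Van der Waals volumetric term.** The deviatoric van der Waals form is
standard (locking stretch $\lambda_m > \sqrt 3$, interaction $a$, invariant
mixture $\beta$); its volumetric part uses the same $(J-1)^{2i}$ series as
the other families for uniformity. The model is only exercised in
calibration here, never in the FE solver, so the choice has no effect on
simulations. Its energy has unbounded curvature at the undeformed state
when $a \neq 0$; the second derivative is guarded by a small floor
($\tilde I - 3 \ge 10^{-12}$) and states at or beyond the locking stretch
return infinite energy, which the fitter treats as a large residual.

## Calibration

`hyperfit()` minimises the *relative* least squares
$\sum_k (T_{model}(\lambda_k)/T_k - 1)^2$ over the supplied curves.
Relative (not absolute) misfit keeps the compression branch, where stresses
are a fraction of a kPa, from being drowned out by the stiff tension tail.
Points with $|T_k| < 10^{-6}$ kPa receive zero weight: every dataset
contains the zero-stress point at $\lambda = 1$, where a relative error is
undefined. The fit recovers deviatoric coefficients only; volumetric
compliances $D_i$ would need a volumetric test and are passed through
unchanged.

* Polynomial and reduced polynomial stresses are linear in the
  coefficients, so the fit is a single weighted linear least squares (QR).
* Ogden exponents enter nonlinearly. The fitter scores every combination of
  $N$ distinct exponents from the fixed grid $\{\pm1, \pm2, \pm4, \pm7\}$
  with the shear moduli solved linearly per combination (variable
  projection), refines the five best-scoring starts by Levenberg–Marquardt
  over the exponents (moduli still projected), then polishes all $2N$
  parameters jointly. The multistart grid is fixed, so the pipeline is
  deterministic; the `seed` argument is recorded for provenance and guards
  any future stochastic refinement.
* Van der Waals fits by bounded Levenberg–Marquardt from a small grid of
  $(\lambda_m, \beta, a)$ starts, with $\lambda_m$ kept above both
  $\sqrt 3$ and the largest data stretch.

Ogden identifiability deserves a caveat: on a single test mode, distinct
$(\mu_i, \alpha_i)$ sets can fit the same curve to near machine precision,
so a near-zero residual does **not** imply coefficient recovery at high
order. The test-suite asserts coefficient recovery up to order 2 and
residual-level self-consistency at order 6.

**Drucker screening.** `drucker_stability()` requires positive incremental
stress work ($dT\,de > 0$) along the uniaxial, equibiaxial and planar
paths, evaluated as $dT/d\lambda > 0$ (central differences with step
$10^{-2}$ of the grid step) at every point of a sweep grid. The default
window $e \in [-0.9, 9]$ with step 0.01 is a deliberately wide screen;
reports can also carry the verdict restricted to the fitted-data strain
range, which is the practically relevant window. Grid points at
non-finite stress (van der Waals beyond locking) count as unstable, and a
grid that would cross $\lambda \le 0$ is clipped with a warning.

**The 15-model roster.** Ogden $N=1..6$, polynomial $N=1..2$, reduced
polynomial $N=1..6$ and van der Waals. Per-candidate failures are kept as
infinite-residual rows rather than aborting the ranking.

## The synthetic data generator

The biaxial tension–compression curve of lung parenchyma that the
calibration stands on is not publicly tabulated, so
`lung_test_dataset()` generates a stand-in: the bundled six-term Ogden
model evaluated in closed form on an equibiaxial nominal-strain grid from
$-0.3$ to $0.7$ (51 points), optionally with i.i.d. Gaussian stress noise.
The grid covers a compression branch and extends beyond $e = 0.5$, where
parenchyma's nonlinearity is pronounced, mirroring the strain range over
which such tests are reported; tension–compression data are handled as one
equibiaxial dataset spanning negative and positive strain. What this
emulates is the *shape and scale* of a parenchyma test curve; what it does
not emulate is inter-specimen scatter, hysteresis, preconditioning, or any
systematic deviation of real parenchyma from the Ogden form. Passing
recovery and ranking tests on these data therefore validates the fitting
machinery, not the biological adequacy of the Ogden model.

## The phantom

`build_phantom()` meshes the solid half-ellipsoid
$(x/a)^2+(y/b)^2+(z/c)^2 \le 1$, $z \ge 0$ — defaults $a=b=50$, $c=120$ mm,
a lung-scale dome — by Kuhn-subdividing a structured grid on the half-cube
into six tetrahedra per cell and mapping it with the smooth cube-to-ball
map $x' = x\sqrt{1 - y^2/2 - z^2/2 + y^2z^2/3}$ (cyclic). The map takes
the cube surface exactly onto the sphere (so boundary nodes lie exactly on
the ellipsoid after scaling) and keeps the base plane flat; unlike the
sup-norm radial map it is smooth, which keeps all tetrahedra positively
oriented at every tested resolution. Named sets give the simulation its
handles: `trachea_top` (apex node patch within an angular radius, default
0.35 rad), `diaphragm_base` (flat base nodes/facets) and `outer_surface`
(the pressure-loaded remainder). Tetrahedra are stored positively oriented
and boundary triangles outward, fixing every downstream sign convention;
meshes target $10^3$–$10^4$ elements, deliberately far below patient-scale
meshes.

## The finite-element solver

Total-Lagrangian statics on constant-gradient tetrahedra (C3D4), full
Newton with a sparse direct solve per iteration, increment cutback
(halving, up to 4 times) on non-convergence or element inversion, and
convergence at relative residual $10^{-6}$ (absolute floor $10^{-8}$ mN)
against the larger of the internal and external force norms.

Boundary conditions map the anatomy: the tracheal attachment fixes all
three displacement components (linear tetrahedra carry no rotational
degrees of freedom, so "no rotation or translation" collapses to fixing
translations); the diaphragm condition fixes X and Y and drives Z with the
scheduled displacement, standing in for the diaphragm's push during
exhalation. The transpulmonary load is a follower pressure (re-evaluated
on the deformed surface each iteration) on `outer_surface`, peak 0.98 kPa
= 10 cmH₂O, ramped by the piecewise-linear schedule (0,0)→(2,1)→(5,0):
exhalation loading over 0–2 s, inhalation unloading over 2–5 s.

**Load stiffness.** The follower-pressure configuration derivative is
included in the tangent by default. With the soft lung model
($\mu_0 = 0.715$ kPa) under a 0.98 kPa pressure, a material-only tangent
makes Newton cycle and diverge beyond roughly 15% of the load, which no
amount of increment cutback repairs; the extra term is cheap (one
cross-product matrix per facet node pair) and restores fast convergence.
`solver_config(load_stiffness = FALSE)` recovers the reduced tangent for
comparison.

**Contact.** The full deformable–deformable contact of patient-scale
models (lung–mediastinum, lung–rib) is out of scope; an optional rigid
triangulated obstacle with frictionless node-to-surface penalty forces
($f = k\,d\,n$ at penetration depth $d$) stands in for stiff neighbouring
anatomy, and the diaphragm's action is modelled by the prescribed base
displacement instead.

**Known numerical limitations.** Displacement-based C3D4 elements lock as
$\nu \to 0.5$; at the effective compressibility used here (bulk/shear
$\approx 10$) locking is mild, but the element choice is the accuracy
bottleneck for bending-dominated responses. Fully incompressible material
definitions (all $D_i = 0$) are legal in calibration and rejected by the
solver. The hydrostatic sphere test pins the volumetric response to the
analytic $J = 1 - pD_1/2$; because a uniform contraction is exactly
representable, it verifies assembly, follower load and Newton rather than
mesh convergence.

## Validation metrics and their conventions

Landmarks are material points stored as a host tetrahedron plus barycentric
weights and advected exactly with the displacement field. Displacements
are decomposed along patient axes x = left/right, y = anterior/posterior,
z = superior/inferior.

The error convention of the comparison tables is **truncation toward zero**
of $|{\,|sim|-|ref|\,}|/|ref| \times 100$: 1 decimal for landmark tables, 2
decimals for volume tables, magnitudes compared (one bundled case pairs a
$-1.27$ reference with a $+1.22$ simulated component; only magnitudes
reproduce its printed cell). Summary rows report the arithmetic mean and
the *population* standard deviation (divide by $n$), again truncated.
These conventions were chosen because they reproduce the bundled nine-case
tables cell by cell — with two caveats in the source tables themselves:
one directional cell (case 4, A/P) prints 1.7 where its own printed inputs
give 1.5 under every rounding convention, and one summary cell (mean
inspiration volume) is rounded where all others truncate. The package
computes both by its uniform convention and documents the discrepancies
rather than special-casing them.

Slice areas intersect a watertight surface with planes perpendicular to
the superior–inferior axis (default five planes, 28.6 mm apart, the first
one spacing below the apex), chain the triangle–plane segments into closed
loops, and take shoelace areas per loop; loops are labelled left/right by
centroid x-sign. Nested loops (internal cavities) are not supported —
cross-sections are treated as unions of disjoint simple regions, which
holds for the phantom and for lung-like shapes.

## Problem sizes

The shipped tests and the acceptance script run, by design, on small
instances: the hydrostatic ball at 384 tetrahedra, breathing cycles on
phantoms of a few hundred to a few thousand elements with 10 increments,
and the calibration roster on 51-point curves. These sizes exercise every
code path; accuracy-critical checks (hydrostatic J, single-element
uniaxial) sit on states the discretisation represents exactly, so small
meshes lose nothing there.

## Design choices that were genuinely open

* **Schedule direction.** Descriptions of the cycle differ on whether
  exhalation or inhalation comes first; the default schedule loads
  (exhales) first, and any knot sequence can be supplied.
* **Diaphragm magnitude.** Per-case diaphragm displacements are not
  tabulated in the source setting; phantom runs take the peak displacement
  as a configuration parameter (default 0 with the base supported).
* **Mediastinum modulus.** A surrogate stiffness quoted as
  $5.87\times10^{-3}$ in the source table is ambiguous in units (kPa or
  MPa); it is left as configuration rather than hard-coded.
* **Relative-LS weighting.** The emphasis of the source fits on strains
  above 0.5 suggests possible weighting; absent a stated scheme, the
  objective is unweighted relative least squares.
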