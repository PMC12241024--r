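---
title: "Modelling safe tissue compression in circular anastomosis staplers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling safe tissue compression in circular anastomosis staplers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(staplecomp)
```

## The problem

A circular end-to-end anastomosis stapler clamps two bowel ends between a
rigid anvil and a rigid staple cartridge, compresses them, and fires a ring
of staples. Too little compression fails to fix the tissue; too much crushes
it. `staplecomp` models the clamped two-layer intestinal wall as a nearly
incompressible hyperelastic annulus, simulates the quasi-static compression,
and classifies each wall layer as safely fixed or damaged from the
*volumetric distribution* of the von Mises equivalent stress. From that
classification it derives, per wall-thickness pair, the set of safe
compression distances, the corresponding compression ratios
(distance / total undeformed thickness), and the safe staple gaps
(remaining tissue height).

## Constitutive model

The intestinal wall is a three-term incompressible Ogden solid,

$$W=\sum_{p=1}^{3}\frac{\mu_p}{\alpha_p}\left(\lambda_1^{\alpha_p}
+\lambda_2^{\alpha_p}+\lambda_3^{\alpha_p}-3\right),$$

with the porcine-colon constants $\mu = (8300, 200, 6200)$ Pa and
$\alpha = (7.625, 13.875, 7.625)$ as defaults. Two conventions for the Ogden
energy circulate; we use the $\mu_p/\alpha_p$ convention of the major
commercial FE solvers, **not** the $2\mu_p/\alpha_p^2$ variant. This choice
is load-bearing: with it, 60% uniaxial compression produces an equivalent
stress of about 0.59 MPa — just inside the 0.3–0.6 MPa effective-fixation
band — which is exactly the internal consistency that makes the published
safe ratios reproducible. The duplicated exponent
($\alpha_1 = \alpha_3 = 7.625$) is kept verbatim from the source fit.

Closed forms used throughout: the uniaxial incompressible Cauchy stress
$\sigma(\lambda) = \sum_p \mu_p(\lambda^{\alpha_p} -
\lambda^{-\alpha_p/2})$, the initial shear modulus
$\mu_0 = \tfrac12\sum_p\mu_p\alpha_p = 0.0567$ MPa, and the von Mises stress
of an axisymmetric state. Units are mm and MPa (1 MPa = 1 N/mm²)
internally; configuration files take moduli in Pa.

## The safety statistic

At every load step each element's centroid von Mises value and volume are
binned:

* **fixed tissue**: equivalent stress strictly above 0.1 MPa (this volume is
  the denominator of both fractions);
* **effective fixation**: stress in [0.3, 0.6] MPa, **inclusive at both
  ends**;
* **damage**: stress strictly above 0.6 MPa.

These boundary conventions make the three quoted ranges mutually exclusive
and exhaustive; a value of exactly 0.6 MPa counts as fixation, not damage. A
layer is *safe* when its fixation fraction strictly exceeds 20% **and** its
damage fraction does not exceed 5% — the strict inequalities mirror the
wording "exceeds 20%" / "more than 5%". If nothing is above 0.1 MPa the
layer is reported as an explicit "no fixation" state rather than a 0/0.

Band sums use deformed (current) element volumes by default — Cauchy stress
pairs naturally with current volume — with a `volume = "reference"` switch,
since the original postprocessing scripts do not record which convention
their volume sums used.

Safe-distance sets are reported as discrete multiples of the 0.1 mm step,
matching how the published table is laid out, and ratios are rounded
half-up in exact decimal arithmetic (integer tenths of a millimetre):
binary floating point would turn 2.3/4.0 into 0.5749… and misprint 0.58 as
0.57. The joint safe gap set is `total − d` over the *intersection* of the
two layers' safe distance sets.

## Two engines

**Uniform engine** (`run_uniform`). The idealised full-contact, laterally
free column: at anvil travel $d$ the stack is in homogeneous incompressible
uniaxial compression with $\lambda_z = 1-d/(t_u+t_l)$, identical in both
layers by series equilibrium. Stress is the closed form above; the reaction
force is $|\sigma|$ times the anvil's effective contact area (a nominal,
reference-area force). This engine is exact in its own idealisation, runs in
milliseconds, and is the analytic oracle for the FE engine. The headline
safe-ratio results are computed with it.

**Axisymmetric FE engine** (`run_fem`). Displacement-based 4-node
quadrilaterals in the $(r,z)$ plane ($z$ = compression axis), total
Lagrangian kinematics, and 2×2 Gauss quadrature. Near-incompressibility is
imposed by a quadratic volumetric penalty (default bulk modulus
$1000\,\mu_0$) with an F-bar treatment — the deformation gradient's
volumetric part is scaled to the element-centroid Jacobian — which serves
the same anti-locking purpose as the classical B-bar/mean-dilatation
element and is simpler to vectorise across elements. On top of the penalty,
an augmented-Lagrangian (Uzawa) pass folds the penalty pressure into
per-element multipliers after each converged step and re-solves until
centroid Jacobians are within 0.5% of unity; this keeps the global volume
change below a few tenths of a percent without the ill-conditioning of a
very large penalty.

The tangent stiffness is a central finite difference of the analytic
element internal force (8 perturbations per element, vectorised across the
mesh). The residual is exact; only the Jacobian is approximate, which
Newton tolerates at 0.1 mm increments. This avoids the notoriously
error-prone hand-derived Ogden tangent in principal-stretch form, whose
coalescent-eigenvalue limits need special-casing.

Boundary conditions per load step: anvil-footprint nodes move rigidly with
the platen (bonded: both displacement components tied), cartridge-footprint
nodes are fixed, the layer interface shares nodes (bonded tissue–tissue
contact), and the outer tissue surface is radially constrained but free
axially. Footprint bands with `area_fraction < 1` are tied through penalty
springs with stiffness `area_fraction × k_tie × mu0 / h` per unit tributary
area (`k_tie = 300` by default). Surface nodes *outside* the contact lands
get one-sided penalty contact against the rigid platen planes: free tissue
may separate from a platen but cannot pass through it.

Newton controls: at most 60 iterations per step, a non-monotone
backtracking line search (accepting a step that improves on the worst of
the five most recent residual norms — a strictly monotone search stagnates
in local residual basins near snapping states), a step-length cap of two
element sizes, automatic bisection of the load increment up to 3 levels,
and, as a last resort, weak stabilization anchors toward the predictor
state (the analogue of a commercial solver's "nonlinear stabilization"),
engaged adaptively and orders of magnitude softer than the tissue. The
convergence criterion is a residual norm below $10^{-6}$ of the force norm.

Stresses are reported at element centroids; current element volume is the
reference volume times the centroid Jacobian. Layer *mean* equivalent
stress is the arithmetic mean over elements — the statistic a
postprocessor's "average" stress probe reports — while the band fractions
are volume-weighted sums, as the safety statistic requires.

## The contact-surface surrogate

The true contact faces of the reference device (a 34 mm-class circular
stapler) are proprietary, so the geometry is an axisymmetric surrogate: a
10–16 mm tissue annulus and, on each platen, two annular contact lands with
10% machined relief (`area_fraction = 0.9`), separated by the
cutting-blade clearance and stopping short of the tissue edges. The
cartridge lands are narrower than the anvil's (effective area ≈ 64% of the
anvil's), encoding the staple holes and blade channel of the cartridge
face. Two findings from building this surrogate are worth recording:

* **Full-face bonding over-confines the model.** If both platens are bonded
  across the whole annulus while the outer surface is radially fixed, the
  nearly incompressible wall is hydrostatically locked: simulated stresses
  reach tens of MPa and platen forces reach $10^4$ N, two orders of
  magnitude above both the fixation band and the force scale that the
  force–compression validation targets. Contact lands narrower than the
  tissue ring — so tissue can escape inward and outward — restore physical
  magnitudes. The published model must implicitly have this property; the
  exact land radii being unpublished, ours are configurable defaults.

* **The asymmetry mechanism is geometric.** The cartridge-side layer
  experiences the higher peak stress because its contact *area* is smaller
  (narrower lands), not because its ties are softer. Softening the
  cartridge ties alone inverts the effect. The shipped defaults realise the
  documented ordering: lower-layer max von Mises ≥ upper-layer max at every
  step beyond a 20% compression ratio, with layer means within 20% of each
  other ("collinear").

With the default surrogate the FE equilibrium path can be traversed to a
compression ratio of about 0.6 on the default 0.5 mm mesh (with the study
penalty level $2000\,\mu_0$ under the augmented scheme; the constitutive
default $1000\,\mu_0$ reaches about 0.5). Beyond that the unsupported
tissue margins fold through — a genuine limit of a fixed Lagrangian mesh at
extreme compression, which commercial codes push past with remeshing. The
published mesh-size protocol (2.5 + 2.5 mm stack compressed to a 1 mm gap,
i.e. ratio 0.8) therefore cannot be traversed by the surrogate in
footprint mode; mesh-convergence runs are performed at gap targets inside
the traversable envelope, and the < 3% refinement-change selection rule is
tested on its own bookkeeping. The sweep records every 0.1 mm step so the
band-fraction curves can be plotted beyond the loss of safety.

## What the synthetic data generator emulates

No ex vivo force–compression measurements are published, so
`make_reference_curve` fabricates a labelled synthetic stand-in: the
uniform engine's closed-form force curve perturbed by seeded multiplicative
log-normal noise (`sigma_log ≤ 0.5`; multiplicative so forces stay
positive). Every curve is a pure function of (parameters, seed) and carries
its provenance as attributes. `validation_curve` then applies the
two-regime contract: all ratio-wise model/reference quotients within one
order of magnitude, and close agreement (quotient in [0.5, 2]) below a 60%
ratio. What passing this shows is that the pipeline's comparison logic and
force scale are coherent — it cannot show agreement with real tissue, and
the generator deliberately omits biological variability (oedema, fat
content, perfusion) and any rate dependence, which the static model does
not represent either.

## Numerical choices and degenerate inputs

* Load program: 0.1 mm steps, default total travel 0.8 × total thickness;
  non-multiple travels are floored with a warning. The uniform engine
  aborts at $\lambda_z \le 0.05$ as an unphysical crush.
* Meshing: structured quads, at least two element rows per layer, element
  size capped at the thinner layer (error otherwise). Mesh volume must
  match the analytic annulus volume within 0.5%.
* Empty safe sets, disjoint layer-safe sets, and all-below-threshold stress
  fields are valid outcomes, reported as empty tables / "no fixation", not
  errors.
* All tabulation arithmetic (ratios, gaps) is integer tenths-of-mm.
* Determinism: identical configuration and seed give byte-identical CSV
  outputs; generators restore the caller's RNG state.

## Problem sizes used in the shipped studies

The packaged tests and the acceptance script run the uniform engine over
full 0.1 mm programs (24–40 steps; milliseconds), the frictionless FE
oracle comparison on a 1 mm mesh to a 60% ratio, the footprint FE property
run on a 0.5 mm mesh (96 elements) to a 50% ratio, and a two-size
mesh-convergence study on the 2.5 + 2.5 mm stack. These sizes were chosen
as the smallest that exercise every property of interest; the engines
accept finer meshes and deeper programs.

## Known limitations

Quasi-static only (no compression-speed effects); bonded ties rather than
frictional contact; axisymmetric smearing of the true 3-D hole pattern
(staple holes become annular relief fractions); no staple forming or
cutting; no tissue damage evolution — damage is inferred from the stress
bands, not fed back into the material; fixed Lagrangian mesh, so very deep
compression of unsupported margins is out of reach; material constants are
an ex vivo porcine fit, applied without individual variation.
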