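---
title: "Abdominal-wall mechanics with stoma incisions: model, phantom and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Abdominal-wall mechanics with stoma incisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`wallfem` simulates the mechanical response of the human abdominal wall
to intraabdominal pressure (IAP), with a focus on what happens around a
stoma incision (trephine). This vignette is the package's own account of
the science: the constitutive model and its assumptions, what the
synthetic wall phantom does and does not emulate, every numerical
convention that affects results, and the known limitations.

## The mechanical model

**Constitutive law.** All tissues are isotropic, homogeneous,
small-strain linear elastic: $\sigma = \mathbf{C}(E,\nu)\,\varepsilon$
with Lamé constants $\lambda = E\nu/((1+\nu)(1-2\nu))$ and
$\mu = E/(2(1+\nu))$. The default Young's moduli come from uniaxial
tension data on abdominal muscle tissue and a tendon-tissue value for
the linea alba:

| region | tissue analogue        | E (MPa) | $\nu$ |
|--------|------------------------|---------|-------|
| EO     | external oblique       | 1.00    | 0.3   |
| IO     | internal oblique       | 0.65    | 0.3   |
| RA     | rectus abdominis       | 0.52    | 0.3   |
| TR     | transverse abdominis   | 1.03    | 0.3   |
| LA     | linea alba (tendinous) | 72      | 0.3   |

Skin and subcutaneous fat are excluded on the usual grounds that they
are at least an order of magnitude softer than muscle and therefore do
not control the load path.

**Loading and supports.** The IAP is a uniform pressure on the inner
(concave) wall surface, applied as a *dead* load on the reference
configuration — the only choice consistent with a one-shot linear
solve; no follower-pressure update is performed. The four lateral wall
edges carry a homogeneous Dirichlet (zero displacement) condition,
standing in for the attachment of the musculature to the skeleton. Five
IAP levels up to 20 kPa (the pressure reached when coughing or jumping)
are swept by default; because the model is linear the levels are exact
scalar multiples of one solve, and the sweep exploits this (one
factorisation per geometry) with an independent-solve self-check on the
first geometry. The intermediate level spacing (4, 8, 12, 16, 20 kPa)
is an equal-spacing choice; only the 20 kPa results are typically
examined.

**Discretisation.** Linear (P1) tetrahedra with element-constant strain
and stress; the stiffness is assembled from the closed-form per-element
expression $K_{ab} = V(\lambda\, g_a g_b^{\mathsf T} + \mu\, g_b
g_a^{\mathsf T} + \mu (g_a \cdot g_b) I)$ with $g_a$ the hat-function
gradients. Surface pressure becomes work-consistent nodal forces
($pA/3$ per facet node along the inward-pushing facet normal). The
linear systems are solved with a sparse supernodal Cholesky
factorisation (deterministic); a Jacobi-preconditioned conjugate
gradient solver (tolerance $10^{-10}$) is available for larger meshes.
The von Mises stress is computed per element; for visualisation a
volume-weighted nodal average is also exported, but all reported maxima
are element maxima (the conservative choice). Maximum deformation is
the largest nodal displacement Euclidean norm in mm.

**Small-strain caveat.** At 20 kPa the default phantom deflects by
roughly 100 mm — comparable to the wall size — so the linear model is
extrapolating far outside the small-strain regime. This is a deliberate
fidelity choice: the constitutive statement of the method is linear and
no large-deformation kinematics is assumed anywhere. Absolute
displacements and enlargements should be read as linear-response
indicators, not as literal geometry; comparisons *between* stoma
positions share the same bias. One visible consequence is discussed
under "Limitations".

## The synthetic wall phantom

Patient-derived anatomy meshes are rarely distributable, so the package
ships a deterministic phantom that reproduces the *mechanical
structure* of the abdominal wall: four soft
muscle strata in series through the thickness, a stiff tendinous strip
joining the two halves in parallel, curvature, edge fixation, and a
circular through-hole at labelled positions.

* **Geometry.** A $300 \times 400$ mm wall, four strata of 3 mm each
  (EO, IO, RA, TR from outer to inner), a 20 mm wide full-thickness
  midline strip (LA), bent to a mid-surface cylinder of radius 200 mm
  about the vertical axis. All dimensions are `phantom_spec()`
  parameters; the defaults are adult-abdomen orders of magnitude.
* **Strata vs. anatomy.** Real abdominal muscles overlap partially and
  wrap around the rectus sheath; the phantom stacks them as full-area
  strata. This preserves the series/parallel load path (soft layers in
  series, stiff midline band in parallel) but not the in-plane
  heterogeneity: away from the strip the phantom is laterally
  homogeneous, so there is no "crossing the RA" vs "lateral to the RA"
  material distinction — position effects on the phantom come from
  distance to the stiff strip and to the fixed edges. Passing tests on
  the phantom therefore validate the *pipeline* (mesh, solver,
  morphometry, sweep logic) and the directional physics of a stiffened
  pressurised wall; they do not certify patient-specific predictions.
* **Curvature by development.** Each through-thickness sheet (a
  cylinder of radius $R_c + \tilde z$) is generated flat and mapped
  isometrically onto its cylinder ($\theta = x/(R_c+\tilde z)$).
  Because a cylinder is developable, in-sheet lengths are preserved
  exactly and the mapping has unit volume Jacobian: the reference
  trephine rim measures exactly like its flat counterpart and the mesh
  volume equals the slab volume. This is what makes the undeformed
  baseline (area $3.14\ \mathrm{cm}^2$, perimeter $6.28$ cm for the
  2 cm incision) exact to the inscribed-polygon truncation.
* **Trephine meshing.** The hole is cut with a structured O-grid
  (butterfly) block: `circle_nodes` nodes (default 64, uniformly spaced
  in angle) lie *exactly* on the requested circle, surrounded by
  `rings` quad rings that grade into the background tensor grid, whose
  lines pass exactly through the O-grid window boundary. A regular
  inscribed 64-gon carries 99.84% of the circle area and 99.96% of its
  perimeter, which is what bounds the baseline truncation error. At
  least 16 circle nodes are enforced. The strip edges ($x = \pm 10$ mm)
  are grid lines wherever they fall outside the O-grid window, so the
  LA region is element-aligned except where the hole window overlaps
  it; inside the window, membership is decided per parent quad, which
  keeps the tag field exactly mirror-symmetric.
* **Stoma positions.** The 17 labels follow the `s0` / `s{i}{j}`
  scheme: `s0` centred on the strip at mid-height; three vertical lines
  at 10%, 23.3% and 36.7% of the width left of the midline with 6, 6
  and 4 stations (height growing with $j$). The exact coordinates are
  package choices, declared in `stoma_positions()` and scaled with the
  wall dimensions.
* **Determinism and jitter.** Given a `phantom_spec` the mesh is
  bit-identical across runs. `seed = 0` (default) means no
  perturbation; a positive seed jitters interior in-plane nodes by up
  to 5% of the resolution for mesh-sensitivity studies, never touching
  the rim, the strip edges or the fixed boundary.

## Numerical conventions

* Units: mm, MPa, N pipeline-wide; 20 kPa enters as 0.02 MPa;
  centimetres appear only in trephine reports.
* Tetrahedra are stored with positive signed volume; the mesh
  constructor repairs negative input tets by swapping two nodes and
  says how many. Node indices are 1-based internally; the Gmsh 1-based
  tags are translated at the I/O boundary.
* Boundary facets are stored outward-oriented with respect to the
  solid; the pressure sign convention (inward-pushing) lives in the
  load assembly, which also verifies facet orientation against the
  tetrahedra and refuses inconsistent groups.
* The deformed trephine rim is measured at the innermost surface (the
  outer rim is also available). Its area is the magnitude of the Newell
  vector area $\tfrac12\lVert\sum r_i \times r_{i+1}\rVert$ — the
  projected area on the best-fitting plane, orientation-robust and
  exact for planar loops. "Axial" and "sagittal" diameters are loop
  extents along configurable global axes (defaults: the horizontal
  body axis and the protrusion direction). Percent enlargements are
  kept at full precision and rounded (2 decimals / integer %) only in
  formatted tables.
* Simplicity of a loop is validated in the reference configuration; at
  measurement time a planar self-intersection test is applied only to
  near-planar loops, because a strongly warped space curve can cross in
  projection while being perfectly regular.
* The Lamé hollow-sphere verification solves the pure-traction problem
  by pinning six well-separated degrees of freedom and projecting the
  best-fit rigid-body motion out of the solution before comparing with
  the closed form.

## Problem sizes

The default phantom resolution (7.5 mm background edge, 64 circle
nodes, 6 O-grid rings, 4 element layers through the thickness) yields
about 11–20 thousand nodes and 52–91 thousand tetrahedra per geometry;
the full 18-geometry, five-pressure sweep solves in a few minutes on a
single CPU. The hollow-sphere verification uses icosphere meshes at
5 / 2.5 / 1.25 mm (up to ~123 000 tetrahedra); the patch test runs on a
unit cube at 0.25 mm. The test suite uses a half-size phantom
(150 × 200 mm, 12 mm resolution, 32 circle nodes) for pipeline
mechanics and the full default phantom for the scientific checks.

## Limitations

* **Reversible, short-time response only.** The model predicts the
  elastic enlargement while pressure is applied; the clinically
  measured quantity is the *permanent* trephine defect (fatigue,
  micro-lesions, tissue adaptation), which a linear elastic model
  cannot represent.
* **Linear kinematics at large deflection.** See the caveat above.
  One concrete consequence on the default phantom: the hoop membrane
  strain of the bulge ($w/R_c \approx 0.6$ at 20 kPa) produces, through
  the Poisson effect, an axial contraction that *shortens* the rim of
  the midline (`s0`) trephine vertically faster than the hoop direction
  widens it — the measured s0 area decreases under load, unlike every
  lateral stoma. A geometrically nonlinear (membrane-stiffening) model
  would moderate the bulge and likely remove this artefact; the linear
  model reports it faithfully, and the sweep results keep it visible
  rather than masking it.
* **No anisotropy, no contact, no dynamics.** Muscle fibre directions,
  inter-layer sliding and viscoelasticity are all out of scope;
  the element model is the documented extension point.
* **Phantom, not anatomy.** Enlargement magnitudes on the phantom are
  not comparable to patient-derived values; only directional,
  between-position statements transfer, with the homogeneity caveat
  above.

## Reproducing everything

`scripts/acceptance.R --seed <s> --out <json>` reruns the verification
oracles and the full default sweep from scratch and writes every
headline number; `tests/testthat/test-acceptance.R` asserts the same
checks at their stated tolerances. Both run against the installed
package with no cached state.
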