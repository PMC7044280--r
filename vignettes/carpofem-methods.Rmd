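---
title: "Methods: finite-element comparison of fused and unfused scaphoid-centrale morphologies"
author: "carpofem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: finite-element comparison of fused and unfused scaphoid-centrale morphologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific question

African apes and humans share a fused scaphoid-centrale in the wrist,
while most other primates keep the os centrale as a separate bone. A
long-standing functional hypothesis holds that the fusion is an
adaptation to knuckle-walking: with no weight-bearing ulnar-carpal
articulation, ground reaction forces in a knuckle-walking hand travel
through the metacarpals, the carpus and the radius, and a bonded
scaphoid-centrale should transmit those loads at lower bone stress than
two separate bones joined by a sliding articulation and a ligament.

`carpofem` turns that hypothesis into a desk-scale, fully reproducible
linear-elastic finite-element experiment. It generates simplified,
seeded carpal geometries of the scaphoid / os centrale / capitate
complex in *fused* and *unfused* variants, loads them with a
species-specific fraction of body weight, solves the multi-body contact
problem, and compares mesh-weighted von Mises stress statistics between
variants with Welch's *t*-tests after a Shapiro-Wilk normality check.

## Mechanical model

**Tissues.** Each bone is a cancellous core meshed with 4-node
constant-strain tetrahedra (E = 500 MPa, nu = 0.30), wrapped by two
membrane layers sharing the nodes of every boundary triangle: cortical
bone (E = 10000 MPa, nu = 0.22, default thickness 1.0 mm) and articular
cartilage (E = 7 MPa, nu = 0.30, thickness 0.55 mm) covering the whole
bone as an additional layer. Sharing nodes couples all membrane degrees
of freedom to the solid directly, the multipoint-coupling behaviour of
bonded shells, without separate constraint machinery. The layers are
membrane-only (no bending stiffness): both are thin and continuously
bonded to the solid substrate, so in-plane stiffness dominates; this is
a deliberate simplification relative to a full shell formulation and
affects both variants identically.

**Contact.** Opposing articular patches are generated node-coincident,
so the non-separation condition reduces to one linear constraint per
node pair: `(u_A - u_B) . n = 0` along the patch normal `n`, with
tangential relative motion left free (sliding). Constraints are applied
by master-slave elimination through a sparse null-space basis, which
keeps the reduced stiffness symmetric positive definite; chained
substitution resolves nodes that belong to two interfaces (the triple
junction of scaphoid, centrale and capitate). Normals are taken from
the undeformed surface and held constant, the small-displacement
assumption of linear statics.

**Ligaments.** The scapho(centrale)capitate ligament is a set of
parallel linear spring strands of total rigidity 40 N/mm. In fused
models the topology is direct (scaphoid patch to capitate patch, each
strand `total/n`); in unfused models each strand runs serially through
the centrale as two segments of `2 total/n` so the strand's series
combination is `total/n` and the parallel aggregate is exactly the
specified total. Eight strands are used by default; the count only
spreads the same total rigidity over the attachment patches.

**Boundary conditions.** Distal facets (capitate base at the third
metacarpal; the centrale facet toward trapezoid/trapezium, which lies
on the fused body in fused models) are fixed. Lateral support from the
lunate, hamate and trapezoid is an elastic foundation: grounded springs
along the patch normal, 20.5 N/mm total per restraint patch,
partitioned over patch nodes by tributary area. Treating that stiffness as
per-region rather than global is a modelling choice, identical across
variants.

**Load.** Forelimbs carry roughly 40% of body weight in hominoid
terrestrial quadrupedalism, i.e. 20% per forelimb: `F = 0.2 m g` with
standard gravity g = 9.80665 m s^-2 (the tabulated default species
loads, e.g. 334.21 N for G. gorilla, round-trip only with the
standard-gravity constant, not the rounded 9.81). The force acts along the proximodistal axis, optionally tilted
5 degrees for the sensitivity set, and is split between the scaphoid's
radial facet and the capitate's lunate facet proportionally to facet
area (loading both facets is part of the protocol; the split itself is
a modelling choice, defaulting to facet-area proportion).

## Synthetic geometry: what it emulates, and what it does not

Real specimens would be CT-derived surfaces; the generator replaces
them with parametric block-built bodies meshed from conforming
structured hex grids split into Kuhn tetrahedra. This guarantees
watertight, positive-volume meshes, exact node coincidence on contact
patches, and full determinism from a single integer seed. The layout
preserves the topology the hypothesis is about: the capitate forms the
distal base; the small centrale sits on its ulnar corner; the scaphoid
is a stepped body resting on both, so part of the proximal load crosses
the scaphoid-centrale joint on its way to the capitate. Fusion merges
scaphoid and centrale into one body and deletes their mutual interface;
everything else is identical between variants, so each species is its
own control, exactly as virtually-fused/virtually-separated specimens
are.

Two generator choices matter mechanically and deserve their rationale:

* **Articular slope (default 0.4, about 22 degrees).** A
  volume-preserving shear of the whole lattice inclines every articular
  plane relative to the load axis. Real carpal articular surfaces are
  strongly inclined to the limb's load axis, which forces shear
  transfer across the midcarpal joints. With perpendicular surfaces a
  frictionless non-separation contact transmits a purely axial load as
  well as a bonded interface would, and the fused/unfused contrast
  collapses to numerical noise; the inclination restores the shear
  demand that makes the fusion mechanically meaningful.
* **Isometric species scaling.** Species differ by load magnitude
  (their published body masses), an isometric size factor
  `(mass / 59.7 kg)^(1/3)` on all lengths including the cortical shell
  thickness, and an individual seeded smooth surface perturbation
  (amplitude 0.12 mm, three random plane waves, applied along the
  outward normal of purely-free surface nodes so no labelled facet is
  distorted). Cartilage thickness stays at 0.55 mm for every species
  (the constant-thickness assumption).

The generator does **not** emulate real carpal shape: no anatomical
curvature of facets, no per-species shape differences beyond size and
perturbation, no trabecular heterogeneity. Passing tests therefore show
that the *pipeline* reproduces the qualitative mechanics of the fusion
(load-path topology, contact, ligament routing) under controlled
conditions; they do not validate absolute stress magnitudes for real
anatomy, which depend on CT geometry that is out of scope.

## Stress statistics

Per-element constant-strain recovery gives a stress tensor for each
tetrahedron and each membrane layer. Summaries are computed per bone
over *bone* tissue only (cancellous + cortical pooled; the
cartilage wrap is a load-transfer medium, not a reported tissue), weighting
each element by its size: volume for solids, area x thickness for
membranes. The mesh-weighted arithmetic mean (MWAM) is
`sum(v w) / sum(w)`; the mesh-weighted median (MWM) is the smallest
value whose cumulative weight reaches half the total. Quartiles use the
same cumulative-weight rule at 1/4 and 3/4, chosen for internal
consistency with the MWM. Box whiskers are min/max, not 1.5 IQR. These statistics exist because the meshes are quasi-ideal
(near- but not exactly uniform element sizes), so unweighted summaries
would be biased by local refinement.

## Inference

Per bone and angle, the five fused and five unfused MWAM values are
pooled (n = 10) for a Shapiro-Wilk check and compared with Welch's
two-sample *t*-test, fused minus unfused, two-sided (the conservative choice). Shapiro-Wilk is implemented
as the Royston (1995) polynomial approximation valid for 3 <= n <=
5000; the test-suite cross-checks it against R's independent
implementation to 1e-12. For fused models the merged scaphoid-centrale
body stands in for the scaphoid, exactly as a fused specimen's scaphoid
includes its centrale. The 5-degree sensitivity set compares pooled
MWAM samples between angles per bone. No multiple-testing correction is
applied across the two bone-level tests.

## Numerical choices

* Unit system mm-N-MPa throughout (10 GPa stored as 10000 MPa);
  stiffnesses are N/mm, consistent with the spring constants.
* Direct sparse Cholesky (CHOLMOD via `Matrix`) with one step of
  iterative refinement if the relative residual exceeds 1e-8; the
  observed residuals are near machine precision. Everything is
  deterministic; the only randomness is the geometry seed.
* Master seed to sub-seed derivation:
  `(seed + 104729 * species_index) mod 2147483647`, so any single
  combination can be regenerated in isolation and all seeds stay within
  32-bit integer range.
* Degenerate inputs fail loudly: non-positive tet volumes after
  perturbation, zero-area membranes, zero-length springs, absent
  patches, non-conforming contacts and singular reduced systems all
  raise errors naming the offending entity.
* Tie pivoting: each tie eliminates the DOF with the largest normal
  component; a near-zero pivot (degenerate normal) is an error rather
  than a silently dropped constraint.

## Verification

The mechanical core is verified against closed forms
(`verification_suite()`, also run by `carpofem verify`): the
constant-strain patch test (uniform traction on a meshed cube) is exact
to machine precision; a 10 mm bar reproduces `sigma L / E`; a grounded
spring gives `F / k`; a 20 x 2 x 2 mm cantilever converges
monotonically to the Euler-Bernoulli tip deflection `P L^3 / 3 E I`
= 0.2 mm, reaching it within 5% at 12 elements through the thickness
(the documented refinement level); von Mises values are invariant under
random tensor rotations. Equilibrium (applied loads + support reactions
+ foundation spring forces = 0) is checked after every solve to 1e-8
relative.

## Problem sizes

Default models use a 1.0 mm target edge length, about 18,000 tetrahedra
and 7,000 membrane triangles per model (12,000 DOFs), chosen as the
resolution where the per-bone MWAM ordering is stable under further
refinement while a full 20-model study (five species, two variants, two
angles) completes in about a minute. The unit-test fixtures use a
1.8 mm edge, where the same qualitative contrasts already hold. These sizes are deliberate
scale reductions of the million-element meshes typical of CT-based
carpal models; the statistics are designed for exactly this kind
of non-uniform, modest-resolution mesh.

## Known limitations

* Absolute stress magnitudes are not comparable to CT-based models;
  only within-study contrasts (fused vs unfused, bone orderings, angle
  sensitivity) are meaningful.
* Membrane-only surface layers omit bending stiffness of the cortical
  shell; with a 1 mm shell on 10-20 mm bones this mainly stiffens both
  variants equally.
* Between-species variance in the synthetic study is dominated by the
  isometric size effect, so the Welch *t* magnitudes are not expected
  to match values obtained from real specimens; the direction and
  per-species consistency of the effect are the reproducible claims.
* Frictionless non-separation contact cannot open a gap; compressive
  study loads keep the interfaces in contact, but tensile load cases
  would need a different contact model.
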