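---
title: "From scalar-field topology to 3D scenes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From scalar-field topology to 3D scenes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhotop)
```

# The objects

Quantum chemical topology (QTAIM) reads chemical structure off a scalar
field — usually the electron density $\rho(\mathbf r)$ — using the
language of dynamical systems. The *critical points* (CPs) of the field,
where $\nabla\rho = 0$, are classified by the eigenvalues
$\lambda_1 \le \lambda_2 \le \lambda_3$ of the Hessian
$\nabla\nabla^{T}\rho$: the rank $\omega$ counts the non-zero
eigenvalues and the signature $\sigma$ sums their signs. The chemically
ubiquitous rank-3 points are the nuclear attractor (NACP, $(3,-3)$),
bond (BCP, $(3,-1)$), ring (RCP, $(3,+1)$) and cage (CCP, $(3,+3)$)
critical points. *Gradient paths* — trajectories of
$d\mathbf r/ds = \pm\nabla\rho/|\nabla\rho|$ — connect CPs and compose
into the familiar composite objects: a pair of paths climbing from a BCP
to two different attractors is an *atomic interaction line* (AIL; a bond
path at an equilibrium geometry); the set of all AILs is the *molecular
graph*; rings and cages collect AILs around RCPs and rings around CCPs;
the bundle of paths descending from one attractor is its *atomic basin*;
the separatrix of paths descending out of one BCP is an *interatomic
surface* (IAS); and a constant-density *envelope* (conventionally at
$\rho = 0.001$ au, enclosing roughly 98% of an atom's electrons) stands
in for the outer boundary of unbounded atoms.

`rhotop` represents this hierarchy as plain S3 objects (`topology`,
`critical_point`, `gradient_path`, `molecular_graph`, …), serializes it
to a DTD-validated XML format (`.top`), maps it onto renderer-agnostic
scene graphs, and — so the whole pipeline is testable without any
quantum-chemistry software — generates complete synthetic topologies
from an analytic promolecular density.

For a complete topology of an isolated, connected molecule the census
obeys the Poincaré–Hopf relation
$n_{\text{NACP}} - n_{\text{BCP}} + n_{\text{RCP}} - n_{\text{CCP}} = 1$,
which the package uses as a standing consistency audit
(`poincare_hopf_residual()`).

# The promolecular density

The synthetic engine needs a field whose topology resembles a molecular
density but whose derivatives are exact and cheap. It uses a
*promolecular* density — a sum of non-interacting spherical atoms — with
one exponential term per occupied Slater shell:

$$\rho(\mathbf r) = \sum_A \sum_i c_i\, e^{-\zeta_i |\mathbf r -
\mathbf R_A|},$$

where the exponents come from Slater's screening rules
($\zeta = 2 Z_{\text{eff}} / n^*$, the factor two because the density is
the squared orbital) and the coefficients normalize each shell to its
electron count, $c = n_e \zeta^3 / 8\pi$, so that the conventional
0.001-au envelope isovalue remains meaningful. For hydrogen this
reduces to the exact ground-state density $\rho = e^{-2r}/\pi$. The
per-element table (H–Kr) ships as a versioned CSV in `extdata/`.

Gradient and Hessian are closed-form derivatives of the sum; the test
suite verifies them against central finite differences at random points.

## Nuclear cusps

A pure exponential sum has a *cusp* at each nucleus: $\rho$ is finite
there but $\nabla\rho$ does not vanish — its magnitude approaches
$\bar\zeta\rho$ from every direction, and the radial second derivative
is positive. In the topological sense each nucleus is still the
attractor of its basin, but no smooth-CP search can converge onto it
(Newton steps near a cusp actually move *away* from the nucleus).
`find_critical_points()` therefore registers every nucleus directly as a
$(3,-3)$ attractor; since the Hessian diverges at the cusp these CPs
carry no eigen-system (the model's eigen-fields are optional for exactly
this reason). All smooth CPs — saddles, ring and cage points — are found
by Newton–Raphson with the analytic Hessian. Real DFT densities are
cusped at nuclei too; production QTAIM codes special-case nuclear
positions in just this way.

# Locating critical points

Newton's method is run from a combinatorial seed set: every nucleus
(offset $10^{-3}$ bohr off-cusp), every pair midpoint within 8 bohr,
every triple and quadruple centroid of diameter under 8 bohr, and the
centroid of the full nuclear set (an eight-membered ring like S$_8$ is
wider than the pairwise cutoff, yet its ring point sits at the global
centroid). Steps are capped at 0.3 bohr (a light trust region), seeds
that wander past the system extent + 20 bohr are discarded, and
convergence requires $|\nabla\rho| < 10^{-10}$ au. Two safeguards matter
in practice:

* **Far-field noise.** In the exponential tail the gradient norm falls
  below any fixed threshold without a stationary point existing, so
  candidates with $\rho \le 10^{-6}$ au are rejected.
* **Duplicates.** Converged points closer than $10^{-3}$ bohr are
  merged, keeping the smaller residual gradient.

Accepted points are classified with a degeneracy tolerance of $10^{-8}$
au on the Hessian eigenvalues — promolecular Hessians are smooth, and
$10^{-8}$ cleanly separates numerical noise from true zeros. Degenerate
($\omega < 3$) CPs are retained and labelled, but never used in AIL or
ring assembly.

# Tracing gradient paths

Paths integrate the normalized gradient field with a fourth-order
Runge–Kutta scheme under step-doubling error control (positional
tolerance $10^{-6}$, steps adapted within $[10^{-6}, 0.25]$ bohr). Two
cusp-specific details: the step is kept below half the distance to the
nearest critical point (otherwise the RK stages can straddle a nuclear
cusp symmetrically and cancel), and a zero-progress guard halves the
step whenever a stage cancellation is detected anyway. A trace ends
when it comes within the snap tolerance ($10^{-4}$ bohr — below visual
resolution, above integrator error) of a known CP, or when $\rho$ drops
below the truncation floor ($10^{-4}$ au by default, deliberately below
the 0.001-au envelope so basin fans extend past envelopes), in which
case the terminus is the reserved "infinity" index $-1$
(`terminus="infinity"` in the file format). Stored polylines are
decimated by Douglas–Peucker at $10^{-3}$ bohr; $\rho$ is recorded at
every stored point, and monotonicity of $\rho$ along each path is a
standing test invariant.

# Assembling the composite objects

**Molecular graph.** For each BCP, two ascending traces along
$\pm\lambda_3$ reach the two flanking attractors; pairs sharing a BCP
with distinct far attractors become AILs. A BCP with anything other
than two attractor-terminated paths is skipped with a warning.

**Rings.** The assembly must decide which AILs a ring-point's ring
paths connect to. The pure textbook recipe — ascending paths from the
RCP that terminate *at* BCPs — is numerically ill-posed: those paths are
separatrices, and generic traces slide off and finish at an attractor
instead (in test runs even seeds aimed exactly at a BCP miss it by half
a bohr in low-symmetry rings). The implementation therefore collects
evidence in a priority order:

1. *Sector terminals* (most selective): a fan of 64 ascending seeds in
   the RCP's $\lambda_2$–$\lambda_3$ eigenplane, plus one targeted seed
   toward each BCP within 8 bohr (needed for puckered rings, whose
   atoms subtend narrow sectors), partitions into sectors ending at the
   ring's atoms. AILs with *both* attractors among those terminals are
   candidates.
2. *BCP evidence* (used only if step 1 does not close a cycle): BCPs
   that a fan path approaches within the capture radius (0.3 bohr), and
   BCPs whose own descending $\pm\lambda_2$ trace — the ring path traced
   from the bond side, which runs inside the interatomic surface — ends
   at or passes the RCP.

Either way, the candidate set is pruned to a single closed cycle over
its attractors (iterative removal of pendant AILs, then a 2-regularity
and connectivity check); ring points whose evidence does not close into
a cycle of at least three AILs are dropped with a warning. That pruning
is what discards, e.g., C–H bonds reached incidentally in benzene, and
entire spurious ring points whose neighbourhoods contain no cycle at
all.

**Cages.** A ring belongs to a cage when the descending trace from its
RCP along the ring axis ($\pm\lambda_1$, its unique negative
eigendirection) reaches that CCP. Tracing *from* the CCP is not an
option: a cage point is a local minimum, so no descending path leaves
it, and in highly symmetric cages (a $T_d$ cage point has an isotropic
Hessian) its eigenvectors are arbitrary. Cage points linked to fewer
than two rings are dropped. Ring and cage tracing uses a lowered
density floor, $\min(10^{-4}, 0.1\,\min_\text{RCP/CCP}\rho)$, because
wide rings can have ring points below the generic truncation density
(the S$_8$ ring point sits at $1.2\times 10^{-5}$ au).

**Basins, surfaces, envelopes.** Basin fans descend from each attractor
along 162 icosahedral directions (subdivision level 2; configurable).
Interatomic surfaces seed descending traces on rings of radii
$0.01\cdot 2^k$ bohr ($k = 0..7$) by 36 angles in the BCP's
$\lambda_1$–$\lambda_2$ eigenplane — the plane tangent to the IAS, which
attracts the descending flow, so these traces are numerically stable —
and triangle-strip meshes join consecutive angular traces at matched
arc-length samples. Envelopes bisect along icosphere rays (level 3,
642 vertices by default) for the outermost radius with
$\rho = \text{isovalue}$ to a relative tolerance of $10^{-8}$; the mesh
inherits icosphere connectivity and is therefore watertight
(V − E + F = 2) by construction.

# Scene construction conventions

The canonical mapping renders CPs as spheres (attractors at
0.25 × the element's Bondi van der Waals radius, colored by element with
PyMOL-compatible colors; all other CPs at a fixed 0.25 bohr — BCP red,
RCP blue, CCP green, degenerate points magenta, a color the convention
leaves open), AIL paths as tubes smoothed by Catmull–Rom-tangent cubic
Bézier segments (tension 0.5, endpoints exact, resampled at 8 points
per segment), basin and ring paths as thin 0.05-bohr tubes, and
surfaces/envelopes as meshes with a transparent per-element surface
material (transparency 0.6 — surfaces are conventionally made
transparent so the molecular graph stays visible; the exact alpha is a
package choice). AIL tubes are element-colored by default with a
uniform-black mode available. Materials carry a Lambert diffuse shader
at intensity 1.0 and a white Cook–Torrance specular shader at intensity
0.5. The vdW-based bond test (`differentiate_interactions()`) calls an
AIL bonded when the internuclear distance is at most 0.6 × the sum of
vdW radii; non-bonded AILs get a 0.25 × tube radius, the thin-line
convention for hydrogen bonds and other weak contacts.

Scene setup is computed from the CP cloud: the frame center is the mean
CP position and the extent $r$ the radius of the bounding sphere about
it (floored at 1 bohr for single-point systems). The camera sits at
$(x_0, y_0, z_0 - 4r)$ — four extents behind the center — and is
oriented to *look at* the center: a camera facing down $-z$ from that
position would face away from the system, and the rim lamp is defined
as "directly behind the system relative to the camera", which fixes the
orientation unambiguously. Key and fill spotlights start at the camera
position, rotate $\pm 45^\circ$ about the vertical axis *through the
system center* (making the whole construction translation-equivariant),
rise by $r$ along $+y$, and aim at the center with energies 1.0 and
0.5; the non-directional rim lamp (0.8) sits at $(x_0, y_0, z_0 + 4r)$.
Only the key > fill ordering is fixed by convention; the specific
energies are configurable defaults. Render defaults: 1000 × 1000 px,
8 anti-aliasing samples, 6 ray-tracing samples, 16-bit PNG without
compression, sky-blue background. Stereo pairs rotate the camera
$\pm 2^\circ$ (configurable within $(0, 10]$) about the vertical axis
through the center and are ordered for cross-eyed viewing (left frame =
right-eye view). Spotlight cone angles and falloff are deliberately
unspecified renderer-side knobs; no claim is made of pixel-identical
output in any particular renderer.

# File format and exports

The `.top` XML format mirrors the object model one-to-one; its DTD
ships at `system.file("extdata", "Topology.dtd", package = "rhotop")`.
Coordinates are bohr and the root carries a mandatory `unit="bohr"`
attribute — readers reject anything else rather than silently convert.
Indices in the file are 0-based; numbers carry 12 significant digits,
which bounds round-trip error at $10^{-9}$ bohr (a test invariant).
`validate_top()` reports well-formedness, structural conformity and the
model-level checks a DTD cannot express (reference resolution,
rank/signature legality) as a severity/path/text table.

The scene JSON is a canonical serialization — sorted keys, 12
significant digits, byte-identical for identical scenes — in scene
units (bohr). Mesh exports (OBJ+MTL, binary little-endian PLY with
per-vertex color, glTF 2.0 with embedded buffers) convert to ångström,
since 3D tools assume human-scale units, with a right-handed +y-up
convention; spheres tessellate as 32 × 16 UV spheres, curves as
12-sided capped tubes. glTF approximates the fixed-function materials
with PBR factors (roughness $= 1 - 0.5\,\times$ specular intensity).
The builder script (`emit_builder_script()`) is emitted text in a
Blender-style Python dialect and is never executed by the package.

# What the synthetic data does and does not show

The promolecular generator reproduces the *structural* topology of the
reference systems at desk scale: censuses satisfying Poincaré–Hopf,
benzene's 12 attractors and single ring, the (HF)$_5$ graph of five
covalent and five hydrogen-bond AILs, hexamethylenetetramine's four
rings enclosing one cage. It does not reproduce quantitative features
of correlated densities: promolecular $\rho$ at BCPs differs from DFT
values, there is no charge transfer or polarization, ellipticities are
meaningless, and weakly bound regions can differ structurally — in this
model hexamethylenetetramine carries four extra axial RCP–CCP pairs
outside its rings (census $\{22, 24, 8, 5\}$, still Poincaré–Hopf
consistent) which the ring/cage assembly prunes, and the acetic-acid
dimer gains a methyl-contact ring. Passing tests therefore demonstrate
the correctness of the machinery — search, tracing, assembly,
serialization, mapping — not agreement with any particular quantum
chemical method; for real densities the package expects `.top` files
produced by an external QCT engine through the adapter route
(construct a `topology()`, call `write_topology()`).

# Problem sizes and tolerances

The test suite runs the full generator on the bundled fixtures at the
default search settings; fan sizes are scaled to the role of each test
(basin fans at icosphere level 1, IAS fans 12 × 4 for the H$_2$
round-trip fixture; full defaults elsewhere). The complete suite
finishes in a few minutes on one CPU, the hexamethylenetetramine
ring-and-cage run (~1 min) dominating. Key tolerances, all
configurable through `topology_options()`:

| quantity | default | rationale |
|---|---|---|
| Hessian degeneracy `zero_tol` | $10^{-8}$ au | separates noise from true zeros on smooth promolecular Hessians |
| Newton acceptance | $|\nabla\rho| < 10^{-10}$ au | quadratic convergence makes this cheap |
| CP acceptance density floor | $10^{-6}$ au | rejects far-field pseudo-solutions |
| duplicate merge | $10^{-3}$ bohr | well below any CP–CP spacing |
| endpoint snap | $10^{-4}$ bohr | below visual resolution, above integrator error |
| path truncation `rho_floor` | $10^{-4}$ au | below the 0.001-au envelope |
| ring capture radius | 0.3 bohr | below half a bond length |
| envelope bisection | $10^{-8}$ relative | vertices on-isovalue to $10^{-6}$ with margin |
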