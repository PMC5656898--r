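# rhotop

Tools for the topology of molecular scalar fields — the critical points,
gradient paths, molecular graphs, atomic basins, interatomic surfaces
and density envelopes of quantum chemical topology (QTAIM) — and for
turning them into publication-ready 3D scenes.

QTAIM reads chemical structure directly off the electron density
ρ(**r**): maxima (nuclear attractors) are atoms, (3,−1) saddles between
them are bond critical points, the pair of gradient paths climbing from
such a saddle to two attractors is an atomic interaction line (a bond
path), and the set of all such lines is the molecular graph — a
first-principles bonding picture. Ring (3,+1) and cage (3,+3) points
complete the census, which for an isolated connected molecule satisfies
the Poincaré–Hopf relation *n* − *b* + *r* − *c* = 1.

The package is aimed at computational chemists who have (or want to
emulate) the output of a QCT analysis program and need a validated,
renderer-agnostic route from topological data to images and meshes. It
provides:

* **A typed topology model** (`topology()`, `critical_point()`,
  `gradient_path()`, …) with classification
  (`classify_critical_point()`), census audits
  (`poincare_hopf_residual()`), and molecular-graph / ring / cage
  assembly.
* **The `.top` XML file format** — read, write, and DTD-backed
  validation (`write_topology()`, `read_topology()`, `validate_top()`;
  the DTD ships in `inst/extdata/Topology.dtd`). Output from any QCT
  engine can enter the pipeline by building a `topology()` and calling
  `write_topology()`.
* **A synthetic-topology engine**: an analytic promolecular density
  ρ(**r**) = Σ c·exp(−ζ|**r**−**R**|) with closed-form derivatives
  (`promolecular_density()`, `evaluate_density()`), Newton
  critical-point search (`find_critical_points()`), adaptive
  Runge–Kutta path tracing (`trace_gradient_path()`), isodensity
  envelope meshing (`build_envelope()`), interatomic surfaces
  (`build_interatomic_surface()`) and a one-call pipeline
  (`generate_topology()`), with bundled reference geometries
  (`build_fixture_geometry()`) and XYZ input (`read_xyz()`).
* **Scene construction**: the canonical mapping of topological objects
  to spheres, smoothed tubes and meshes (`map_topology()`), automatic
  camera / three-point lighting / render settings (`place_camera()`,
  `place_lights()`, `default_render_settings()`), stereoscopic pairs
  (`make_stereo_pair()`), bonded/non-bonded AIL differentiation
  (`differentiate_interactions()`).
* **Exports**: deterministic scene JSON, OBJ+MTL, binary PLY, glTF 2.0,
  and a Blender-style builder script (`export_scene_json()`,
  `export_mesh_scene()`, `emit_builder_script()`), plus a command-line
  interface (`exec/rhotop`, see `?cli_main`).

## Worked example

Generate the complete promolecular topology of an idealized benzene
(D6h, C–C 1.3915 Å, C–H 1.0800 Å), inspect it, and map it to a scene:

```r
library(rhotop)

top <- generate_topology(build_fixture_geometry("benzene"),
                         topology_options(components = c("graph", "rings")))
print(top)
#> QCT topology: 12 nuclei, 25 critical points
#>   census: nacp=12 bcp=12 rcp=1 ccp=0 degenerate=0
#>   Poincare-Hopf residual: 1
#>   AILs: 12  rings: 1  cages: 0  basins: 0  envelopes: 0  interatomic surfaces: 0
```

The search finds the 12 nuclear attractors (one atomic basin per atom),
12 bond critical points (6 C–C + 6 C–H), and the single ring point at
the center; the alternating census sum is 1, as it must be for a
connected molecule. The molecular graph holds 12 atomic interaction
lines, and the ring is the closed cycle of the 6 C–C lines (the C–H
lines are pruned by cycle closure). All 12 AILs pass the van der Waals
bond test:

```r
part <- differentiate_interactions(top$gvf$molecular_graph, top$nuclei,
                                   topology = top)
length(part$bonded); length(part$nonbonded)
#> [1] 12
#> [1] 0

scene <- map_topology(top)
print(scene)
#> scene graph: 49 objects ( 25 spheres, 24 curves, 0 meshes ), 8 materials
```

25 spheres (one per critical point) and 24 tubes (two bond-path tubes
per AIL); the camera is placed automatically four bounding-radii behind
the system (here at z = −18.68 bohr), with key/fill/rim lights at ±45°.
Export for any renderer:

```r
export_scene_json(scene, "benzene.scene.json")
export_mesh_scene(scene, "gltf", "benzene.gltf")
write_topology(top, "benzene.top")
```

The same pipeline runs from the shell:

```sh
rhotop synth benzene -o benzene.top        # logs the census + residual
rhotop scene benzene.top --differentiate   # scene JSON (+ mesh export flags)
```

## Scope

The package never computes wavefunctions or DFT densities: the
promolecular engine is an analytic stand-in whose topology mimics
molecular densities at desk scale (see the methods vignette,
`vignettes/qct-topology-scenes.Rmd`, for what that does and does not
demonstrate). Parsers for vendor-specific QCT outputs are out of scope;
the `.top` format plus the in-memory constructors are the adapter
surface. Rendering itself is delegated to external tools through the
standard exports.
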