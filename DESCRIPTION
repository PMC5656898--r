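Package: rhotop
Title: Quantum Chemical Topology Models, Synthetic Promolecular Topologies,
    and Renderer-Agnostic 3D Scenes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with the topology of molecular scalar fields
    in the quantum-chemical-topology (QTAIM) sense. Provides a typed
    in-memory model of critical points, gradient paths, molecular graphs,
    rings, cages, basins, interatomic surfaces and density envelopes; a
    validated XML file format (.top) with a shipped document type
    definition; an analytic promolecular density engine that generates
    complete synthetic topologies (Newton critical-point search,
    Runge-Kutta gradient-path tracing, isodensity envelope meshing) for
    bundled reference geometries or arbitrary XYZ input; a canonical
    mapping from topological objects to renderer-agnostic 3D scenes
    (spheres, smoothed tube curves, triangulated meshes, materials,
    automatic camera and three-point lighting); and exporters to OBJ/MTL,
    binary PLY, glTF 2.0, a deterministic scene JSON, and a Blender-style
    builder script.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
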