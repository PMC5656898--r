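test_that("scene JSON is deterministic and complete", {
  top <- fixture_graph_topology("hcn")
  scene <- map_topology(top)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  export_scene_json(scene, f1)
  export_scene_json(scene, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  parsed <- jsonlite::fromJSON(f1, simplifyVector = FALSE)
  expect_length(parsed$objects, length(scene$objects))
  expect_identical(parsed$units, "bohr")
  expect_identical(parsed$render$width, 1000L)
  # empty scene still serializes with populated defaults
  f3 <- withr::local_tempfile(fileext = ".json")
  export_scene_json(map_topology(topology()), f3)
  empty <- jsonlite::fromJSON(f3, simplifyVector = FALSE)
  expect_length(empty$objects, 0)
  expect_false(is.null(empty$camera))
  expect_false(is.null(empty$lights))
})

test_that("the benzene scene JSON holds 49 objects under the default style", {
  f <- withr::local_tempfile(fileext = ".json")
  export_scene_json(map_topology(fixture_graph_topology("benzene")), f)
  parsed <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_length(parsed$objects, 49)
})

test_that("OBJ export matches the closed-form tessellation counts", {
  # one sphere at default tessellation: 32*(16-1)+2 vertices
  top1 <- topology(nuclei = list(nucleus("H", c(0, 0, 0), 0)),
                   critical_points = list(critical_point(c(0, 0, 0), 3, -3)))
  scene1 <- map_topology(top1)
  f <- withr::local_tempfile(fileext = ".obj")
  export_mesh_scene(scene1, "obj", f)
  lines <- readLines(f)
  expect_identical(sum(grepl("^v ", lines)), 482L)
  expect_identical(sum(grepl("^f ", lines)), 32L * 2L + 14L * 32L * 2L)
  expect_true(file.exists(sub("\\.obj$", ".mtl", f)))

  # full scene: re-parsed vertex count equals the sum of per-object formulas
  scene <- map_topology(fixture_graph_topology("hcn"))
  f2 <- withr::local_tempfile(fileext = ".obj")
  export_mesh_scene(scene, "obj", f2)
  lines2 <- readLines(f2)
  expected <- sum(vapply(scene$objects, function(o) {
    switch(o$kind,
           sphere = 482L,
           curve = nrow(o$points) * 12L + 2L,
           mesh = nrow(o$mesh$vertices))
  }, integer(1)))
  expect_identical(sum(grepl("^v ", lines2)), expected)
  # face indices stay within the vertex count
  fidx <- as.integer(unlist(strsplit(sub("^f ", "", grep("^f ", lines2,
                                                         value = TRUE)), " ")))
  expect_lte(max(fidx), expected)
  expect_gte(min(fidx), 1L)
  # MTL carries every material once with its dissolve
  mtl <- readLines(sub("\\.obj$", ".mtl", f2))
  for (m in scene$materials) {
    expect_identical(sum(mtl == paste("newmtl", m$name)), 1L)
  }
  # empty scene: valid file with zero geometry
  f3 <- withr::local_tempfile(fileext = ".obj")
  export_mesh_scene(map_topology(topology()), "obj", f3)
  expect_identical(sum(grepl("^v ", readLines(f3))), 0L)
})

test_that("binary PLY export carries the advertised geometry", {
  scene <- map_topology(fixture_graph_topology("h2"))
  f <- withr::local_tempfile(fileext = ".ply")
  export_mesh_scene(scene, "ply", f)
  raw <- readBin(f, "raw", file.size(f))
  header_end <- grepRaw("end_header\n", raw)[1] + nchar("end_header\n") - 1
  header <- strsplit(rawToChar(raw[1:header_end]), "\n")[[1]]
  nv <- as.integer(sub("element vertex ", "", grep("element vertex", header,
                                                   value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("element face", header,
                                                 value = TRUE)))
  expect_identical(header[2], "format binary_little_endian 1.0")
  # 12 bytes position + 3 bytes color per vertex; 13 bytes per face
  expect_equal(length(raw) - header_end, nv * 15 + nf * 13)
  expect_identical(nv, sum(vapply(scene$objects, function(o) {
    switch(o$kind, sphere = 482L, curve = nrow(o$points) * 12L + 2L,
           mesh = nrow(o$mesh$vertices))
  }, integer(1))))
})

test_that("glTF export embeds coherent buffers and PBR materials", {
  scene <- map_topology(fixture_graph_topology("h2"))
  f <- withr::local_tempfile(fileext = ".gltf")
  export_mesh_scene(scene, "gltf", f)
  doc <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_identical(doc$asset$version, "2.0")
  expect_length(doc$meshes, length(scene$objects))
  expect_length(doc$nodes, length(scene$objects))
  expect_length(doc$accessors, 2 * length(scene$objects))
  # buffer length equals the summed bufferView spans
  total <- sum(vapply(doc$bufferViews, function(v) v$byteLength, numeric(1)))
  expect_equal(doc$buffers[[1]]$byteLength, total)
  uri <- doc$buffers[[1]]$uri
  expect_true(startsWith(uri, "data:application/octet-stream;base64,"))
  b64 <- sub("^data:application/octet-stream;base64,", "", uri)
  expect_identical(length(jsonlite::base64_dec(b64)), as.integer(total))
  # roughness encodes the Cook-Torrance intensity: 1 - 0.5 * 0.5
  rough <- vapply(doc$materials, function(m) {
    m$pbrMetallicRoughness$roughnessFactor
  }, numeric(1))
  expect_true(all(rough == 0.75))
  expect_error(export_mesh_scene(scene, "stl", withr::local_tempfile()),
               "arg")
})

test_that("the builder script enumerates materials once and objects exactly", {
  scene <- map_topology(fixture_graph_topology("hcn"))
  f1 <- withr::local_tempfile(fileext = ".py")
  f2 <- withr::local_tempfile(fileext = ".py")
  emit_builder_script(scene, f1)
  emit_builder_script(scene, f2)
  expect_identical(readLines(f1), readLines(f2))
  lines <- readLines(f1)
  for (m in scene$materials) {
    expect_identical(sum(grepl(paste0("make_material\\('", m$name, "'"),
                               lines)), 1L)
  }
  n_create <- sum(grepl("^add_(sphere|curve|mesh)\\(", lines))
  expect_identical(n_create, length(scene$objects))
  expect_identical(sum(grepl("^add_camera\\(", lines)), 1L)
  expect_identical(sum(grepl("^add_(spot|lamp)\\(", lines)), 3L)
  expect_identical(sum(grepl("^set_render\\(", lines)), 1L)
})

test_that("tube and sphere tessellations are well-formed meshes", {
  tube <- tube_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 1, 0)), 0.1, sides = 8)
  expect_identical(nrow(tube$vertices), 3L * 8L + 2L)
  expect_true(all(tube$faces >= 1 & tube$faces <= nrow(tube$vertices)))
  sph <- uv_sphere_mesh(c(1, 2, 3), 2, nu = 8, nv = 6)
  expect_identical(nrow(sph$vertices), 8L * 5L + 2L)
  d <- sqrt(rowSums(sweep(sph$vertices, 2, c(1, 2, 3), `-`)^2))
  expect_equal(unname(d), rep(2, nrow(sph$vertices)))
  # closed surface: every edge shared by exactly two faces
  ekey <- apply(rbind(sph$faces[, 1:2], sph$faces[, 2:3], sph$faces[, c(3, 1)]),
                1, function(e) paste(sort(e), collapse = "-"))
  expect_true(all(table(ekey) == 2))
})
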