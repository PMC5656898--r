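test_that("default materials follow the element + fixed-set rule", {
  top <- fixture_graph_topology("benzene")
  mats <- default_materials(top)
  names <- vapply(mats, function(m) m$name, character(1))
  expect_setequal(names, c("C-nucleus", "H-nucleus", "C-surface", "H-surface",
                           "bcp", "rcp", "ccp", "ail"))
  expect_length(mats, 8)
  by_name <- function(n) mats[[match(n, names)]]
  expect_equal(by_name("bcp")$diffuse_rgb, c(1, 0, 0))
  expect_equal(by_name("rcp")$diffuse_rgb, c(0, 0, 1))
  expect_equal(by_name("ccp")$diffuse_rgb, c(0, 1, 0))
  expect_equal(by_name("ail")$diffuse_rgb, c(0, 0, 0))
  expect_equal(by_name("C-surface")$transparency, 0.6)
  expect_equal(by_name("C-nucleus")$transparency, 0)

  # a topology with one element and only attractors still carries the fixed set
  top1 <- topology(nuclei = list(nucleus("H", c(0, 0, 0), 0)),
                   critical_points = list(critical_point(c(0, 0, 0), 3, -3)))
  names1 <- vapply(default_materials(top1), function(m) m$name, character(1))
  expect_setequal(names1, c("H-nucleus", "H-surface", "bcp", "rcp", "ccp", "ail"))

  # degenerate CPs pull in the extra magenta material
  top2 <- topology(nuclei = list(nucleus("H", c(0, 0, 0), 0)),
                   critical_points = list(
                     critical_point(c(0, 0, 0), 3, -3),
                     critical_point(c(3, 0, 0), 2, 0, label = "degenerate")))
  names2 <- vapply(default_materials(top2), function(m) m$name, character(1))
  expect_true("degenerate-cp" %in% names2)
  expect_warning(col <- rhotop:::.element_color("Uuo"), "gray")
  expect_equal(col, c(0.5, 0.5, 0.5))
})

test_that("the benzene graph scene maps to 25 spheres and 24 AIL tubes", {
  top <- fixture_graph_topology("benzene")
  scene <- map_topology(top)
  kinds <- vapply(scene$objects, function(o) o$kind, character(1))
  expect_identical(sum(kinds == "sphere"), 25L)
  expect_identical(sum(kinds == "curve"), 24L)
  expect_length(scene$objects, 49)
  # NACP spheres scale with the vdW radius; other CPs share one radius
  radii <- vapply(scene$objects[kinds == "sphere"], function(o) o$radius,
                  numeric(1))
  mats <- vapply(scene$objects[kinds == "sphere"], function(o) o$material,
                 character(1))
  expect_equal(unique(radii[mats == "bcp"]), 0.25)
  expect_equal(unique(radii[mats == "C-nucleus"]),
               0.25 * angstrom_to_bohr(1.70))
  # AIL tubes are element-colored by default ...
  ail_mats <- vapply(scene$objects[kinds == "curve"], function(o) o$material,
                     character(1))
  expect_setequal(unique(ail_mats), c("C-nucleus", "H-nucleus"))
  # ... and uniformly black on request
  scene_u <- map_topology(top, scene_style(uniform_ail = TRUE))
  ail_u <- vapply(Filter(function(o) o$kind == "curve", scene_u$objects),
                  function(o) o$material, character(1))
  expect_identical(unname(table(ail_u)[["ail"]]), 24L)
})

test_that("an empty topology maps to an empty scene with default setup", {
  scene <- map_topology(topology())
  expect_length(scene$objects, 0)
  expect_s3_class(scene$camera, "camera")
  expect_length(scene$lights, 3)
  expect_identical(scene$render$width, 1000L)
})

test_that("path smoothing interpolates endpoints and preserves collinearity", {
  # collinear control points stay collinear (affine invariance)
  pts <- cbind(seq(0, 1, length.out = 7), 2 * seq(0, 1, length.out = 7), 0)
  sm <- smooth_path(pts)
  expect_equal(sm[1, ], pts[1, ])
  expect_equal(sm[nrow(sm), ], pts[nrow(pts), ])
  d <- sm[, 2] - 2 * sm[, 1]
  expect_lt(max(abs(d)), 1e-9)
  # two points give a straight densely sampled segment
  sm2 <- smooth_path(rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_identical(nrow(sm2), 9L)
  expect_equal(sm2[1, ], c(0, 0, 0))
  expect_equal(sm2[9, ], c(1, 1, 1))
  # duplicate removal; degenerate input errors
  expect_error(smooth_path(rbind(c(0, 0, 0), c(0, 0, 0))), "at least 2")
  # endpoints of real AIL paths are preserved exactly
  top <- fixture_graph_topology("benzene")
  p <- top$gvf$molecular_graph$ails[[1]]$paths[[1]]$points
  smp <- smooth_path(p)
  expect_identical(smp[1, ], unname(p[1, ]))
  expect_identical(smp[nrow(smp), ], unname(p[nrow(p), ]))
})

test_that("interactions partition into bonded and non-bonded by the vdW rule", {
  top <- fixture_graph_topology("h2")
  part <- differentiate_interactions(top$gvf$molecular_graph, top$nuclei,
                                     topology = top)
  expect_identical(part$bonded, 1L)
  expect_length(part$nonbonded, 0)
  # a fabricated AIL between nuclei 6 A apart is non-bonded
  far <- angstrom_to_bohr(6)
  cps <- list(critical_point(c(0, 0, 0), 3, -3),
              critical_point(c(0, 0, far), 3, -3),
              critical_point(c(0, 0, far / 2), 3, -1,
                             eigenvalues = c(-1, -0.5, 2),
                             eigenvectors = diag(3)))
  seg <- function(a, b, i, j) gradient_path(rbind(a, (a + b) / 2, b), i, j)
  ail <- atomic_interaction_line(
    list(seg(c(0, 0, far / 2), c(0, 0, 0), 3, 1),
         seg(c(0, 0, far / 2), c(0, 0, far), 3, 2)), 3)
  nuclei <- list(nucleus("C", c(0, 0, 0), 0), nucleus("C", c(0, 0, far), 1))
  part2 <- differentiate_interactions(molecular_graph(list(ail)), nuclei)
  expect_identical(part2$nonbonded, 1L)
  # differentiated style thins the non-bonded tubes
  hf5 <- fixture_graph_topology("hf_pentamer")
  scene <- map_topology(hf5, scene_style(differentiate = TRUE))
  curve_r <- vapply(Filter(function(o) o$kind == "curve", scene$objects),
                    function(o) o$radius, numeric(1))
  expect_setequal(round(unique(curve_r), 6), round(c(0.1, 0.025), 6))
  expect_identical(sum(curve_r == 0.025), 10L)  # 2 tubes per H-bond AIL
})

test_that("AIL resizing is multiplicative and leaves other objects alone", {
  top <- fixture_graph_topology("benzene")
  scene <- map_topology(top)
  expect_identical(resize_ails(scene, 1), scene)
  s2 <- resize_ails(resize_ails(scene, 2), 2)
  s4 <- resize_ails(scene, 4)
  r2 <- vapply(s2$objects, function(o) if (o$kind == "curve") o$radius else NA_real_,
               numeric(1))
  r4 <- vapply(s4$objects, function(o) if (o$kind == "curve") o$radius else NA_real_,
               numeric(1))
  expect_equal(r2, r4)
  half <- resize_ails(scene, 0.5)
  for (k in seq_along(scene$objects)) {
    o1 <- scene$objects[[k]]; o2 <- half$objects[[k]]
    if (o1$kind == "curve" && startsWith(o1$tag, "ail:")) {
      expect_equal(o2$radius, o1$radius / 2)
    } else if (o1$kind == "sphere") {
      expect_identical(o2$radius, o1$radius)
    }
  }
  expect_error(resize_ails(scene, 0), "factor")
})

test_that("mapping is deterministic", {
  top <- fixture_graph_topology("hcn")
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  export_scene_json(map_topology(top), f1)
  export_scene_json(map_topology(top), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
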