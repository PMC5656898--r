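test_that("the single-atom density follows its closed form", {
  den <- promolecular_density(list(nucleus("H", c(0, 0, 0), 0)))
  ev <- evaluate_density(den, c(1, 0, 0))
  # hydrogen carries one shell with coefficient 1/pi and exponent 2
  expect_equal(ev$rho, exp(-2) / pi, tolerance = 1e-12)
  expect_equal(ev$grad, c(-2 * exp(-2) / pi, 0, 0), tolerance = 1e-12)
  # radial Hessian eigenvalue is +zeta^2*rho along the axis
  expect_equal(ev$hess[1, 1], 4 * exp(-2) / pi, tolerance = 1e-12)
  expect_error(evaluate_density(den, c(0, 0, 1e-12)), "cusp")
})

test_that("atomic densities integrate to their electron counts", {
  for (sym in c("H", "C", "S")) {
    den <- promolecular_density(list(nucleus(sym, c(0, 0, 0), 0)))
    z <- match(sym, element_data()$symbol)
    q <- stats::integrate(function(r) {
      vapply(r, function(ri) {
        4 * pi * ri^2 * rhotop:::.promol_rho_only(den, c(ri, 0, 0))
      }, numeric(1))
    }, 0, Inf, rel.tol = 1e-9)
    expect_equal(q$value, z, tolerance = 1e-6)
  }
})

test_that("fixture geometries match their construction rules", {
  benz <- build_fixture_geometry("benzene")
  expect_length(benz$nuclei, 12)
  centroid <- colMeans(t(vapply(benz$nuclei, function(n) n$position, numeric(3))))
  expect_equal(centroid, c(0, 0, 0), tolerance = 1e-12)
  h2 <- build_fixture_geometry("h2")
  expect_equal(sqrt(sum((h2$nuclei[[1]]$position - h2$nuclei[[2]]$position)^2)),
               0.74 / 0.529177210903, tolerance = 1e-9)
  expect_length(build_fixture_geometry("hexamethylenetetramine")$nuclei, 22)
  expect_length(build_fixture_geometry("s8")$nuclei, 8)
  expect_length(build_fixture_geometry("acetic_dimer")$nuclei, 16)
  expect_error(build_fixture_geometry("caffeine"), "available")
  # S8 crown respects its internal coordinates
  s8 <- build_fixture_geometry("s8")
  p <- t(vapply(s8$nuclei, function(n) n$position, numeric(3)))
  expect_equal(sqrt(sum((p[1, ] - p[2, ])^2)), 2.05 / 0.529177210903,
               tolerance = 1e-9)
  v1 <- p[1, ] - p[2, ]; v2 <- p[3, ] - p[2, ]
  ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  expect_equal(ang, 108, tolerance = 1e-6)
})

test_that("XYZ input is parsed and converted to bohr", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "water-like test geometry",
               "O 0.000 0.000 0.000",
               "H 0.757 0.586 0.000",
               "H -0.757 0.586 0.000"), f)
  geo <- read_xyz(f)
  expect_length(geo$nuclei, 3)
  expect_identical(geo$nuclei[[1]]$element, "O")
  expect_equal(geo$nuclei[[2]]$position[1], angstrom_to_bohr(0.757))
  expect_error(read_xyz("does-not-exist.xyz"), "not found")
  f2 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("5", "truncated", "O 0 0 0"), f2)
  expect_error(read_xyz(f2), "fewer atoms")
})

test_that("the benzene critical-point census matches an independent grid scan", {
  den <- fixture_density("benzene")
  cen <- cp_census(fixture_cps("benzene"))
  expect_identical(unname(cen[c("nacp", "bcp", "rcp", "ccp")]),
                   c(12L, 12L, 1L, 0L))
  # all benzene CPs lie in the molecular plane: scan it
  oracle <- grid_census_oracle(den, list(x = seq(-6, 6, 0.1),
                                         y = seq(-6, 6, 0.1), z = 0),
                               spacing = 0.1)
  expect_identical(unname(oracle), c(12L, 12L, 1L, 0L))
})

test_that("the HCN census matches an independent 3D grid scan", {
  den <- fixture_density("hcn")
  cen <- cp_census(fixture_cps("hcn"))
  expect_identical(unname(cen[c("nacp", "bcp", "rcp", "ccp")]),
                   c(3L, 2L, 0L, 0L))
  oracle <- grid_census_oracle(den, list(x = seq(-2.5, 2.5, 0.1),
                                         y = seq(-2.5, 2.5, 0.1),
                                         z = seq(-2.5, 6.7, 0.1)),
                               spacing = 0.1)
  expect_identical(unname(oracle), c(3L, 2L, 0L, 0L))
})

test_that("critical-point positions are equivariant under rigid motions", {
  geo <- build_fixture_geometry("hcn")
  th <- 0.71
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  shift <- c(0.3, -1.2, 2.5)
  moved <- lapply(geo$nuclei, function(n) {
    nucleus(n$element, as.numeric(R %*% n$position) + shift, n$index)
  })
  cps1 <- fixture_cps("hcn")
  cps2 <- find_critical_points(promolecular_density(moved))
  expect_length(cps2, length(cps1))
  pos1 <- t(vapply(cps1, function(cp) cp$position, numeric(3)))
  pos2 <- t(vapply(cps2, function(cp) cp$position, numeric(3)))
  mapped <- t(R %*% t(pos1)) + rep(shift, each = nrow(pos1))
  for (i in seq_len(nrow(mapped))) {
    d <- sqrt(rowSums(sweep(pos2, 2, mapped[i, ], `-`)^2))
    expect_lt(min(d), 1e-6)
    expect_identical(cps2[[which.min(d)]]$label, cps1[[i]]$label)
  }
})

test_that("gradient paths of a lone atom are radial", {
  den <- promolecular_density(list(nucleus("C", c(0.5, -0.5, 1), 0)))
  cps <- find_critical_points(den)
  u <- c(2, 1, -1) / sqrt(6)
  gp <- trace_gradient_path(den, cps[[1]]$position, direction = u,
                            orientation = "descending", cps = cps)
  expect_identical(gp$cp_start, 1L)
  expect_identical(gp$cp_end, -1L)
  rel <- sweep(gp$points[-1, , drop = FALSE], 2, cps[[1]]$position, `-`)
  rel <- rel / sqrt(rowSums(rel^2))
  expect_lt(max(1 - abs(rel %*% u)), 1e-6)
})

test_that("bond paths ascend from the BCP to the flanking attractors", {
  den <- fixture_density("h2")
  cps <- fixture_cps("h2")
  b <- which(cp_labels(cps) == "BCP")
  v3 <- cps[[b]]$eigenvectors[, 3]
  ends <- vapply(c(1, -1), function(s) {
    trace_gradient_path(den, cps[[b]]$position, direction = s * v3,
                        orientation = "ascending", cps = cps)$cp_end
  }, integer(1))
  expect_setequal(ends, which(cp_labels(cps) == "NACP"))
})

test_that("path tracing respects its error contracts", {
  den <- fixture_density("h2")
  cps <- fixture_cps("h2")
  expect_error(trace_gradient_path(den, cps[[1]]$position,
                                   direction = c(0, 0, 1),
                                   orientation = "descending", cps = cps,
                                   max_steps = 3),
               "step-count cap")
})

test_that("polyline decimation stays within its deviation tolerance", {
  t <- seq(0, 2 * pi, length.out = 400)
  pts <- cbind(cos(t), sin(t), t / 5)
  keep <- rhotop:::.decimate_polyline(pts, 1e-3)
  expect_lt(length(keep), nrow(pts) / 2)
  # oracle: deviation of every dropped point from its decimated chord
  dec <- pts[keep, ]
  for (i in seq_len(nrow(pts))) {
    seg <- findInterval(i, keep, rightmost.closed = TRUE)
    a <- dec[seg, ]; b <- dec[min(seg + 1, nrow(dec)), ]
    ab <- b - a
    tpar <- if (sum(ab^2) > 0) sum((pts[i, ] - a) * ab) / sum(ab^2) else 0
    d <- sqrt(sum((pts[i, ] - a - max(0, min(1, tpar)) * ab)^2))
    expect_lt(d, 1.5e-3)
  }
})

test_that("envelopes sit on their isovalue with icosphere connectivity", {
  den <- promolecular_density(list(nucleus("H", c(0, 0, 0), 0)))
  cps <- find_critical_points(den)
  env <- build_envelope(den, 1, cps, isovalue = 0.001, subdivision_level = 1)
  radii <- sqrt(rowSums(env$mesh$vertices^2))
  expect_equal(unname(radii), rep(log(1 / (0.001 * pi)) / 2, 42),
               tolerance = 1e-7)
  # watertight: V - E + F == 2 and every edge borders exactly two faces
  m <- env$mesh
  expect_identical(nrow(m$vertices) - nrow(m$edges) + nrow(m$faces), 2L)
  ekey <- apply(rbind(m$faces[, 1:2], m$faces[, 2:3], m$faces[, c(3, 1)]),
                1, function(e) paste(sort(e), collapse = "-"))
  expect_true(all(table(ekey) == 2))
  expect_error(build_envelope(den, 1, cps, isovalue = 1e-50),
               "isovalue too small")
  expect_error(build_envelope(den, 1, cps, isovalue = 10), "below the density")
})

test_that("a benzene carbon envelope is a watertight sphere-like mesh", {
  den <- fixture_density("benzene")
  cps <- fixture_cps("benzene")
  env <- build_envelope(den, 1, cps, isovalue = 0.001, subdivision_level = 2)
  m <- env$mesh
  expect_identical(nrow(m$vertices) - nrow(m$edges) + nrow(m$faces), 2L)
  rho <- vapply(seq_len(nrow(m$vertices)), function(i) {
    rhotop:::.promol_rho_only(den, m$vertices[i, ])
  }, numeric(1))
  expect_lt(max(abs(rho - 0.001) / 0.001), 1e-6)
})

test_that("the H2 interatomic surface is the perpendicular bisector plane", {
  top <- fixture_h2_full()
  den <- fixture_density("h2")
  cps <- top$critical_points
  s <- top$gvf$interatomic_surfaces[[1]]
  n1 <- top$nuclei[[1]]$position; n2 <- top$nuclei[[2]]$position
  for (p in s$paths) {
    d <- abs(sqrt(rowSums(sweep(p$points, 2, n1, `-`)^2)) -
             sqrt(rowSums(sweep(p$points, 2, n2, `-`)^2)))
    expect_lt(max(d), 1e-4)
  }
  # points offset either side of the surface flow to the two different attractors
  b <- which(cp_labels(cps) == "BCP")
  axis <- (n2 - n1) / sqrt(sum((n2 - n1)^2))
  probe <- s$mesh$vertices[10, ]
  ends <- vapply(c(1, -1), function(s0) {
    trace_gradient_path(den, probe + s0 * 0.01 * axis,
                        orientation = "ascending", cps = cps)$cp_end
  }, integer(1))
  expect_setequal(ends, which(cp_labels(cps) == "NACP"))
  expect_error(build_interatomic_surface(den, 1, cps), "bond critical")
})

test_that("the bifluoride anion has one interatomic surface per BCP", {
  top <- cached_fixture("hfh_surf", generate_topology(
    build_fixture_geometry("hfh_anion"),
    topology_options(components = c("graph", "surfaces"),
                     ias_angular = 8, ias_rings = 4)))
  expect_length(top$gvf$interatomic_surfaces, 2)
  bcps <- vapply(top$gvf$interatomic_surfaces, function(s) s$bcp, integer(1))
  expect_setequal(bcps, which(cp_labels(top$critical_points) == "BCP"))
  # atomic surfaces reference only AIL-connected interatomic surfaces
  graph <- top$gvf$molecular_graph
  for (as in top$gvf$atomic_surfaces) {
    for (i in as$interatomic_surfaces) {
      a <- graph$ails[[which(vapply(graph$ails, function(x) x$bcp, integer(1)) ==
                             top$gvf$interatomic_surfaces[[i]]$bcp)]]
      expect_true(as$nacp %in% a$nacps)
    }
  }
})

test_that("basin fans originate at their attractor and terminate per contract", {
  top <- fixture_h2_full()
  expect_length(top$gvf$basins, 2)
  for (b in top$gvf$basins) {
    expect_length(b$paths, 42)  # icosphere level 1 directions
    for (p in b$paths) {
      expect_identical(p$cp_start, b$nacp)
      last_rho <- p$scalars$rho[nrow(p$points)]
      expect_true(p$cp_end != -1L || last_rho < 1e-4 * 1.05)
    }
  }
})
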