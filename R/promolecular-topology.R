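#' Default seed set for the critical-point search
#'
#' Seeds are placed at every nucleus (offset slightly off the density
#' cusp), at the midpoint of every nuclear pair closer than `pair_cut`,
#' at the centroid of every nuclear triple and quadruple whose diameter
#' is below `pair_cut`, and at the centroid of the full nuclear set
#' (which captures ring and cage points of wide rings whose members all
#' exceed the pairwise cutoff). Saddles, ring and cage points of a
#' promolecular density lie close to such combinatorial centers.
#'
#' @param density a [promolecular_density()].
#' @param pair_cut distance cutoff in bohr (default 8).
#' @return an n x 3 matrix of seed positions.
#' @export
default_cp_seeds <- function(density, pair_cut = 8) {
  pos <- density$nucleus_positions
  n <- nrow(pos)
  seeds <- pos + matrix(1e-3 / sqrt(3), n, 3)  # off-cusp nuclear seeds
  if (n >= 2) {
    seeds <- rbind(seeds, colMeans(pos))
    dm <- as.matrix(stats::dist(pos))
    pairs <- which(upper.tri(dm) & dm < pair_cut, arr.ind = TRUE)
    if (nrow(pairs) > 0) {
      seeds <- rbind(seeds, (pos[pairs[, 1], , drop = FALSE] +
                             pos[pairs[, 2], , drop = FALSE]) / 2)
    }
    for (k in 3:4) {
      if (n < k) break
      combos <- utils::combn(n, k)
      keep <- apply(combos, 2, function(ix) max(dm[ix, ix]) < pair_cut)
      combos <- combos[, keep, drop = FALSE]
      if (ncol(combos) > 0) {
        cent <- t(apply(combos, 2, function(ix) colMeans(pos[ix, , drop = FALSE])))
        seeds <- rbind(seeds, cent)
      }
    }
  }
  unname(seeds)
}

#' Locate the critical points of a promolecular density
#'
#' Nuclei are registered directly as `(3,-3)` nuclear attractor critical
#' points: the exponential promolecular density has a cusp at each
#' nucleus, where the gradient does not vanish in the smooth sense, so the
#' attractors are identified analytically and carry no eigen-system. All
#' smooth critical points (bond, ring, cage and degenerate points) are
#' found by Newton–Raphson on \eqn{\nabla\rho} using the analytic Hessian,
#' started from `seeds`. A converged point is accepted when
#' \eqn{|\nabla\rho| <} `newton_tol`; duplicates within `merge_tol` are
#' merged keeping the point with the smaller gradient norm, and each
#' survivor is classified with [classify_critical_point()] and annotated
#' with its eigen-system and `"rho"` scalar.
#'
#' @param density a [promolecular_density()].
#' @param seeds optional n x 3 matrix of start points; defaults to
#'   [default_cp_seeds()].
#' @param newton_tol gradient-norm acceptance threshold in au (default 1e-10).
#' @param max_iter Newton iteration cap per seed (default 100).
#' @param merge_tol duplicate-merge distance in bohr (default 1e-3).
#' @param zero_tol Hessian degeneracy tolerance in au (default 1e-8).
#' @param min_rho acceptance floor on the density at a candidate point
#'   (default 1e-6 au): in the exponential far field the gradient norm
#'   falls below any fixed `newton_tol` even though no stationary point
#'   exists, so candidates with negligible density are rejected as noise.
#' @return list of [critical_point()] objects: NACPs first (nucleus
#'   order), then BCPs, RCPs, CCPs and degenerate points, each class in
#'   deterministic coordinate order.
#' @export
find_critical_points <- function(density, seeds = NULL,
                                 newton_tol = 1e-10, max_iter = 100,
                                 merge_tol = .default_merge_tol,
                                 zero_tol = .default_zero_tol,
                                 min_rho = 1e-6) {
  if (is.null(seeds)) seeds <- default_cp_seeds(density)
  seeds <- as.matrix(seeds)
  ext <- .density_extent(density)
  escape2 <- (ext$radius + 20)^2
  npos <- density$nucleus_positions

  found_pos <- list(); found_gn <- numeric(0)
  for (s in seq_len(nrow(seeds))) {
    x <- seeds[s, ]
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      # never evaluate derivatives inside the cusp region
      if (min(rowSums(sweep(npos, 2, x, `-`)^2)) < (10 * merge_tol)^2) break
      ev <- .promol_eval(density, x)
      gn <- sqrt(sum(ev$grad^2))
      if (gn < newton_tol) { ok <- ev$rho > min_rho; break }
      step <- tryCatch(-solve(ev$hess, ev$grad), error = function(e) NULL)
      if (is.null(step)) break
      sn <- sqrt(sum(step^2))
      if (sn > 0.3) step <- step * (0.3 / sn)   # trust-region cap
      x <- x + step
      if (sum((x - ext$center)^2) > escape2) break  # diverged; drop seed
    }
    if (!ok) next
    found_pos[[length(found_pos) + 1]] <- x
    found_gn <- c(found_gn, sqrt(sum(.promol_eval(density, x)$grad^2)))
  }

  # merge duplicates, preferring smaller |grad|
  kept <- list(); kept_gn <- numeric(0)
  if (length(found_pos) > 0) {
    ord <- order(found_gn)
    for (i in ord) {
      x <- found_pos[[i]]
      dup <- FALSE
      for (j in seq_along(kept)) {
        if (sum((x - kept[[j]])^2) < merge_tol^2) { dup <- TRUE; break }
      }
      if (!dup) { kept[[length(kept) + 1]] <- x; kept_gn <- c(kept_gn, found_gn[i]) }
    }
  }

  cps <- vector("list", 0)
  for (k in seq_len(nrow(npos))) {
    nuc <- density$nuclei[[k]]
    cps[[length(cps) + 1]] <- critical_point(
      nuc$position, rank = 3, signature = -3, label = "NACP",
      scalars = c(rho = .promol_rho_only(density, nuc$position)))
  }
  others <- list()
  for (k in seq_along(kept)) {
    x <- kept[[k]]
    ev <- .promol_eval(density, x)
    es <- eigen(ev$hess, symmetric = TRUE)
    ord <- order(es$values)
    vals <- es$values[ord]
    vecs <- es$vectors[, ord, drop = FALSE]
    cls <- classify_critical_point(vals, zero_tol)
    others[[length(others) + 1]] <- critical_point(
      x, rank = cls$rank, signature = cls$signature, label = cls$label,
      eigenvalues = vals, eigenvectors = vecs,
      scalars = c(rho = ev$rho), zero_tol = zero_tol)
  }
  # deterministic order: BCP, RCP, CCP, degenerate; lexicographic within
  if (length(others) > 0) {
    lab_rank <- c(BCP = 1, RCP = 2, CCP = 3, degenerate = 4)
    key <- vapply(others, function(cp) {
      sprintf("%d_%+.6f_%+.6f_%+.6f", lab_rank[[cp$label]],
              cp$position[1], cp$position[2], cp$position[3])
    }, character(1))
    others <- others[order(key)]
  }
  c(cps, others)
}

#' Trace a gradient path of a promolecular density
#'
#' Integrates \eqn{dr/ds = \pm\nabla\rho/|\nabla\rho|} with an adaptive
#' fourth-order Runge–Kutta scheme (step-doubling error control). The
#' trace terminates when it comes within `snap_tol` of a known critical
#' point (the endpoint is snapped onto it) or when \eqn{\rho} falls below
#' `rho_floor`, in which case `cp_end` is the infinity sentinel `-1`. The
#' dense trajectory is decimated (Douglas–Peucker, max deviation 1e-3
#' bohr) before being stored. The minimum approach distance to every
#' critical point is recorded in the `"approach_dist"` attribute.
#'
#' @param density a [promolecular_density()].
#' @param start start position (bohr); typically a critical point.
#' @param direction optional unit vector: when given, the integration is
#'   seeded one `seed_step` along it (required when `start` is a critical
#'   point, where the gradient vanishes or is cusped).
#' @param orientation `"ascending"` (toward increasing rho) or
#'   `"descending"`.
#' @param step initial step length in bohr (default 0.05; adapted in
#'   `[1e-6, 0.25]`).
#' @param rho_floor truncation density in au (default 1e-4).
#' @param cps list of known [critical_point()]s for termination tests.
#' @param snap_tol termination/snap distance in bohr (default 1e-4).
#' @param seed_step offset applied along `direction` (default 1e-3 bohr).
#' @param max_steps accepted-step cap (default 1e5); exceeding it is an
#'   error.
#' @return a [gradient_path()] whose `scalars$rho` column holds the
#'   density along the stored points.
#' @export
trace_gradient_path <- function(density, start, direction = NULL,
                                orientation = c("ascending", "descending"),
                                step = 0.05, rho_floor = 1e-4, cps = list(),
                                snap_tol = .default_snap_tol,
                                seed_step = 1e-3, max_steps = 1e5) {
  orientation <- match.arg(orientation)
  sgn <- if (orientation == "ascending") 1 else -1
  start <- .check_pos3(start)
  cp_pos <- if (length(cps) > 0) {
    t(vapply(cps, function(cp) cp$position, numeric(3)))
  } else matrix(numeric(0), 0, 3)

  # identify cp_start from the unseeded start point
  cp_start <- -1L
  if (nrow(cp_pos) > 0) {
    d0 <- sqrt(rowSums(sweep(cp_pos, 2, start, `-`)^2))
    if (min(d0) <= snap_tol) cp_start <- which.min(d0)
  }

  x <- start
  if (!is.null(direction)) {
    direction <- .check_pos3(direction)
    direction <- direction / sqrt(sum(direction^2))
    x <- start + seed_step * direction
  }

  field <- function(p) {
    g <- .promol_eval(density, p)$grad
    gn <- sqrt(sum(g^2))
    if (gn < 1e-300) return(c(0, 0, 0))
    sgn * g / gn
  }
  rk4 <- function(p, h) {
    k1 <- field(p)
    k2 <- field(p + h / 2 * k1)
    k3 <- field(p + h / 2 * k2)
    k4 <- field(p + h * k3)
    p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }

  pts <- matrix(start, nrow = 1)
  rhos <- .promol_rho_only(density, start)
  if (!is.null(direction)) {
    pts <- rbind(pts, x)
    rhos <- c(rhos, .promol_rho_only(density, x))
  }
  approach <- if (nrow(cp_pos) > 0) {
    sqrt(rowSums(sweep(cp_pos, 2, x, `-`)^2))
  } else numeric(0)
  if (cp_start != -1L && length(approach) > 0) approach[cp_start] <- 0

  h <- step
  tol <- 1e-6
  cp_end <- NA_integer_
  n_acc <- 0
  while (is.na(cp_end)) {
    if (n_acc >= max_steps) stop("gradient path exceeded the step-count cap")
    # near a critical point the normalized field varies on the scale of
    # the remaining distance (and reverses across a nuclear cusp), so
    # keep the step below half that distance
    if (nrow(cp_pos) > 0) {
      dx <- sqrt(rowSums(sweep(cp_pos, 2, x, `-`)^2))
      dmin <- min(dx[seq_len(nrow(cp_pos)) != cp_start], Inf)
      if (dmin < 0.2) h <- min(h, max(dmin / 2, 1e-6))
    }
    # adaptive RK4 by step doubling
    repeat {
      x1 <- rk4(x, h)
      xh <- rk4(x, h / 2)
      x2 <- rk4(xh, h / 2)
      err <- sqrt(sum((x1 - x2)^2))
      moved <- sqrt(sum((x2 - x)^2))
      if (moved < h / 100 && h > 1e-6) {
        # stages straddle a cusp and cancel; shrink until progress resumes
        h <- max(1e-6, h / 2)
        next
      }
      if (err <= tol || h <= 1e-6) break
      h <- max(1e-6, h * max(0.2, 0.9 * (tol / err)^0.2))
    }
    xn <- x2
    if (err < tol / 32) h <- min(0.25, h * 2)
    n_acc <- n_acc + 1
    x <- xn
    rho_here <- .promol_rho_only(density, x)
    pts <- rbind(pts, x)
    rhos <- c(rhos, rho_here)
    if (nrow(cp_pos) > 0) {
      d <- sqrt(rowSums(sweep(cp_pos, 2, x, `-`)^2))
      approach <- pmin(approach, d)
      hit <- which(d <= snap_tol)
      hit <- hit[hit != cp_start]
      if (length(hit) > 0) {
        cp_end <- hit[which.min(d[hit])]
        pts[nrow(pts), ] <- cps[[cp_end]]$position
        rhos[length(rhos)] <- cps[[cp_end]]$scalars[["rho"]]
        break
      }
    }
    if (rho_here < rho_floor) { cp_end <- -1L; break }
  }

  keep <- .decimate_polyline(pts, 1e-3)
  gp <- gradient_path(pts[keep, , drop = FALSE], cp_start, cp_end,
                      scalars = data.frame(rho = rhos[keep]))
  attr(gp, "approach_dist") <- approach
  gp
}

# Douglas-Peucker indices to keep, tolerance in bohr
.decimate_polyline <- function(pts, tol) {
  n <- nrow(pts)
  if (n <= 2) return(seq_len(n))
  keep <- logical(n)
  keep[c(1, n)] <- TRUE
  stack <- list(c(1, n))
  while (length(stack) > 0) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j - i < 2) next
    a <- pts[i, ]; b <- pts[j, ]
    ab <- b - a
    len2 <- sum(ab^2)
    mid <- (i + 1):(j - 1)
    rel <- sweep(pts[mid, , drop = FALSE], 2, a, `-`)
    tpar <- if (len2 > 0) pmin(1, pmax(0, (rel %*% ab) / len2)) else rep(0, length(mid))
    proj <- outer(as.numeric(tpar), ab)
    dev2 <- rowSums((rel - proj)^2)
    w <- which.max(dev2)
    if (dev2[w] > tol^2) {
      k <- mid[w]
      keep[k] <- TRUE
      stack[[length(stack) + 1]] <- c(i, k)
      stack[[length(stack) + 1]] <- c(k, j)
    }
  }
  which(keep)
}

#' Build a constant-density envelope around a nuclear attractor
#'
#' For every direction of an icosahedral subdivision mesh the outermost
#' radius with \eqn{\rho =} `isovalue` is found by scanning inward from 50
#' bohr and bisecting the bracketing interval to a relative density
#' tolerance of 1e-8. The triangulation inherits the icosphere
#' connectivity, so the mesh is watertight by construction.
#'
#' @param density a [promolecular_density()].
#' @param nacp 1-based NACP index into `cps`.
#' @param cps list of [critical_point()]s.
#' @param isovalue density value in au (default 0.001, below the density
#'   at any nucleus).
#' @param subdivision_level icosphere level (default 3, 642 vertices).
#' @return an [envelope()].
#' @export
build_envelope <- function(density, nacp, cps, isovalue = 0.001,
                           subdivision_level = 3) {
  center <- cps[[nacp]]$position
  if (.promol_rho_only(density, center) <= isovalue) {
    stop("isovalue must lie below the density at the nuclear attractor")
  }
  ico <- icosphere(subdivision_level)
  dirs <- ico$vertices
  radii <- numeric(nrow(dirs))
  scan_r <- seq(50, 0.05, by = -0.25)
  for (i in seq_len(nrow(dirs))) {
    u <- dirs[i, ]
    pts <- sweep(outer(scan_r, u), 2, center, `+`)
    rho <- .promol_rho_grad_batch(density, pts)$rho
    k <- which(rho >= isovalue)[1]
    if (is.na(k) || k == 1) {
      stop("density never drops below the isovalue within 50 bohr along a ray; ",
           "isovalue too small")
    }
    lo <- scan_r[k]; hi <- scan_r[k - 1]   # rho(lo) >= iso >= rho(hi)
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      rm <- .promol_rho_only(density, center + mid * u)
      if (abs(rm - isovalue) / isovalue < 1e-8) { lo <- mid; break }
      if (rm >= isovalue) lo <- mid else hi <- mid
    }
    radii[i] <- lo
  }
  verts <- sweep(dirs * radii, 2, center, `+`)
  envelope(nacp, isovalue,
           mesh = triangulation(verts, edges = ico$edges, faces = ico$faces))
}

#' Build the interatomic surface fanning out of a bond critical point
#'
#' Descending gradient paths are seeded on rings of `n_rings` radii
#' (\eqn{\epsilon 2^k}, \eqn{\epsilon = 0.01} bohr) by `n_angular`
#' directions in the BCP's \eqn{\lambda_1}–\eqn{\lambda_2} eigenplane —
#' the plane tangent to the interatomic surface, which attracts the
#' descending flow. The surface mesh joins consecutive angular traces at
#' matched arc-length samples into triangle strips around the BCP.
#'
#' @param density a [promolecular_density()].
#' @param bcp 1-based BCP index into `cps`; must be rank 3, signature -1.
#' @param cps list of [critical_point()]s.
#' @param n_angular number of angular seed directions (default 36).
#' @param n_rings number of seed radii / radial mesh samples (default 8).
#' @param rho_floor truncation density for the traces (default 1e-4 au).
#' @param snap_tol termination tolerance in bohr.
#' @return an [interatomic_surface()] with a triangulated mesh.
#' @export
build_interatomic_surface <- function(density, bcp, cps, n_angular = 36,
                                      n_rings = 8, rho_floor = 1e-4,
                                      snap_tol = .default_snap_tol) {
  cp <- cps[[bcp]]
  if (cp$rank != 3L || cp$signature != -1L) {
    stop("interatomic surfaces are built at (3,-1) bond critical points")
  }
  v1 <- cp$eigenvectors[, 1]; v2 <- cp$eigenvectors[, 2]
  eps <- 0.01
  angles <- 2 * pi * (seq_len(n_angular) - 1) / n_angular
  paths <- list()
  first_ring <- vector("list", n_angular)
  for (j in seq_len(n_angular)) {
    u <- cos(angles[j]) * v1 + sin(angles[j]) * v2
    for (k in seq_len(n_rings) - 1L) {
      gp <- trace_gradient_path(density, cp$position, direction = u,
                                orientation = "descending",
                                rho_floor = rho_floor, cps = cps,
                                snap_tol = snap_tol,
                                seed_step = eps * 2^k)
      paths[[length(paths) + 1]] <- gp
      if (k == 0L) first_ring[[j]] <- gp
    }
  }
  # mesh: BCP center + n_rings arc-length samples along each innermost trace
  nv <- 1 + n_angular * n_rings
  verts <- matrix(0, nv, 3)
  verts[1, ] <- cp$position
  for (j in seq_len(n_angular)) {
    samp <- .arclength_samples(first_ring[[j]]$points, n_rings)
    verts[1 + (j - 1) * n_rings + seq_len(n_rings), ] <- samp
  }
  faces <- list()
  idx <- function(j, k) 1 + ((j - 1) %% n_angular) * n_rings + k
  for (j in seq_len(n_angular)) {
    faces[[length(faces) + 1]] <- c(1, idx(j, 1), idx(j + 1, 1))
    for (k in seq_len(n_rings - 1)) {
      faces[[length(faces) + 1]] <- c(idx(j, k), idx(j, k + 1), idx(j + 1, k))
      faces[[length(faces) + 1]] <- c(idx(j + 1, k), idx(j, k + 1), idx(j + 1, k + 1))
    }
  }
  mesh <- triangulation(verts, faces = do.call(rbind, faces))
  interatomic_surface(bcp, paths, mesh = mesh)
}

# sample a polyline at m equally spaced arc-length fractions (excluding 0)
.arclength_samples <- function(pts, m) {
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                       pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  targets <- total * seq_len(m) / m
  out <- matrix(0, m, 3)
  for (i in seq_len(m)) {
    t0 <- targets[i]
    j <- findInterval(t0, s, rightmost.closed = TRUE)
    j <- min(max(j, 1), length(seg))
    f <- if (seg[j] > 0) (t0 - s[j]) / seg[j] else 0
    out[i, ] <- pts[j, ] + f * (pts[j + 1, ] - pts[j, ])
  }
  out
}

#' Options controlling topology generation
#'
#' @param components character vector choosing which composite objects to
#'   build: any of `"graph"`, `"rings"`, `"cages"`, `"basins"`,
#'   `"surfaces"`, `"envelopes"`. Rings require the graph; cages require
#'   rings.
#' @param basin_level icosphere subdivision level for the basin direction
#'   fan (default 2, i.e. 162 descending paths per attractor).
#' @param ring_fan number of ascending ring-path seeds in the RCP
#'   eigenplane (default 64).
#' @param envelope_level icosphere level for envelopes (default 3,
#'   642 vertices).
#' @param envelope_isovalue envelope density in au (default 0.001).
#' @param rho_floor gradient-path truncation density in au (default 1e-4,
#'   below the envelope convention so basins extend past envelopes).
#' @param ias_angular,ias_rings interatomic-surface fan parameters
#'   (defaults 36 and 8).
#' @param newton_tol,merge_tol,snap_tol,zero_tol numerical tolerances, see
#'   [find_critical_points()] and [trace_gradient_path()].
#' @param capture_tol ring-path near-approach radius in bohr (default 0.3).
#' @return a named list of options for [generate_topology()].
#' @export
topology_options <- function(components = c("graph", "rings", "cages",
                                            "basins", "surfaces", "envelopes"),
                             basin_level = 2, ring_fan = 64,
                             envelope_level = 3, envelope_isovalue = 0.001,
                             rho_floor = 1e-4, ias_angular = 36, ias_rings = 8,
                             newton_tol = 1e-10,
                             merge_tol = .default_merge_tol,
                             snap_tol = .default_snap_tol,
                             zero_tol = .default_zero_tol,
                             capture_tol = 0.3) {
  components <- match.arg(components, several.ok = TRUE)
  list(components = components, basin_level = basin_level,
       ring_fan = ring_fan, envelope_level = envelope_level,
       envelope_isovalue = envelope_isovalue, rho_floor = rho_floor,
       ias_angular = ias_angular, ias_rings = ias_rings,
       newton_tol = newton_tol, merge_tol = merge_tol,
       snap_tol = snap_tol, zero_tol = zero_tol, capture_tol = capture_tol)
}

#' Generate the complete topology of a promolecular density
#'
#' Full synthetic-topology pipeline for a nuclear geometry: locate all
#' critical points; for each BCP trace the pair of ascending bond paths
#' along \eqn{\pm\lambda_3} and assemble the molecular graph; for each RCP
#' trace an ascending fan in the \eqn{\lambda_2}–\eqn{\lambda_3}
#' eigenplane (plus targeted seeds toward each in-range BCP) and assemble
#' rings by cycle closure; link rings to cages by descending traces from
#' each RCP along its ring axis (\eqn{\pm\lambda_1}); and optionally build
#' per-attractor basin fans, interatomic/atomic surfaces and isodensity
#' envelopes.
#'
#' @param geometry a `fixture_geometry` (see [build_fixture_geometry()],
#'   [read_xyz()]) or a list of [nucleus()] objects.
#' @param options a [topology_options()] list.
#' @return a [topology()].
#' @export
#' @examples
#' top <- generate_topology(build_fixture_geometry("h2"),
#'                          topology_options(components = "graph"))
#' cp_census(top$critical_points)
generate_topology <- function(geometry, options = topology_options()) {
  nuclei <- if (inherits(geometry, "fixture_geometry")) geometry$nuclei else geometry
  den <- promolecular_density(nuclei)
  opt <- options
  cps <- find_critical_points(den, newton_tol = opt$newton_tol,
                              merge_tol = opt$merge_tol,
                              zero_tol = opt$zero_tol)
  labels <- vapply(cps, function(cp) cp$label, character(1))
  bcp_idx <- which(labels == "BCP")
  rcp_idx <- which(labels == "RCP")
  ccp_idx <- which(labels == "CCP")
  nacp_idx <- which(labels == "NACP")

  graph <- molecular_graph()
  if ("graph" %in% opt$components && length(bcp_idx) > 0) {
    bond_paths <- list()
    for (b in bcp_idx) {
      v3 <- cps[[b]]$eigenvectors[, 3]
      for (s in c(1, -1)) {
        bond_paths[[length(bond_paths) + 1]] <- trace_gradient_path(
          den, cps[[b]]$position, direction = s * v3,
          orientation = "ascending", rho_floor = opt$rho_floor,
          cps = cps, snap_tol = opt$snap_tol)
      }
    }
    graph <- assemble_molecular_graph(bond_paths, cps)
  }

  ring_surfaces <- list()
  rings <- list(); cages <- list()
  if ("rings" %in% opt$components && length(rcp_idx) > 0 &&
      length(graph$ails) > 0) {
    # ring and cage points of weakly bound rings can sit below the
    # generic truncation density; keep tracing down to well below the
    # least dense ring/cage point
    cp_rho <- vapply(cps[c(rcp_idx, ccp_idx)],
                     function(cp) cp$scalars[["rho"]], numeric(1))
    ring_floor <- min(opt$rho_floor, 0.1 * min(cp_rho))
    for (r in rcp_idx) {
      cp <- cps[[r]]
      v2 <- cp$eigenvectors[, 2]; v3 <- cp$eigenvectors[, 3]
      n1 <- cp$eigenvectors[, 1]
      dirs <- lapply(2 * pi * (seq_len(opt$ring_fan) - 1) / opt$ring_fan,
                     function(a) cos(a) * v2 + sin(a) * v3)
      # targeted seeds: the in-plane direction of each nearby BCP starts
      # next to the separatrix of that bond's sector boundary, so its
      # trace terminates at one of the bond's own attractors even for
      # strongly puckered rings whose atoms subtend narrow sectors
      for (b in bcp_idx) {
        dv <- cps[[b]]$position - cp$position
        if (sqrt(sum(dv^2)) > 8) next
        dv <- dv - sum(dv * n1) * n1
        nn <- sqrt(sum(dv^2))
        if (nn > 1e-8) dirs[[length(dirs) + 1]] <- dv / nn
      }
      rpaths <- lapply(dirs, function(u) {
        trace_gradient_path(den, cp$position, direction = u,
                            orientation = "ascending",
                            rho_floor = ring_floor, cps = cps,
                            snap_tol = opt$snap_tol)
      })
      ring_surfaces[[length(ring_surfaces) + 1]] <- ring_surface(r, rpaths)
    }
    # BCP-side ring-path evidence: the descending trace leaving a BCP
    # along +-lambda2 (within the interatomic surface) runs into the ring
    # interior and reaches the RCP the bond belongs to
    bcp_links <- NULL
    link_rows <- list()
    for (a in graph$ails) {
      v2b <- cps[[a$bcp]]$eigenvectors[, 2]
      for (s in c(1, -1)) {
        gp <- trace_gradient_path(den, cps[[a$bcp]]$position,
                                  direction = s * v2b,
                                  orientation = "descending",
                                  rho_floor = ring_floor, cps = cps,
                                  snap_tol = opt$snap_tol)
        app <- attr(gp, "approach_dist")
        hits <- rcp_idx[rcp_idx == gp$cp_end | app[rcp_idx] <= opt$capture_tol]
        for (r in hits) {
          link_rows[[length(link_rows) + 1]] <- c(bcp = a$bcp, rcp = r)
        }
      }
    }
    if (length(link_rows) > 0) bcp_links <- do.call(rbind, link_rows)
    links <- NULL
    if ("cages" %in% opt$components && length(ccp_idx) > 0) {
      link_rows <- list()
      for (r in rcp_idx) {
        v1 <- cps[[r]]$eigenvectors[, 1]
        for (s in c(1, -1)) {
          gp <- trace_gradient_path(den, cps[[r]]$position, direction = s * v1,
                                    orientation = "descending",
                                    rho_floor = ring_floor / 10,
                                    cps = cps, snap_tol = opt$snap_tol)
          hit <- gp$cp_end
          app <- attr(gp, "approach_dist")
          if (hit == -1L && !is.null(app)) {
            close_ccp <- ccp_idx[app[ccp_idx] <= opt$capture_tol]
            if (length(close_ccp) > 0) hit <- close_ccp[which.min(app[close_ccp])]
          }
          if (hit != -1L && hit %in% ccp_idx) {
            link_rows[[length(link_rows) + 1]] <- c(rcp = r, ccp = hit)
          }
        }
      }
      if (length(link_rows) > 0) links <- do.call(rbind, link_rows)
    }
    rc <- assemble_rings_and_cages(graph, ring_surfaces, cps,
                                   rcp_ccp_links = links,
                                   bcp_rcp_links = bcp_links,
                                   capture_tol = opt$capture_tol)
    rings <- rc$rings; cages <- rc$cages
  }

  basins <- list()
  if ("basins" %in% opt$components) {
    dirs <- icosphere(opt$basin_level)$vertices
    for (a in nacp_idx) {
      bpaths <- lapply(seq_len(nrow(dirs)), function(i) {
        trace_gradient_path(den, cps[[a]]$position, direction = dirs[i, ],
                            orientation = "descending",
                            rho_floor = opt$rho_floor, cps = cps,
                            snap_tol = opt$snap_tol)
      })
      basins[[length(basins) + 1]] <- atomic_basin(a, bpaths)
    }
  }

  ias_list <- list(); atomic_surfaces <- list()
  if ("surfaces" %in% opt$components && length(graph$ails) > 0) {
    graph_bcps <- vapply(graph$ails, function(x) x$bcp, integer(1))
    for (b in graph_bcps) {
      ias_list[[length(ias_list) + 1]] <- build_interatomic_surface(
        den, b, cps, n_angular = opt$ias_angular, n_rings = opt$ias_rings,
        rho_floor = opt$rho_floor, snap_tol = opt$snap_tol)
    }
    for (a in nacp_idx) {
      member <- which(vapply(graph$ails, function(x) a %in% x$nacps, logical(1)))
      if (length(member) > 0) {
        atomic_surfaces[[length(atomic_surfaces) + 1]] <-
          atomic_surface(a, member)  # ias_list is ordered like graph$ails
      }
    }
  }

  envelopes <- list()
  if ("envelopes" %in% opt$components) {
    for (a in nacp_idx) {
      envelopes[[length(envelopes) + 1]] <- build_envelope(
        den, a, cps, isovalue = opt$envelope_isovalue,
        subdivision_level = opt$envelope_level)
    }
  }

  src <- source_information(
    qm_method = "promolecular", basis_set = "slater-shell exponential sum",
    wavefunction_program = "none",
    qct_program = paste0("rhotop ", as.character(utils::packageVersion("rhotop"))))
  topology(source = src, nuclei = nuclei, critical_points = cps,
           gvf = gradient_vector_field(
             molecular_graph = graph, rings = rings, cages = cages,
             atomic_surfaces = atomic_surfaces,
             ring_surfaces = ring_surfaces, basins = basins,
             envelopes = envelopes, interatomic_surfaces = ias_list),
           snap_tol = opt$snap_tol)
}
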