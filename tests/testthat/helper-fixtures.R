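# shared lazily-computed fixtures; the store persists across test files
# within one test run, so expensive topologies are generated only once
.fixture_store <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (is.null(.fixture_store[[key]])) {
    .fixture_store[[key]] <- suppressWarnings(force(expr))
  }
  .fixture_store[[key]]
}

fixture_density <- function(name) {
  cached_fixture(paste0("den:", name),
                 promolecular_density(build_fixture_geometry(name)))
}

fixture_cps <- function(name) {
  cached_fixture(paste0("cps:", name), find_critical_points(fixture_density(name)))
}

# graph + rings + cages topology (no basins/surfaces/envelopes)
fixture_graph_topology <- function(name) {
  cached_fixture(paste0("gtop:", name), generate_topology(
    build_fixture_geometry(name),
    topology_options(components = c("graph", "rings", "cages"))))
}

# small complete topology for h2 (reduced fans keep it fast)
fixture_h2_full <- function() {
  cached_fixture("h2full", generate_topology(
    build_fixture_geometry("h2"),
    topology_options(basin_level = 1, envelope_level = 2,
                     ias_angular = 12, ias_rings = 4)))
}

cp_labels <- function(cps) vapply(cps, function(cp) cp$label, character(1))

# independent grid-scan census oracle: attractors are grid-local maxima
# of rho; smooth CPs are grid-local minima of |grad rho|^2 with a small
# gradient, classified by the Hessian eigenvalues at the grid point.
# `grid` is a list of x/y/z coordinate vectors (a fixed plane is allowed).
grid_census_oracle <- function(den, grid, spacing, grad_cut = 0.25,
                               rho_cut = 1e-5) {
  pts <- as.matrix(expand.grid(x = grid$x, y = grid$y, z = grid$z))
  ev <- rhotop:::.promol_rho_grad_batch(den, pts)
  dims <- vapply(grid, length, integer(1))
  arr_rho <- array(ev$rho, dim = dims)
  arr_g2 <- array(ev$grad2, dim = dims)
  local_extrema <- function(arr, maxima, candidates) {
    idx <- which(candidates, arr.ind = TRUE)
    keep <- logical(nrow(idx))
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, ]
      lo <- pmax(i - 1, 1); hi <- pmin(i + 1, dim(arr))
      nb <- arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
      v <- arr[i[1], i[2], i[3]]
      keep[r] <- if (maxima) v >= max(nb) else v <= min(nb)
      # boundary extrema (along non-singleton axes) are window artifacts
      if (any((i == 1 | i == dim(arr)) & dim(arr) > 1)) keep[r] <- FALSE
    }
    idx[keep, , drop = FALSE]
  }
  to_xyz <- function(idx) {
    cbind(grid$x[idx[, 1]], grid$y[idx[, 2]], grid$z[idx[, 3]])
  }
  cluster_count <- function(pts, tol = 0.5) {
    if (nrow(pts) == 0) return(pts)
    keep <- pts[1, , drop = FALSE]
    for (r in seq_len(nrow(pts))[-1]) {
      d2 <- rowSums(sweep(keep, 2, pts[r, ], `-`)^2)
      if (min(d2) > tol^2) keep <- rbind(keep, pts[r, ])
    }
    keep
  }
  maxima <- to_xyz(local_extrema(arr_rho, TRUE, arr_rho > rho_cut))
  nacp <- nrow(cluster_count(maxima))
  saddles <- to_xyz(local_extrema(arr_g2, FALSE, arr_g2 < grad_cut^2))
  if (nrow(saddles) > 0) {
    # grid points that land exactly on a nuclear cusp are not saddles
    nd <- apply(saddles, 1, function(p) {
      sqrt(min(rowSums(sweep(den$nucleus_positions, 2, p, `-`)^2)))
    })
    saddles <- saddles[nd > 0.2, , drop = FALSE]
  }
  if (nrow(saddles) > 0) {
    svals <- rhotop:::.promol_rho_grad_batch(den, saddles)
    saddles <- saddles[sqrt(svals$grad2) < grad_cut & svals$rho > rho_cut, ,
                       drop = FALSE]
  }
  saddles <- cluster_count(saddles)
  counts <- c(nacp = nacp, bcp = 0L, rcp = 0L, ccp = 0L)
  for (r in seq_len(nrow(saddles))) {
    h <- rhotop:::.promol_eval(den, saddles[r, ])$hess
    cls <- classify_critical_point(sort(eigen(h, symmetric = TRUE,
                                              only.values = TRUE)$values),
                                   zero_tol = 1e-8)
    if (cls$label %in% c("BCP", "RCP", "CCP")) {
      nm <- tolower(cls$label)
      counts[nm] <- counts[nm] + 1L
    }
  }
  counts
}

# finite-difference derivatives of the promolecular density (independent
# oracle for the analytic gradient/Hessian)
fd_gradient <- function(den, r, h = 1e-5) {
  vapply(1:3, function(k) {
    e <- numeric(3); e[k] <- h
    (rhotop:::.promol_rho_only(den, r + e) -
     rhotop:::.promol_rho_only(den, r - e)) / (2 * h)
  }, numeric(1))
}

fd_hessian <- function(den, r, h = 1e-4) {
  cols <- vapply(1:3, function(k) {
    e <- numeric(3); e[k] <- h
    (rhotop:::.promol_eval(den, r + e)$grad -
     rhotop:::.promol_eval(den, r - e)$grad) / (2 * h)
  }, numeric(3))
  (cols + t(cols)) / 2
}
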