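#' Build a promolecular density for a set of nuclei
#'
#' The promolecular density is a sum of spherically symmetric atomic
#' densities, one exponential term per occupied Slater shell:
#' \deqn{\rho(r) = \sum_A \sum_i c_i \exp(-\zeta_i |r - R_A|)}
#' with per-element coefficients \eqn{c_i > 0} (au) and exponents
#' \eqn{\zeta_i > 0} (1/bohr) from the bundled table, normalized so that
#' each shell integrates to its electron count. Its topology (maxima at
#' nuclei, saddles between bonded atoms, ring/cage minima) mimics that of
#' a molecular electron density and serves as an analytic stand-in with
#' closed-form gradient and Hessian.
#'
#' @param nuclei list of [nucleus()] objects, or a `fixture_geometry`.
#' @return an object of class `promolecular_density`.
#' @seealso [evaluate_density()], [find_critical_points()],
#'   [generate_topology()]
#' @export
promolecular_density <- function(nuclei) {
  if (inherits(nuclei, "fixture_geometry")) nuclei <- nuclei$nuclei
  if (length(nuclei) == 0) stop("at least one nucleus is required")
  terms <- .promolecular_terms()
  pos <- list(); cc <- list(); zz <- list(); owner <- list()
  for (k in seq_along(nuclei)) {
    nuc <- nuclei[[k]]
    rows <- terms[terms$symbol == nuc$element, ]
    if (nrow(rows) == 0) {
      stop("no promolecular terms for element ", nuc$element)
    }
    pos[[k]] <- matrix(rep(nuc$position, each = nrow(rows)), ncol = 3)
    cc[[k]] <- rows$coef; zz[[k]] <- rows$zeta
    owner[[k]] <- rep(k, nrow(rows))
  }
  npos <- t(vapply(nuclei, function(n) n$position, numeric(3)))
  structure(list(nuclei = nuclei,
                 nucleus_positions = npos,
                 term_position = do.call(rbind, pos),
                 term_coef = unlist(cc), term_zeta = unlist(zz),
                 term_nucleus = unlist(owner)),
            class = "promolecular_density")
}

.promolecular_terms <- function() {
  if (is.null(.rhotop_cache$promol_terms)) {
    .rhotop_cache$promol_terms <- utils::read.csv(
      .extdata("promolecular_terms.csv"), stringsAsFactors = FALSE)
  }
  .rhotop_cache$promol_terms
}

# core evaluator: rho, gradient, Hessian of the exponential sum at a
# single point; no cusp guard (rho itself is finite at nuclei, only the
# derivatives are singular there)
.promol_eval <- function(den, r, derivatives = TRUE) {
  diff <- sweep(den$term_position, 2, r, `-`)
  diff <- -diff                              # r - R_A
  d <- sqrt(rowSums(diff * diff))
  d <- pmax(d, 1e-300)
  e <- den$term_coef * exp(-den$term_zeta * d)
  rho <- sum(e)
  if (!derivatives) return(list(rho = rho))
  b <- den$term_zeta * e / d                 # zeta*f/d
  grad <- colSums(diff * (-b))
  a <- (den$term_zeta^2 * e + b) / d^2       # (zeta^2 f + zeta f / d) / d^2
  hess <- crossprod(diff * a, diff) - diag(sum(b), 3)
  list(rho = rho, grad = as.numeric(grad), hess = unname(hess))
}

.promol_rho_only <- function(den, r) .promol_eval(den, r, derivatives = FALSE)$rho

# vectorized rho + |grad|^2 over an n x 3 matrix of points (used by the
# grid-scan test oracle and envelope bracketing); chunked to bound memory
.promol_rho_grad_batch <- function(den, pts) {
  n <- nrow(pts)
  rho <- numeric(n); g2 <- numeric(n)
  chunk <- max(1L, as.integer(2e6 / length(den$term_coef)))
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    p <- pts[idx, , drop = FALSE]
    dx <- outer(p[, 1], den$term_position[, 1], `-`)
    dy <- outer(p[, 2], den$term_position[, 2], `-`)
    dz <- outer(p[, 3], den$term_position[, 3], `-`)
    d <- sqrt(dx * dx + dy * dy + dz * dz)
    d[d < 1e-300] <- 1e-300
    e <- sweep(exp(sweep(d, 2, -den$term_zeta, `*`)), 2, den$term_coef, `*`)
    rho[idx] <- rowSums(e)
    b <- sweep(e, 2, den$term_zeta, `*`) / d
    gx <- rowSums(-b * dx); gy <- rowSums(-b * dy); gz <- rowSums(-b * dz)
    g2[idx] <- gx * gx + gy * gy + gz * gz
  }
  list(rho = rho, grad2 = g2)
}

#' Evaluate a promolecular density, its gradient and Hessian
#'
#' @param density a [promolecular_density()].
#' @param r numeric length-3 position in bohr. Must not coincide with a
#'   nucleus: the exponential cusp makes the derivatives singular there.
#' @return list with components `rho` (au), `grad` (length 3) and `hess`
#'   (symmetric 3x3 matrix), all exact closed-form derivatives.
#' @export
#' @examples
#' den <- promolecular_density(list(nucleus("H", c(0, 0, 0), 0)))
#' evaluate_density(den, c(1, 0, 0))$rho  # (1/pi) * exp(-2)
evaluate_density <- function(density, r) {
  r <- .check_pos3(r)
  d <- sqrt(rowSums(sweep(density$nucleus_positions, 2, r, `-`)^2))
  if (any(d < 1e-10)) {
    stop("evaluation point coincides with a nucleus (density cusp)")
  }
  .promol_eval(density, r)
}

# system extent helper: centroid and max nuclear distance
.density_extent <- function(den) {
  ctr <- colMeans(den$nucleus_positions)
  r <- sqrt(max(rowSums(sweep(den$nucleus_positions, 2, ctr, `-`)^2)))
  list(center = ctr, radius = max(r, 1))
}

#' Bundled fixture geometries
#'
#' Idealized symmetric geometries for a set of reference molecules,
#' constructed from internal coordinates and returned in bohr:
#' \describe{
#'   \item{h2}{H2, bond 0.74 Å, centered on the origin.}
#'   \item{hcn}{linear HCN, H–C 1.066 Å, C–N 1.153 Å.}
#'   \item{benzene}{D6h, C–C 1.3915 Å, C–H 1.0800 Å, centroid at origin.}
#'   \item{hf_pentamer}{planar C5h ring of five HF units, F–H 0.93 Å with
#'     collinear H···F hydrogen bonds of 1.80 Å.}
#'   \item{hfh_anion}{linear centrosymmetric [F–H–F]^-, F–H 1.14 Å.}
#'   \item{s8}{crown D4d S8, S–S 2.05 Å, S–S–S angle 108°.}
#'   \item{acetic_dimer}{centrosymmetric (CH3COOH)2 with two collinear
#'     O–H···O hydrogen bonds (H···O 1.68 Å).}
#'   \item{hexamethylenetetramine}{adamantane-like (CH2)6N4 cage, C–N
#'     1.47 Å, C–H 1.09 Å, ideal tetrahedral angles.}
#' }
#'
#' @param name one of the fixture names above.
#' @return an object of class `fixture_geometry` with fields `name` and
#'   `nuclei`.
#' @export
build_fixture_geometry <- function(name) {
  known <- c("benzene", "s8", "hf_pentamer", "hfh_anion", "acetic_dimer",
             "hexamethylenetetramine", "hcn", "h2")
  if (!name %in% known) {
    stop("unknown fixture '", name, "'; available: ",
         paste(known, collapse = ", "))
  }
  ang <- angstrom_to_bohr
  nuclei <- switch(name,
    h2 = {
      z <- ang(0.74) / 2
      list(nucleus("H", c(0, 0, -z), 0), nucleus("H", c(0, 0, z), 1))
    },
    hcn = {
      list(nucleus("H", c(0, 0, 0), 0),
           nucleus("C", c(0, 0, ang(1.066)), 1),
           nucleus("N", c(0, 0, ang(1.066 + 1.153)), 2))
    },
    benzene = {
      rc <- ang(1.3915); rh <- ang(1.3915 + 1.08)
      out <- list()
      for (k in 0:5) {
        th <- k * pi / 3
        out[[k + 1]] <- nucleus("C", c(rc * cos(th), rc * sin(th), 0), k)
      }
      for (k in 0:5) {
        th <- k * pi / 3
        out[[k + 7]] <- nucleus("H", c(rh * cos(th), rh * sin(th), 0), k + 6)
      }
      out
    },
    hf_pentamer = {
      # pentagon of F atoms; H on each edge, 0.93 A from its F along the
      # edge so that F-H...F is collinear with H...F = 1.80 A
      side <- ang(0.93 + 1.80)
      rad <- side / (2 * sin(pi / 5))
      fpos <- lapply(0:4, function(k) {
        th <- 2 * pi * k / 5
        c(rad * cos(th), rad * sin(th), 0)
      })
      out <- list()
      for (k in 0:4) out[[k + 1]] <- nucleus("F", fpos[[k + 1]], k)
      for (k in 0:4) {
        a <- fpos[[k + 1]]; b <- fpos[[(k + 1) %% 5 + 1]]
        u <- (b - a) / sqrt(sum((b - a)^2))
        out[[k + 6]] <- nucleus("H", a + ang(0.93) * u, k + 5)
      }
      out
    },
    hfh_anion = {
      d <- ang(1.14)
      list(nucleus("F", c(0, 0, -d), 0), nucleus("H", c(0, 0, 0), 1),
           nucleus("F", c(0, 0, d), 2))
    },
    s8 = {
      # crown: S_k at (R cos(45k), R sin(45k), (-1)^k h); R,h solved from
      # S-S = 2.05 A and S-S-S angle 108 deg
      L <- ang(2.05); theta <- 108 * pi / 180
      sol <- .solve_crown(L, theta, n = 8)
      out <- list()
      for (k in 0:7) {
        th <- k * pi / 4
        out[[k + 1]] <- nucleus("S", c(sol$R * cos(th), sol$R * sin(th),
                                       ifelse(k %% 2 == 0, sol$h, -sol$h)), k)
      }
      out
    },
    acetic_dimer = {
      .acetic_dimer_nuclei()
    },
    hexamethylenetetramine = {
      # N at alternate tetrahedron vertices (a,a,a)-type, C at (2a,0,0)-type;
      # b = 2a gives ideal tetrahedral N-C-N, C-N = a*sqrt(3)
      a <- ang(1.47) / sqrt(3); b <- 2 * a
      npos <- rbind(c(a, a, a), c(a, -a, -a), c(-a, a, -a), c(-a, -a, a))
      cpos <- rbind(c(b, 0, 0), c(-b, 0, 0), c(0, b, 0), c(0, -b, 0),
                    c(0, 0, b), c(0, 0, -b))
      out <- list()
      for (k in 1:4) out[[k]] <- nucleus("N", npos[k, ], k - 1)
      for (k in 1:6) out[[4 + k]] <- nucleus("C", cpos[k, ], 3 + k)
      # two H per C completing a tetrahedron around it
      half <- acos(-1 / 3) / 2   # half of the ideal H-C-H angle
      ch <- ang(1.09)
      idx <- 10
      for (k in 1:6) {
        cpt <- cpos[k, ]
        dn <- sqrt(colSums((t(npos) - cpt)^2))
        nb <- npos[order(dn)[1:2], , drop = FALSE]
        u <- (nb[1, ] - cpt); u <- u / sqrt(sum(u^2))
        v <- (nb[2, ] - cpt); v <- v / sqrt(sum(v^2))
        w <- -(u + v); w <- w / sqrt(sum(w^2))      # bisector, away from Ns
        p <- .cross3(u, v); p <- p / sqrt(sum(p^2)) # normal to N-C-N plane
        for (s in c(1, -1)) {
          hdir <- cos(half) * w + s * sin(half) * p
          out[[idx + 1]] <- nucleus("H", cpt + ch * hdir, idx)
          idx <- idx + 1
        }
      }
      out
    })
  geo <- structure(list(name = name, nuclei = nuclei),
                   class = "fixture_geometry")
  .check_geometry(geo)
  geo
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.check_geometry <- function(geo) {
  pos <- t(vapply(geo$nuclei, function(n) n$position, numeric(3)))
  if (nrow(pos) > 1) {
    dm <- as.matrix(stats::dist(pos))
    diag(dm) <- Inf
    if (min(dm) <= 0.5) stop("interatomic distances must exceed 0.5 bohr")
  }
  invisible(geo)
}

# solve crown-ring R (ring radius) and h (half height) for bond length L
# and bond angle theta; alternating z = +-h, azimuthal spacing 2*pi/n
.solve_crown <- function(L, theta, n = 8) {
  phi <- 2 * pi / n
  # with R fixed by h through the bond-length constraint, match the angle
  angle_err <- function(h) {
    R2 <- (L^2 - 4 * h^2) / (2 * (1 - cos(phi)))
    if (R2 <= 0) return(NA_real_)
    R <- sqrt(R2)
    p0 <- c(R, 0, h)
    p1 <- c(R * cos(phi), R * sin(phi), -h)
    p2 <- c(R * cos(2 * phi), R * sin(2 * phi), h)
    v1 <- p0 - p1; v2 <- p2 - p1
    acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) - theta
  }
  h <- stats::uniroot(angle_err, c(1e-6, L / 2 - 1e-6), tol = 1e-12)$root
  list(R = sqrt((L^2 - 4 * h^2) / (2 * (1 - cos(phi)))), h = h)
}

# centrosymmetric acetic acid dimer built from standard internal
# coordinates; heavy atoms and acidic H in the xy-plane
.acetic_dimer_nuclei <- function() {
  ang <- angstrom_to_bohr
  deg <- function(d) d * pi / 180
  # monomer in the plane: carboxyl C at origin, methyl C along -x
  cc <- ang(1.50); co_d <- ang(1.22); co_s <- ang(1.31)
  oh <- ang(0.97); ch <- ang(1.09); hb <- ang(1.68)
  c2 <- c(0, 0, 0)                       # carboxyl carbon
  c1 <- c(-cc, 0, 0)                     # methyl carbon
  o1 <- c2 + co_d * c(cos(deg(55)), sin(deg(55)), 0)    # C=O
  o2 <- c2 + co_s * c(cos(deg(-65)), sin(deg(-65)), 0)  # C-O(H)
  # O-H pointing toward the partner's carbonyl O (roughly +x)
  h_o <- o2 + oh * c(cos(deg(-5)), sin(deg(-5)), 0)
  # methyl hydrogens at 109.5 deg from the C1->C2 bond, staggered about it
  axis <- c(1, 0, 0)
  ref <- c(0, 1, 0)
  h_in <- c1 + ch * (cos(deg(109.5)) * axis +
                     sin(deg(109.5)) * ref)
  hs <- lapply(c(120, 240), function(a) {
    # rotate h_in - c1 about the C2->C1 axis direction (-x) by a degrees
    v <- h_in - c1
    k <- c(-1, 0, 0)
    th <- deg(a)
    vr <- v * cos(th) + .cross3(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
    c1 + vr
  })
  mono <- rbind(c1, c2, o1, o2, h_o, h_in, hs[[1]], hs[[2]])
  elems <- c("C", "C", "O", "O", "H", "H", "H", "H")
  # place inversion center on the O...H hydrogen-bond midline: partner's
  # carbonyl O sits hb beyond the acidic H along the O-H direction
  dir <- (h_o - o2); dir <- dir / sqrt(sum(dir^2))
  o1_partner_target <- h_o + hb * dir
  center <- (o1 + o1_partner_target) / 2
  mono <- sweep(mono, 2, center, `-`)
  dimer <- rbind(mono, -mono)
  elems <- c(elems, elems)
  out <- vector("list", nrow(dimer))
  for (k in seq_len(nrow(dimer))) {
    out[[k]] <- nucleus(elems[k], dimer[k, ], k - 1)
  }
  out
}

#' Read an XYZ geometry file
#'
#' Standard XYZ: atom count line, comment line, then `symbol x y z` rows
#' in ångström. Coordinates are converted to bohr.
#'
#' @param path path to the file.
#' @return a `fixture_geometry` named after the file.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("XYZ file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("XYZ file too short: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) stop("invalid atom count in XYZ header: ", path)
  if (length(lines) < 2 + n) stop("XYZ file lists fewer atoms than its header: ", path)
  nuclei <- vector("list", n)
  for (k in seq_len(n)) {
    fields <- strsplit(trimws(lines[2 + k]), "\\s+")[[1]]
    if (length(fields) < 4) stop("malformed XYZ atom line ", 2 + k)
    xyz <- suppressWarnings(as.numeric(fields[2:4]))
    if (any(is.na(xyz))) stop("non-numeric coordinate on XYZ line ", 2 + k)
    nuclei[[k]] <- nucleus(fields[1], angstrom_to_bohr(xyz), k - 1)
  }
  geo <- structure(list(name = sub("\\.xyz$", "", basename(path)),
                        nuclei = nuclei),
                   class = "fixture_geometry")
  .check_geometry(geo)
  geo
}

#' Icosahedral sphere subdivision
#'
#' Subdivides a unit icosahedron `level` times (each level splits every
#' triangle in four, vertices projected back to the sphere). Levels 0–3
#' give 12, 42, 162 and 642 vertices.
#'
#' @param level non-negative integer subdivision level.
#' @return a [triangulation()] of the unit sphere (vertices, edges, faces).
#' @export
icosphere <- function(level = 2) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (i in seq_len(level)) {
    midcache <- new.env(parent = emptyenv())
    nf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- midcache[[key]]
      if (!is.null(hit)) return(hit)
      m <- v[a, ] + v[b, ]
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      idx <- nrow(v)
      assign(key, idx, envir = midcache)
      idx
    }
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[4 * t - 3, ] <- c(a, ab, ca)
      nf[4 * t - 2, ] <- c(b, bc, ab)
      nf[4 * t - 1, ] <- c(cc, ca, bc)
      nf[4 * t, ]     <- c(ab, bc, ca)
    }
    f <- nf
  }
  e <- unique(t(apply(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]), 1, sort)))
  triangulation(v, edges = e, faces = f)
}
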