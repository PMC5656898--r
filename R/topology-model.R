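#' @name topology-model
#' @title Typed model of a scalar-field topology
#'
#' @description
#' The in-memory representation used throughout the package mirrors the
#' object hierarchy of quantum chemical topology (QCT): a [topology()]
#' owns source metadata, nuclei, critical points and a gradient vector
#' field, which in turn is composed of a molecular graph (atomic
#' interaction lines), rings, cages, atomic basins, interatomic/atomic
#' surfaces, ring surfaces and constant-density envelopes.
#'
#' Conventions:
#' * All coordinates are in bohr.
#' * Critical points are referenced by 1-based position in
#'   `topology$critical_points`; the reserved sentinel `-1` denotes the
#'   critical point at infinity (a truncated gradient-path terminus).
#' * Nucleus `index` fields are 0-based identifiers, as written to file.
NULL

# default tolerances (see methods vignette for rationale)
.default_zero_tol  <- 1e-8   # Hessian eigenvalue degeneracy threshold (au)
.default_snap_tol  <- 1e-4   # path endpoint <-> CP identity (bohr)
.default_merge_tol <- 1e-3   # duplicate-CP merging distance (bohr)

.check_pos3 <- function(x, what = "position") {
  if (!is.numeric(x) || length(x) != 3 || !all(is.finite(x))) {
    stop(what, " must be a finite numeric vector of length 3")
  }
  as.numeric(x)
}

.check_scalars <- function(scalars) {
  if (is.null(scalars)) return(stats::setNames(numeric(0), character(0)))
  if (!is.numeric(scalars) || is.null(names(scalars)) ||
      any(!nzchar(names(scalars))) || any(!is.finite(scalars))) {
    stop("scalars must be a named numeric vector with non-empty names and finite values")
  }
  scalars
}

#' Construct a point with attached scalar values
#'
#' A point in R^3 carrying a map from scalar-function names (e.g. `"rho"`)
#' to values in atomic units.
#'
#' @param position numeric length-3, bohr.
#' @param scalars named numeric vector (may be empty).
#' @return an object of class `qct_point`.
#' @export
qct_point <- function(position, scalars = c()) {
  structure(list(position = .check_pos3(position),
                 scalars = .check_scalars(scalars)),
            class = "qct_point")
}

#' Construct a critical point
#'
#' A critical point of a scalar field, characterized by its rank
#' \eqn{\omega} (number of non-zero Hessian eigenvalues) and signature
#' \eqn{\sigma} (sum of their signs). Eigen-data are optional: cusp
#' attractors of a promolecular density, where the Hessian diverges, carry
#' none.
#'
#' @param position numeric length-3, bohr.
#' @param rank integer in 0..3.
#' @param signature integer with `abs(signature) <= rank` and
#'   `signature %% 2 == rank %% 2`.
#' @param label one of `"NACP"`, `"BCP"`, `"RCP"`, `"CCP"`, `"degenerate"`;
#'   derived from `(rank, signature)` when `NULL`.
#' @param eigenvalues optional ascending numeric triple (au).
#' @param eigenvectors optional 3x3 matrix of orthonormal columns matching
#'   `eigenvalues`.
#' @param scalars named numeric vector of scalar values at the point.
#' @param zero_tol degeneracy tolerance used to cross-check `eigenvalues`
#'   against `rank`/`signature`.
#' @return an object of class `critical_point` (inherits `qct_point`).
#' @export
critical_point <- function(position, rank, signature, label = NULL,
                           eigenvalues = NULL, eigenvectors = NULL,
                           scalars = c(), zero_tol = .default_zero_tol) {
  rank <- as.integer(rank); signature <- as.integer(signature)
  if (!(rank %in% 0:3)) stop("rank must be in 0..3")
  if (abs(signature) > rank) stop("|signature| must not exceed rank")
  if ((signature - rank) %% 2L != 0L) {
    stop("signature and rank must have equal parity (sigma = omega mod 2)")
  }
  if (!is.null(eigenvalues)) {
    if (length(eigenvalues) != 3 || any(!is.finite(eigenvalues)) ||
        is.unsorted(eigenvalues)) {
      stop("eigenvalues must be a finite ascending triple")
    }
    cls <- classify_critical_point(eigenvalues, zero_tol)
    if (cls$rank != rank || cls$signature != signature) {
      stop("eigenvalues are inconsistent with the stated rank/signature")
    }
  }
  if (!is.null(eigenvectors)) {
    eigenvectors <- as.matrix(eigenvectors)
    if (!all(dim(eigenvectors) == c(3, 3)) || any(!is.finite(eigenvectors))) {
      stop("eigenvectors must be a finite 3x3 matrix")
    }
  }
  if (is.null(label)) label <- .cp_label(rank, signature)
  structure(list(position = .check_pos3(position),
                 scalars = .check_scalars(scalars),
                 rank = rank, signature = signature, label = label,
                 eigenvalues = if (is.null(eigenvalues)) NULL else as.numeric(eigenvalues),
                 eigenvectors = eigenvectors),
            class = c("critical_point", "qct_point"))
}

.cp_label <- function(rank, signature) {
  if (rank != 3L) return("degenerate")
  switch(as.character(signature),
         "-3" = "NACP", "-1" = "BCP", "1" = "RCP", "3" = "CCP")
}

#' Construct a nucleus
#'
#' @param element element symbol; must appear in the bundled periodic table.
#' @param position numeric length-3, bohr.
#' @param index integer identifier >= 0 (0-based, as serialized).
#' @return an object of class `nucleus`.
#' @export
nucleus <- function(element, position, index) {
  .element_row(element)  # errors for unknown symbols
  index <- as.integer(index)
  if (is.na(index) || index < 0L) stop("nucleus index must be an integer >= 0")
  structure(list(element = element, position = .check_pos3(position),
                 index = index),
            class = "nucleus")
}

#' Construct a gradient path
#'
#' An ordered polyline following the gradient field between two critical
#' points (one possibly at infinity, sentinel index `-1`).
#'
#' @param points n x 3 numeric matrix of positions (bohr), n >= 2, with
#'   consecutive points distinct.
#' @param cp_start,cp_end 1-based critical-point indices (`-1` = infinity).
#' @param scalars optional data.frame of per-point scalar values (one row
#'   per point; typically a single `rho` column).
#' @return an object of class `gradient_path`.
#' @export
gradient_path <- function(points, cp_start, cp_end, scalars = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3 || nrow(points) < 2 || any(!is.finite(points))) {
    stop("points must be a finite n x 3 matrix with n >= 2")
  }
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  if (any(seg == 0)) stop("consecutive path points must be distinct")
  if (!is.null(scalars)) {
    scalars <- as.data.frame(scalars)
    if (nrow(scalars) != nrow(points)) {
      stop("scalars must have one row per path point")
    }
  }
  structure(list(points = unname(points),
                 cp_start = as.integer(cp_start), cp_end = as.integer(cp_end),
                 scalars = scalars),
            class = "gradient_path")
}

#' Construct an atomic interaction line
#'
#' Two gradient paths sharing a bond critical point and terminating at two
#' distinct nuclear attractors; at an equilibrium geometry this is a bond
#' path.
#'
#' @param paths list of exactly two [gradient_path()] objects that share
#'   `bcp` at one end.
#' @param bcp 1-based index of the shared BCP.
#' @return an object of class `atomic_interaction_line`.
#' @export
atomic_interaction_line <- function(paths, bcp) {
  if (length(paths) != 2) stop("an atomic interaction line needs exactly 2 gradient paths")
  bcp <- as.integer(bcp)
  ends <- vapply(paths, function(p) {
    if (p$cp_start == bcp) p$cp_end
    else if (p$cp_end == bcp) p$cp_start
    else stop("both paths of an AIL must reference the shared BCP at one end")
  }, integer(1))
  if (ends[1] == ends[2]) stop("the two far endpoints of an AIL must be distinct")
  structure(list(paths = paths, bcp = bcp, nacps = ends),
            class = "atomic_interaction_line")
}

#' Construct a molecular graph
#'
#' @param ails list of [atomic_interaction_line()] objects, no two sharing
#'   a BCP.
#' @return an object of class `molecular_graph`.
#' @export
molecular_graph <- function(ails = list()) {
  bcps <- vapply(ails, function(a) a$bcp, integer(1))
  if (anyDuplicated(bcps)) stop("no two AILs may share the same BCP")
  structure(list(ails = ails), class = "molecular_graph")
}

#' Construct a ring
#' @param ails integer indices (>= 3) into the molecular graph's AIL list,
#'   forming a closed cycle over their nuclear attractors.
#' @param rcp 1-based index of the ring critical point.
#' @export
qct_ring <- function(ails, rcp) {
  if (length(ails) < 3) stop("a ring needs at least 3 atomic interaction lines")
  structure(list(ails = as.integer(ails), rcp = as.integer(rcp)),
            class = "qct_ring")
}

#' Construct a cage
#' @param rings integer indices (>= 2) into the topology's ring list.
#' @param ccp 1-based index of the cage critical point.
#' @export
qct_cage <- function(rings, ccp) {
  if (length(rings) < 2) stop("a cage needs at least 2 rings")
  structure(list(rings = as.integer(rings), ccp = as.integer(ccp)),
            class = "qct_cage")
}

#' Construct an atomic basin
#' @param nacp 1-based NACP index; every path must start there.
#' @param paths list of [gradient_path()] objects with `cp_start == nacp`.
#' @export
atomic_basin <- function(nacp, paths) {
  nacp <- as.integer(nacp)
  if (!all(vapply(paths, function(p) p$cp_start == nacp, logical(1)))) {
    stop("every basin path must start at the basin's NACP")
  }
  structure(list(nacp = nacp, paths = paths), class = "atomic_basin")
}

#' Construct an interatomic surface
#' @param bcp 1-based BCP index; every path must start there.
#' @param paths list of [gradient_path()] objects with `cp_start == bcp`.
#' @param mesh optional [triangulation()].
#' @export
interatomic_surface <- function(bcp, paths, mesh = NULL) {
  bcp <- as.integer(bcp)
  if (!all(vapply(paths, function(p) p$cp_start == bcp, logical(1)))) {
    stop("every interatomic-surface path must start at the surface's BCP")
  }
  structure(list(bcp = bcp, paths = paths, mesh = mesh),
            class = "interatomic_surface")
}

#' Construct an atomic surface
#'
#' The union of the interatomic surfaces whose BCPs are bonded (through
#' the molecular graph) to one nuclear attractor.
#'
#' @param nacp 1-based NACP index.
#' @param interatomic_surfaces integer indices into the gradient vector
#'   field's flat interatomic-surface list.
#' @export
atomic_surface <- function(nacp, interatomic_surfaces) {
  structure(list(nacp = as.integer(nacp),
                 interatomic_surfaces = as.integer(interatomic_surfaces)),
            class = "atomic_surface")
}

#' Construct a constant-density envelope
#' @param nacp 1-based NACP index the envelope belongs to.
#' @param isovalue positive density value in au (convention: 0.001).
#' @param mesh a [triangulation()] of the isosurface.
#' @param points optional list of [qct_point()]s (kept for file round-trips).
#' @export
envelope <- function(nacp, isovalue, mesh, points = NULL) {
  if (!is.numeric(isovalue) || isovalue <= 0) stop("isovalue must be > 0")
  structure(list(nacp = as.integer(nacp), isovalue = as.numeric(isovalue),
                 points = points, mesh = mesh),
            class = "envelope")
}

#' Construct a ring surface
#' @param rcp 1-based RCP index; every path must start there.
#' @param paths list of [gradient_path()]s with `cp_start == rcp`.
#' @export
ring_surface <- function(rcp, paths) {
  rcp <- as.integer(rcp)
  if (!all(vapply(paths, function(p) p$cp_start == rcp, logical(1)))) {
    stop("every ring path must start at the ring's RCP")
  }
  structure(list(rcp = rcp, paths = paths), class = "ring_surface")
}

#' Construct a triangulation
#' @param vertices n x 3 numeric matrix (bohr).
#' @param edges integer m x 2 matrix of 1-based vertex index pairs (may be
#'   zero rows).
#' @param faces integer k x 3 matrix of 1-based vertex index triples with
#'   3 distinct vertices each (may be zero rows).
#' @export
triangulation <- function(vertices, edges = NULL, faces = NULL) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 3 || any(!is.finite(vertices))) {
    stop("vertices must be a finite n x 3 matrix")
  }
  n <- nrow(vertices)
  edges <- if (is.null(edges)) matrix(integer(0), 0, 2) else {
    e <- matrix(as.integer(edges), ncol = 2)
    if (any(e < 1 | e > n)) stop("edge index out of range")
    e
  }
  faces <- if (is.null(faces)) matrix(integer(0), 0, 3) else {
    f <- matrix(as.integer(faces), ncol = 3)
    if (any(f < 1 | f > n)) stop("face index out of range")
    if (any(apply(f, 1, anyDuplicated) > 0)) stop("faces must have 3 distinct vertices")
    f
  }
  structure(list(vertices = unname(vertices), edges = edges, faces = faces),
            class = "triangulation")
}

#' Construct source information
#' @param qm_method,basis_set,wavefunction_program,qct_program free-text
#'   provenance strings.
#' @export
source_information <- function(qm_method = "", basis_set = "",
                               wavefunction_program = "", qct_program = "") {
  structure(list(qm_method = qm_method, basis_set = basis_set,
                 wavefunction_program = wavefunction_program,
                 qct_program = qct_program),
            class = "source_information")
}

#' Construct a gradient vector field
#'
#' Container for the composite objects built from gradient paths. The flat
#' `interatomic_surfaces` list is shared: atomic surfaces reference into it
#' by index, since one interatomic surface bounds two atoms.
#'
#' @param molecular_graph a [molecular_graph()].
#' @param rings,cages,atomic_surfaces,ring_surfaces,basins,envelopes,
#'   interatomic_surfaces lists of the corresponding objects.
#' @export
gradient_vector_field <- function(molecular_graph = rhotop::molecular_graph(),
                                  rings = list(), cages = list(),
                                  atomic_surfaces = list(),
                                  ring_surfaces = list(),
                                  basins = list(), envelopes = list(),
                                  interatomic_surfaces = list()) {
  structure(list(molecular_graph = molecular_graph, rings = rings,
                 cages = cages, atomic_surfaces = atomic_surfaces,
                 ring_surfaces = ring_surfaces, basins = basins,
                 envelopes = envelopes,
                 interatomic_surfaces = interatomic_surfaces),
            class = "gradient_vector_field")
}

#' Construct a topology
#'
#' Validates cross-references: every CP index used by the gradient vector
#' field must resolve (or be the infinity sentinel), every gradient path's
#' terminal points must lie within `snap_tol` of its referenced CPs, and
#' every NACP must lie within `snap_tol` of exactly one nucleus.
#'
#' @param source a [source_information()].
#' @param nuclei list of [nucleus()] objects.
#' @param critical_points list of [critical_point()] objects.
#' @param gvf a [gradient_vector_field()].
#' @param snap_tol endpoint/nucleus identification tolerance in bohr.
#' @return an object of class `qct_topology`.
#' @export
topology <- function(source = source_information(), nuclei = list(),
                     critical_points = list(),
                     gvf = gradient_vector_field(),
                     snap_tol = .default_snap_tol) {
  ncp <- length(critical_points)
  check_ref <- function(i, what) {
    if (any(i != -1L & (i < 1L | i > ncp))) {
      stop("unresolvable critical-point reference in ", what)
    }
  }
  check_path <- function(p, what) {
    check_ref(c(p$cp_start, p$cp_end), what)
    for (side in c("cp_start", "cp_end")) {
      i <- p[[side]]
      if (i == -1L) next
      pt <- if (side == "cp_start") p$points[1, ] else p$points[nrow(p$points), ]
      if (sqrt(sum((pt - critical_points[[i]]$position)^2)) > snap_tol) {
        stop("gradient path endpoint in ", what,
             " is not within snap tolerance of its referenced CP")
      }
    }
  }
  for (a in gvf$molecular_graph$ails) {
    check_ref(a$bcp, "molecular graph")
    for (p in a$paths) check_path(p, "molecular graph")
  }
  for (r in gvf$rings) check_ref(r$rcp, "ring")
  for (cg in gvf$cages) check_ref(cg$ccp, "cage")
  for (b in gvf$basins) {
    check_ref(b$nacp, "basin")
    for (p in b$paths) check_path(p, "basin")
  }
  for (s in gvf$interatomic_surfaces) {
    check_ref(s$bcp, "interatomic surface")
    for (p in s$paths) check_path(p, "interatomic surface")
  }
  for (s in gvf$atomic_surfaces) check_ref(s$nacp, "atomic surface")
  for (s in gvf$ring_surfaces) {
    check_ref(s$rcp, "ring surface")
    for (p in s$paths) check_path(p, "ring surface")
  }
  for (e in gvf$envelopes) check_ref(e$nacp, "envelope")
  # every NACP sits on exactly one nucleus
  if (length(nuclei) > 0 && ncp > 0) {
    npos <- t(vapply(nuclei, function(n) n$position, numeric(3)))
    for (cp in critical_points) {
      if (cp$label != "NACP") next
      d <- sqrt(colSums((t(npos) - cp$position)^2))
      if (sum(d <= snap_tol) != 1) {
        stop("every NACP must lie within snap tolerance of exactly one nucleus")
      }
    }
  }
  structure(list(source = source, nuclei = nuclei,
                 critical_points = critical_points, gvf = gvf),
            class = "qct_topology")
}

#' Classify a critical point from Hessian eigenvalues
#'
#' The rank \eqn{\omega} is the number of eigenvalues whose magnitude
#' exceeds `zero_tol`; the signature \eqn{\sigma} is the sum of the
#' algebraic signs of those eigenvalues. Rank-3 points are labelled by
#' signature: `(3,-3)` NACP, `(3,-1)` BCP, `(3,+1)` RCP, `(3,+3)` CCP;
#' anything of lower rank is `"degenerate"`.
#'
#' @param eigenvalues ascending numeric triple of Hessian eigenvalues (au).
#' @param zero_tol positive degeneracy tolerance (au); default `1e-8`.
#' @return list with components `rank`, `signature`, `label`.
#' @export
#' @examples
#' classify_critical_point(c(-2, -1, 5))   # (3, -1) "BCP"
classify_critical_point <- function(eigenvalues, zero_tol = .default_zero_tol) {
  if (length(eigenvalues) != 3 || any(!is.finite(eigenvalues))) {
    stop("eigenvalues must be a finite numeric triple")
  }
  if (is.unsorted(eigenvalues)) stop("eigenvalues must be sorted ascending")
  if (!is.numeric(zero_tol) || zero_tol <= 0) stop("zero_tol must be > 0")
  nonzero <- abs(eigenvalues) > zero_tol
  rank <- sum(nonzero)
  signature <- sum(sign(eigenvalues[nonzero]))
  list(rank = as.integer(rank), signature = as.integer(signature),
       label = .cp_label(as.integer(rank), as.integer(signature)))
}

#' Poincaré–Hopf residual of a critical-point census
#'
#' Computes `n_nacp - n_bcp + n_rcp - n_ccp`. For the complete topology of
#' an isolated, connected system the value is 1; other values indicate a
#' missed or spurious critical point.
#'
#' @param n_nacp,n_bcp,n_rcp,n_ccp non-negative integer counts.
#' @return integer residual.
#' @export
poincare_hopf_residual <- function(n_nacp, n_bcp, n_rcp, n_ccp) {
  counts <- c(n_nacp, n_bcp, n_rcp, n_ccp)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  as.integer(n_nacp - n_bcp + n_rcp - n_ccp)
}

#' Tabulate a critical-point census
#' @param cps list of [critical_point()] objects.
#' @return named integer vector with entries `nacp`, `bcp`, `rcp`, `ccp`,
#'   `degenerate`.
#' @export
cp_census <- function(cps) {
  labels <- vapply(cps, function(cp) cp$label, character(1))
  c(nacp = sum(labels == "NACP"), bcp = sum(labels == "BCP"),
    rcp = sum(labels == "RCP"), ccp = sum(labels == "CCP"),
    degenerate = sum(labels == "degenerate"))
}

#' Assemble the molecular graph from a set of gradient paths
#'
#' Pairs of NACP-terminated gradient paths sharing one BCP become atomic
#' interaction lines; each BCP contributes at most one AIL. Paths that do
#' not match the BCP–NACP pattern are ignored. A BCP with a number of
#' NACP-terminated paths different from two (or whose two paths reach the
#' same NACP) is skipped with a warning.
#'
#' @param paths list of [gradient_path()] objects.
#' @param cps list of [critical_point()] objects the path indices refer to.
#' @return a [molecular_graph()].
#' @export
assemble_molecular_graph <- function(paths, cps) {
  labels <- vapply(cps, function(cp) cp$label, character(1))
  is_lab <- function(i, lab) {
    if (length(i) != 1 || is.na(i) || i < 1L || i > length(cps)) return(FALSE)
    labels[i] == lab
  }
  cand <- Filter(function(p) {
    (is_lab(p$cp_start, "BCP") && is_lab(p$cp_end, "NACP")) ||
    (is_lab(p$cp_end, "BCP") && is_lab(p$cp_start, "NACP"))
  }, paths)
  if (length(cand) == 0) return(molecular_graph())
  bcp_of <- vapply(cand, function(p) {
    if (is_lab(p$cp_start, "BCP")) p$cp_start else p$cp_end
  }, integer(1))
  ails <- list()
  for (b in sort(unique(bcp_of))) {
    pair <- cand[bcp_of == b]
    far <- vapply(pair, function(p) if (p$cp_start == b) p$cp_end else p$cp_start,
                  integer(1))
    if (length(pair) != 2 || far[1] == far[2]) {
      warning("BCP ", b, " does not have two gradient paths to distinct NACPs; skipped")
      next
    }
    ails[[length(ails) + 1]] <- atomic_interaction_line(pair, b)
  }
  molecular_graph(ails)
}

# distances from each CP to each of a path's recorded near-approach
# minima; used by ring assembly (attribute set by trace_gradient_path)
.path_reached_cps <- function(path, capture_tol) {
  reached <- integer(0)
  if (path$cp_end != -1L) reached <- path$cp_end
  app <- attr(path, "approach_dist")
  if (!is.null(app)) reached <- union(reached, which(app <= capture_tol))
  reached
}

#' Assemble rings and cages from ring surfaces and the molecular graph
#'
#' For each ring critical point, candidate AILs are selected from the
#' evidence carried by its ring-surface paths: an AIL is a candidate when
#' its bond critical point is reached (terminal CP, or approached within
#' `capture_tol` — the BCP-terminated ring path is a separatrix, so
#' numerical traces pass close rather than ending exactly on it), or when
#' both of its nuclear attractors are terminal points of ring paths (the
#' fan partitions into sectors ending at the ring's atoms, which is the
#' numerically stable signature of ring membership), or when BCP-side
#' evidence in `bcp_rcp_links` connects it to this RCP. The candidate set is
#' pruned to a single closed cycle over its nuclear attractors by
#' iterative removal of pendant AILs; ring surfaces that do not yield a
#' valid cycle of at least 3 AILs are omitted with a warning. A ring belongs to a cage when the descending trace from its
#' RCP along the ring-axis eigendirection reaches that cage critical point;
#' that connectivity is supplied via `rcp_ccp_links` (computed by
#' [generate_topology()]).
#'
#' @param graph a [molecular_graph()].
#' @param ring_surfaces list of [ring_surface()] objects.
#' @param cps list of [critical_point()] objects.
#' @param rcp_ccp_links optional two-column matrix/data.frame of
#'   (rcp index, ccp index) pairs; when `NULL` no cages are formed.
#' @param bcp_rcp_links optional two-column matrix/data.frame of
#'   (bcp index, rcp index) pairs from descending traces leaving each BCP
#'   within its interatomic surface (see [generate_topology()]).
#' @param capture_tol near-approach radius in bohr for counting a BCP as
#'   reached by a ring path (default 0.3).
#' @return list with components `rings` (list of [qct_ring()]) and
#'   `cages` (list of [qct_cage()]).
#' @export
assemble_rings_and_cages <- function(graph, ring_surfaces, cps,
                                     rcp_ccp_links = NULL,
                                     bcp_rcp_links = NULL,
                                     capture_tol = 0.3) {
  ail_bcps <- vapply(graph$ails, function(a) a$bcp, integer(1))
  labels <- vapply(cps, function(cp) cp$label, character(1))
  rings <- list()
  for (rs in ring_surfaces) {
    reached <- sort(unique(unlist(lapply(rs$paths, .path_reached_cps,
                                         capture_tol = capture_tol))))
    reached <- reached[reached >= 1L]
    bcps <- reached[labels[reached] == "BCP"]
    terms <- vapply(rs$paths, function(p) p$cp_end, integer(1))
    terms <- terms[terms >= 1L]
    nacps <- unique(terms[labels[terms] == "NACP"])
    if (!is.null(bcp_rcp_links) && NROW(bcp_rcp_links) > 0) {
      bl <- as.data.frame(bcp_rcp_links)
      names(bl) <- c("bcp", "rcp")
      bcps_wide <- union(bcps, bl$bcp[bl$rcp == rs$rcp])
    } else bcps_wide <- bcps
    # the sector-terminal evidence is the most selective; widen to the
    # BCP-side evidence only when it does not close a cycle on its own
    cand_sets <- list(
      which(vapply(graph$ails, function(a) all(a$nacps %in% nacps),
                   logical(1))),
      which(ail_bcps %in% bcps_wide |
            vapply(graph$ails, function(a) all(a$nacps %in% nacps),
                   logical(1))))
    cyc <- NULL
    for (cand in cand_sets) {
      if (length(cand) < 3) next
      cyc <- .prune_to_cycle(graph$ails[cand])
      if (!is.null(cyc)) break
    }
    if (max(lengths(cand_sets)) < 3) {
      warning("ring paths of RCP ", rs$rcp,
              " reach fewer than 3 candidate AILs; ring omitted")
      next
    }
    if (is.null(cyc)) {
      warning("AILs reached from RCP ", rs$rcp, " do not close into a single cycle; ring omitted")
      next
    }
    rings[[length(rings) + 1]] <- qct_ring(cand[cyc], rs$rcp)
  }
  cages <- list()
  if (!is.null(rcp_ccp_links) && length(rings) > 0 && NROW(rcp_ccp_links) > 0) {
    links <- as.data.frame(rcp_ccp_links)
    names(links) <- c("rcp", "ccp")
    ring_rcps <- vapply(rings, function(r) r$rcp, integer(1))
    for (ccp in sort(unique(links$ccp))) {
      members <- which(ring_rcps %in% links$rcp[links$ccp == ccp])
      if (length(members) >= 2) {
        cages[[length(cages) + 1]] <- qct_cage(members, ccp)
      } else {
        warning("CCP ", ccp, " is linked to fewer than 2 rings; cage omitted")
      }
    }
  }
  list(rings = rings, cages = cages)
}

# Given a list of AILs, return the positions (within the list) of a subset
# forming one simple closed cycle over NACPs, or NULL. Pendant edges are
# removed iteratively; the survivor must be connected and 2-regular.
.prune_to_cycle <- function(ails) {
  if (length(ails) < 3) return(NULL)
  keep <- rep(TRUE, length(ails))
  repeat {
    ends <- unlist(lapply(ails[keep], function(a) a$nacps))
    deg <- table(ends)
    leaves <- as.integer(names(deg)[deg == 1])
    if (length(leaves) == 0) break
    drop <- which(keep & vapply(ails, function(a) any(a$nacps %in% leaves), logical(1)))
    if (length(drop) == 0) break
    keep[drop] <- FALSE
    if (sum(keep) < 3) return(NULL)
  }
  idx <- which(keep)
  ends <- unlist(lapply(ails[idx], function(a) a$nacps))
  deg <- table(ends)
  if (any(deg != 2)) return(NULL)
  # connectivity: walk the cycle
  nodes <- as.integer(names(deg))
  adj <- lapply(ails[idx], function(a) a$nacps)
  visited_edges <- logical(length(idx))
  cur <- nodes[1]
  for (step in seq_along(idx)) {
    nxt <- which(!visited_edges & vapply(adj, function(e) cur %in% e, logical(1)))[1]
    if (is.na(nxt)) return(NULL)
    visited_edges[nxt] <- TRUE
    e <- adj[[nxt]]
    cur <- if (e[1] == cur) e[2] else e[1]
  }
  if (!all(visited_edges) || cur != nodes[1]) return(NULL)
  idx
}

#' @export
print.qct_topology <- function(x, ...) {
  cen <- cp_census(x$critical_points)
  cat("QCT topology:", length(x$nuclei), "nuclei,",
      length(x$critical_points), "critical points\n")
  cat("  census:", paste(names(cen), cen, sep = "=", collapse = " "), "\n")
  cat("  Poincare-Hopf residual:",
      poincare_hopf_residual(cen["nacp"], cen["bcp"], cen["rcp"], cen["ccp"]), "\n")
  g <- x$gvf
  cat("  AILs:", length(g$molecular_graph$ails),
      " rings:", length(g$rings), " cages:", length(g$cages),
      " basins:", length(g$basins), " envelopes:", length(g$envelopes),
      " interatomic surfaces:", length(g$interatomic_surfaces), "\n")
  invisible(x)
}
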