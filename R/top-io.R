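#' @name top-io
#' @title Reading, writing and validating .top topology files
#'
#' @description
#' The `.top` format is an XML serialization of the [topology()] model,
#' defined by the DTD shipped at
#' `system.file("extdata", "Topology.dtd", package = "rhotop")`. Element
#' names follow the model's class names; all indices are 0-based in the
#' file (converted to/from the package's 1-based in-memory indices);
#' coordinates are bohr (the mandatory `unit` attribute must read
#' `"bohr"`); numbers carry 12 significant digits.
NULL

.fmt_num <- function(x) sprintf("%.12g", x)

.xml_pos <- function(parent, pos) {
  xml2::xml_add_child(parent, "PositionVector",
                      x = .fmt_num(pos[1]), y = .fmt_num(pos[2]),
                      z = .fmt_num(pos[3]))
}

.xml_point <- function(parent, pos, scalars = NULL) {
  pt <- xml2::xml_add_child(parent, "Point")
  .xml_pos(pt, pos)
  if (!is.null(scalars)) {
    for (nm in names(scalars)) {
      xml2::xml_add_child(pt, "Scalar", name = nm,
                          value = .fmt_num(scalars[[nm]]))
    }
  }
  pt
}

# file index (0-based, -1 sentinel preserved) from in-memory index
.to_file_idx <- function(i) ifelse(i == -1L, -1L, i - 1L)
.from_file_idx <- function(i) ifelse(i == -1L, -1L, i + 1L)

.xml_path_elem <- function(parent, gp) {
  attrs <- list(cp_start = as.character(.to_file_idx(gp$cp_start)),
                cp_end = as.character(.to_file_idx(gp$cp_end)))
  if (gp$cp_end == -1L) attrs$terminus <- "infinity"
  node <- do.call(xml2::xml_add_child, c(list(parent, "GradientPath"), attrs))
  scal <- gp$scalars
  for (i in seq_len(nrow(gp$points))) {
    s <- if (!is.null(scal)) as.list(scal[i, , drop = FALSE]) else NULL
    .xml_point(node, gp$points[i, ], s)
  }
  node
}

.xml_triangulation <- function(parent, tri) {
  node <- xml2::xml_add_child(parent, "Triangulation")
  for (i in seq_len(nrow(tri$vertices))) .xml_pos(node, tri$vertices[i, ])
  for (i in seq_len(nrow(tri$edges))) {
    xml2::xml_add_child(node, "Edge", a = as.character(tri$edges[i, 1] - 1L),
                        b = as.character(tri$edges[i, 2] - 1L))
  }
  for (i in seq_len(nrow(tri$faces))) {
    xml2::xml_add_child(node, "Face", a = as.character(tri$faces[i, 1] - 1L),
                        b = as.character(tri$faces[i, 2] - 1L),
                        c = as.character(tri$faces[i, 3] - 1L))
  }
  node
}

#' Write a topology to a .top XML file
#'
#' @param topology a [topology()] object.
#' @param destination output file path.
#' @return `destination`, invisibly.
#' @export
write_topology <- function(topology, destination) {
  ncp <- length(topology$critical_points)
  ref_ok <- function(i) all(i == -1L | (i >= 1L & i <= ncp))
  doc <- xml2::xml_new_root("Topology", unit = "bohr")
  src <- topology$source
  xml2::xml_add_child(doc, "SourceInformation",
                      qm_method = src$qm_method, basis_set = src$basis_set,
                      wavefunction_program = src$wavefunction_program,
                      qct_program = src$qct_program)
  for (nuc in topology$nuclei) {
    node <- xml2::xml_add_child(doc, "Nucleus",
                                index = as.character(nuc$index),
                                element = nuc$element)
    .xml_pos(node, nuc$position)
  }
  for (k in seq_len(ncp)) {
    cp <- topology$critical_points[[k]]
    node <- xml2::xml_add_child(doc, "CriticalPoint",
                                index = as.character(k - 1L),
                                rank = as.character(cp$rank),
                                signature = as.character(cp$signature),
                                label = cp$label)
    .xml_point(node, cp$position, as.list(cp$scalars))
    if (!is.null(cp$eigenvalues)) {
      xml2::xml_add_child(node, "Eigenvalues",
                          l1 = .fmt_num(cp$eigenvalues[1]),
                          l2 = .fmt_num(cp$eigenvalues[2]),
                          l3 = .fmt_num(cp$eigenvalues[3]))
    }
    if (!is.null(cp$eigenvectors)) {
      ev <- xml2::xml_add_child(node, "Eigenvectors")
      for (j in 1:3) .xml_pos(ev, cp$eigenvectors[, j])
    }
  }
  gvf <- topology$gvf
  gnode <- xml2::xml_add_child(doc, "GradientVectorField")
  mg <- xml2::xml_add_child(gnode, "MolecularGraph")
  for (a in gvf$molecular_graph$ails) {
    if (!ref_ok(c(a$bcp, a$nacps))) {
      stop("unresolvable critical-point reference in AtomicInteractionLine (BCP ",
           a$bcp, ")")
    }
    an <- xml2::xml_add_child(mg, "AtomicInteractionLine",
                              bcp = as.character(.to_file_idx(a$bcp)))
    for (p in a$paths) .xml_path_elem(an, p)
  }
  for (r in gvf$rings) {
    if (!ref_ok(r$rcp)) stop("unresolvable critical-point reference in Ring")
    rn <- xml2::xml_add_child(gnode, "Ring",
                              rcp = as.character(.to_file_idx(r$rcp)))
    for (i in r$ails) {
      xml2::xml_add_child(rn, "AtomicInteractionLineRef",
                          index = as.character(i - 1L))
    }
  }
  for (cg in gvf$cages) {
    if (!ref_ok(cg$ccp)) stop("unresolvable critical-point reference in Cage")
    cn <- xml2::xml_add_child(gnode, "Cage",
                              ccp = as.character(.to_file_idx(cg$ccp)))
    for (i in cg$rings) {
      xml2::xml_add_child(cn, "RingRef", index = as.character(i - 1L))
    }
  }
  for (rs in gvf$ring_surfaces) {
    if (!ref_ok(rs$rcp)) stop("unresolvable critical-point reference in RingSurface")
    rn <- xml2::xml_add_child(gnode, "RingSurface",
                              rcp = as.character(.to_file_idx(rs$rcp)))
    for (p in rs$paths) .xml_path_elem(rn, p)
  }
  for (b in gvf$basins) {
    if (!ref_ok(b$nacp)) stop("unresolvable critical-point reference in AtomicBasin")
    bn <- xml2::xml_add_child(gnode, "AtomicBasin",
                              nacp = as.character(.to_file_idx(b$nacp)))
    for (p in b$paths) .xml_path_elem(bn, p)
  }
  for (k in seq_along(gvf$interatomic_surfaces)) {
    s <- gvf$interatomic_surfaces[[k]]
    if (!ref_ok(s$bcp)) stop("unresolvable critical-point reference in InteratomicSurface")
    sn <- xml2::xml_add_child(gnode, "InteratomicSurface",
                              index = as.character(k - 1L),
                              bcp = as.character(.to_file_idx(s$bcp)))
    for (p in s$paths) .xml_path_elem(sn, p)
    if (!is.null(s$mesh)) .xml_triangulation(sn, s$mesh)
  }
  for (s in gvf$atomic_surfaces) {
    if (!ref_ok(s$nacp)) stop("unresolvable critical-point reference in AtomicSurface")
    sn <- xml2::xml_add_child(gnode, "AtomicSurface",
                              nacp = as.character(.to_file_idx(s$nacp)))
    for (i in s$interatomic_surfaces) {
      xml2::xml_add_child(sn, "InteratomicSurfaceRef",
                          index = as.character(i - 1L))
    }
  }
  for (e in gvf$envelopes) {
    if (!ref_ok(e$nacp)) stop("unresolvable critical-point reference in Envelope")
    en <- xml2::xml_add_child(gnode, "Envelope",
                              nacp = as.character(.to_file_idx(e$nacp)),
                              isovalue = .fmt_num(e$isovalue))
    .xml_triangulation(en, e$mesh)
  }
  txt <- as.character(doc)
  # insert the DOCTYPE referencing the shipped DTD after the declaration
  txt <- sub("\\?>\n", "?>\n<!DOCTYPE Topology SYSTEM \"Topology.dtd\">\n", txt)
  writeLines(txt, destination, useBytes = TRUE)
  invisible(destination)
}

#' Validate a .top file
#'
#' Checks well-formedness, conformity with the shipped document type
#' definition (element structure and required attributes) and model-level
#' constraints the DTD cannot express: resolution of every critical-point
#' reference, rank/signature legality, unit declaration, and AIL/ring
#' cardinalities.
#'
#' @param source path to a `.top` file.
#' @return an object of class `validation_report`: list with `valid`
#'   (logical; true iff no error-severity message) and `messages` (a
#'   data.frame with columns `severity`, `path`, `text`).
#' @export
validate_top <- function(source) {
  msgs <- list()
  add <- function(severity, path, text) {
    msgs[[length(msgs) + 1]] <<- data.frame(severity = severity, path = path,
                                            text = text)
  }
  doc <- tryCatch(xml2::read_xml(source),
                  error = function(e) {
                    add("error", "/", paste("XML parse failure:",
                                            conditionMessage(e)))
                    NULL
                  })
  if (!is.null(doc)) .validate_doc(doc, add)
  messages <- if (length(msgs) > 0) do.call(rbind, msgs) else
    data.frame(severity = character(0), path = character(0), text = character(0))
  structure(list(valid = !any(messages$severity == "error"),
                 messages = messages),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(if (x$valid) "VALID" else "INVALID", "topology document\n")
  for (i in seq_len(nrow(x$messages))) {
    m <- x$messages[i, ]
    cat(sprintf("  [%s] %s: %s\n", m$severity, m$path, m$text))
  }
  invisible(x)
}

.validate_doc <- function(doc, add) {
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "Topology") {
    add("error", xml2::xml_path(root), "root element must be Topology")
    return(invisible())
  }
  unit <- xml2::xml_attr(root, "unit")
  if (is.na(unit)) {
    add("error", xml2::xml_path(root), "missing mandatory unit attribute")
  } else if (unit != "bohr") {
    add("error", xml2::xml_path(root),
        paste0("unsupported unit '", unit, "': only bohr is accepted"))
  }
  num_attr <- function(node, attr, integer = FALSE) {
    v <- xml2::xml_attr(node, attr)
    if (is.na(v)) {
      add("error", xml2::xml_path(node),
          paste0("missing required attribute '", attr, "'"))
      return(NA_real_)
    }
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x) || (integer && x != round(x))) {
      add("error", xml2::xml_path(node),
          paste0("attribute '", attr, "' is not ",
                 if (integer) "an integer" else "numeric", ": ", v))
      return(NA_real_)
    }
    x
  }
  check_posvec <- function(node) {
    for (a in c("x", "y", "z")) num_attr(node, a)
  }
  for (pv in xml2::xml_find_all(doc, "//PositionVector")) check_posvec(pv)
  for (sc in xml2::xml_find_all(doc, "//Scalar")) {
    if (is.na(xml2::xml_attr(sc, "name"))) {
      add("error", xml2::xml_path(sc), "Scalar requires a name attribute")
    }
    num_attr(sc, "value")
  }
  for (pt in xml2::xml_find_all(doc, "//Point")) {
    if (length(xml2::xml_find_all(pt, "./PositionVector")) != 1) {
      add("error", xml2::xml_path(pt), "Point requires exactly one PositionVector")
    }
  }
  cps <- xml2::xml_find_all(doc, "/Topology/CriticalPoint")
  ncp <- length(cps)
  for (cp in cps) {
    rank <- num_attr(cp, "rank", integer = TRUE)
    sig <- num_attr(cp, "signature", integer = TRUE)
    if (!is.na(rank) && !is.na(sig)) {
      if (!(rank %in% 0:3)) {
        add("error", xml2::xml_path(cp), paste("rank out of range:", rank))
      } else if (abs(sig) > rank || (sig - rank) %% 2 != 0) {
        add("error", xml2::xml_path(cp),
            paste0("illegal rank/signature pair (", rank, ",", sig,
                   "): requires |sigma| <= omega and sigma == omega (mod 2)"))
      }
    }
    if (length(xml2::xml_find_all(cp, "./Point")) != 1) {
      add("error", xml2::xml_path(cp), "CriticalPoint requires exactly one Point")
    }
  }
  check_ref <- function(node, attr, n = ncp, allow_inf = FALSE) {
    i <- num_attr(node, attr, integer = TRUE)
    if (is.na(i)) return(invisible())
    if (allow_inf && i == -1) return(invisible())
    if (i < 0 || i >= n) {
      add("error", xml2::xml_path(node),
          paste0("reference '", attr, "'=", i, " does not resolve (", n,
                 " available)"))
    }
  }
  for (nuc in xml2::xml_find_all(doc, "/Topology/Nucleus")) {
    num_attr(nuc, "index", integer = TRUE)
    if (is.na(xml2::xml_attr(nuc, "element"))) {
      add("error", xml2::xml_path(nuc), "Nucleus requires an element attribute")
    }
  }
  for (gp in xml2::xml_find_all(doc, "//GradientPath")) {
    check_ref(gp, "cp_start", allow_inf = TRUE)
    check_ref(gp, "cp_end", allow_inf = TRUE)
    if (length(xml2::xml_find_all(gp, "./Point")) < 2) {
      add("error", xml2::xml_path(gp), "GradientPath requires at least 2 Points")
    }
  }
  gvf <- xml2::xml_find_all(doc, "/Topology/GradientVectorField")
  if (length(gvf) != 1) {
    add("error", xml2::xml_path(root),
        "Topology requires exactly one GradientVectorField")
    return(invisible())
  }
  nail <- length(xml2::xml_find_all(doc, "//AtomicInteractionLine"))
  for (a in xml2::xml_find_all(doc, "//AtomicInteractionLine")) {
    check_ref(a, "bcp")
    if (length(xml2::xml_find_all(a, "./GradientPath")) != 2) {
      add("error", xml2::xml_path(a),
          "AtomicInteractionLine requires exactly 2 GradientPaths")
    }
  }
  nring <- length(xml2::xml_find_all(doc, "//Ring"))
  for (r in xml2::xml_find_all(doc, "//Ring")) {
    check_ref(r, "rcp")
    refs <- xml2::xml_find_all(r, "./AtomicInteractionLineRef")
    if (length(refs) < 3) {
      add("error", xml2::xml_path(r), "Ring requires at least 3 AIL references")
    }
    for (rr in refs) check_ref(rr, "index", n = nail)
  }
  for (cg in xml2::xml_find_all(doc, "//Cage")) {
    check_ref(cg, "ccp")
    refs <- xml2::xml_find_all(cg, "./RingRef")
    if (length(refs) < 2) {
      add("error", xml2::xml_path(cg), "Cage requires at least 2 Ring references")
    }
    for (rr in refs) check_ref(rr, "index", n = nring)
  }
  for (rs in xml2::xml_find_all(doc, "//RingSurface")) check_ref(rs, "rcp")
  for (b in xml2::xml_find_all(doc, "//AtomicBasin")) check_ref(b, "nacp")
  nias <- length(xml2::xml_find_all(doc, "//InteratomicSurface"))
  for (s in xml2::xml_find_all(doc, "//InteratomicSurface")) check_ref(s, "bcp")
  for (s in xml2::xml_find_all(doc, "//AtomicSurface")) {
    check_ref(s, "nacp")
    for (rr in xml2::xml_find_all(s, "./InteratomicSurfaceRef")) {
      check_ref(rr, "index", n = nias)
    }
  }
  for (e in xml2::xml_find_all(doc, "//Envelope")) {
    check_ref(e, "nacp")
    iso <- num_attr(e, "isovalue")
    if (!is.na(iso) && iso <= 0) {
      add("error", xml2::xml_path(e), "Envelope isovalue must be > 0")
    }
    if (length(xml2::xml_find_all(e, "./Triangulation")) != 1) {
      add("error", xml2::xml_path(e), "Envelope requires a Triangulation")
    }
  }
  for (tri in xml2::xml_find_all(doc, "//Triangulation")) {
    nv <- length(xml2::xml_find_all(tri, "./PositionVector"))
    for (ed in xml2::xml_find_all(tri, "./Edge")) {
      for (a in c("a", "b")) check_ref(ed, a, n = nv)
    }
    for (fc in xml2::xml_find_all(tri, "./Face")) {
      for (a in c("a", "b", "c")) check_ref(fc, a, n = nv)
    }
  }
  invisible()
}

.parse_posvec <- function(node) {
  as.numeric(c(xml2::xml_attr(node, "x"), xml2::xml_attr(node, "y"),
               xml2::xml_attr(node, "z")))
}

.parse_point <- function(node) {
  pos <- .parse_posvec(xml2::xml_find_first(node, "./PositionVector"))
  scal <- xml2::xml_find_all(node, "./Scalar")
  values <- vapply(scal, function(s) as.numeric(xml2::xml_attr(s, "value")),
                   numeric(1))
  names(values) <- vapply(scal, function(s) xml2::xml_attr(s, "name"),
                          character(1))
  list(position = pos, scalars = values)
}

.parse_path <- function(node) {
  pts <- xml2::xml_find_all(node, "./Point")
  parsed <- lapply(pts, .parse_point)
  mat <- t(vapply(parsed, function(p) p$position, numeric(3)))
  nm <- unique(unlist(lapply(parsed, function(p) names(p$scalars))))
  scal <- NULL
  if (length(nm) > 0) {
    scal <- as.data.frame(lapply(nm, function(n) {
      vapply(parsed, function(p) {
        if (n %in% names(p$scalars)) p$scalars[[n]] else NA_real_
      }, numeric(1))
    }))
    names(scal) <- nm
  }
  gradient_path(mat,
                .from_file_idx(as.integer(xml2::xml_attr(node, "cp_start"))),
                .from_file_idx(as.integer(xml2::xml_attr(node, "cp_end"))),
                scalars = scal)
}

.parse_triangulation <- function(node) {
  verts <- t(vapply(xml2::xml_find_all(node, "./PositionVector"),
                    .parse_posvec, numeric(3)))
  edges <- xml2::xml_find_all(node, "./Edge")
  faces <- xml2::xml_find_all(node, "./Face")
  emat <- if (length(edges) > 0) {
    t(vapply(edges, function(e) as.integer(c(xml2::xml_attr(e, "a"),
                                             xml2::xml_attr(e, "b"))) + 1L,
             integer(2)))
  } else NULL
  fmat <- if (length(faces) > 0) {
    t(vapply(faces, function(f) as.integer(c(xml2::xml_attr(f, "a"),
                                             xml2::xml_attr(f, "b"),
                                             xml2::xml_attr(f, "c"))) + 1L,
             integer(3)))
  } else NULL
  triangulation(verts, edges = emat, faces = fmat)
}

#' Read a .top topology file
#'
#' The document is validated first; any error-severity finding aborts the
#' read. Scalar-function names form an open vocabulary: unknown names are
#' accepted as-is.
#'
#' @param source path to a `.top` file.
#' @param simple when `TRUE`, only critical points and the molecular graph
#'   are populated (rings, cages, basins, surfaces, ring surfaces and
#'   envelopes are dropped), mirroring a lightweight import.
#' @return a [topology()].
#' @export
read_topology <- function(source, simple = FALSE) {
  report <- validate_top(source)
  if (!report$valid) {
    bad <- report$messages[report$messages$severity == "error", ]
    stop("invalid .top document:\n",
         paste(sprintf("  %s: %s", bad$path, bad$text), collapse = "\n"))
  }
  doc <- xml2::read_xml(source)
  src_node <- xml2::xml_find_first(doc, "/Topology/SourceInformation")
  gattr <- function(node, a) {
    v <- xml2::xml_attr(node, a)
    if (is.na(v)) "" else v
  }
  src <- source_information(qm_method = gattr(src_node, "qm_method"),
                            basis_set = gattr(src_node, "basis_set"),
                            wavefunction_program = gattr(src_node, "wavefunction_program"),
                            qct_program = gattr(src_node, "qct_program"))
  nuclei <- lapply(xml2::xml_find_all(doc, "/Topology/Nucleus"), function(n) {
    nucleus(xml2::xml_attr(n, "element"),
            .parse_posvec(xml2::xml_find_first(n, "./PositionVector")),
            as.integer(xml2::xml_attr(n, "index")))
  })
  cps <- lapply(xml2::xml_find_all(doc, "/Topology/CriticalPoint"), function(n) {
    pt <- .parse_point(xml2::xml_find_first(n, "./Point"))
    evn <- xml2::xml_find_first(n, "./Eigenvalues")
    evals <- if (inherits(evn, "xml_missing")) NULL else {
      as.numeric(c(xml2::xml_attr(evn, "l1"), xml2::xml_attr(evn, "l2"),
                   xml2::xml_attr(evn, "l3")))
    }
    evc <- xml2::xml_find_first(n, "./Eigenvectors")
    evecs <- if (inherits(evc, "xml_missing")) NULL else {
      vapply(xml2::xml_find_all(evc, "./PositionVector"), .parse_posvec,
             numeric(3))
    }
    critical_point(pt$position,
                   rank = as.integer(xml2::xml_attr(n, "rank")),
                   signature = as.integer(xml2::xml_attr(n, "signature")),
                   label = xml2::xml_attr(n, "label"),
                   eigenvalues = evals, eigenvectors = evecs,
                   scalars = pt$scalars)
  })
  gnode <- xml2::xml_find_first(doc, "/Topology/GradientVectorField")
  ails <- lapply(xml2::xml_find_all(gnode, "./MolecularGraph/AtomicInteractionLine"),
                 function(n) {
    atomic_interaction_line(lapply(xml2::xml_find_all(n, "./GradientPath"),
                                   .parse_path),
                            .from_file_idx(as.integer(xml2::xml_attr(n, "bcp"))))
  })
  graph <- molecular_graph(ails)
  if (simple) {
    return(topology(source = src, nuclei = nuclei, critical_points = cps,
                    gvf = gradient_vector_field(molecular_graph = graph)))
  }
  rings <- lapply(xml2::xml_find_all(gnode, "./Ring"), function(n) {
    qct_ring(vapply(xml2::xml_find_all(n, "./AtomicInteractionLineRef"),
                    function(r) as.integer(xml2::xml_attr(r, "index")) + 1L,
                    integer(1)),
             .from_file_idx(as.integer(xml2::xml_attr(n, "rcp"))))
  })
  cages <- lapply(xml2::xml_find_all(gnode, "./Cage"), function(n) {
    qct_cage(vapply(xml2::xml_find_all(n, "./RingRef"),
                    function(r) as.integer(xml2::xml_attr(r, "index")) + 1L,
                    integer(1)),
             .from_file_idx(as.integer(xml2::xml_attr(n, "ccp"))))
  })
  ring_surfaces <- lapply(xml2::xml_find_all(gnode, "./RingSurface"), function(n) {
    ring_surface(.from_file_idx(as.integer(xml2::xml_attr(n, "rcp"))),
                 lapply(xml2::xml_find_all(n, "./GradientPath"), .parse_path))
  })
  basins <- lapply(xml2::xml_find_all(gnode, "./AtomicBasin"), function(n) {
    atomic_basin(.from_file_idx(as.integer(xml2::xml_attr(n, "nacp"))),
                 lapply(xml2::xml_find_all(n, "./GradientPath"), .parse_path))
  })
  ias <- lapply(xml2::xml_find_all(gnode, "./InteratomicSurface"), function(n) {
    trin <- xml2::xml_find_first(n, "./Triangulation")
    interatomic_surface(.from_file_idx(as.integer(xml2::xml_attr(n, "bcp"))),
                        lapply(xml2::xml_find_all(n, "./GradientPath"), .parse_path),
                        mesh = if (inherits(trin, "xml_missing")) NULL else
                          .parse_triangulation(trin))
  })
  asurf <- lapply(xml2::xml_find_all(gnode, "./AtomicSurface"), function(n) {
    atomic_surface(.from_file_idx(as.integer(xml2::xml_attr(n, "nacp"))),
                   vapply(xml2::xml_find_all(n, "./InteratomicSurfaceRef"),
                          function(r) as.integer(xml2::xml_attr(r, "index")) + 1L,
                          integer(1)))
  })
  envelopes <- lapply(xml2::xml_find_all(gnode, "./Envelope"), function(n) {
    envelope(.from_file_idx(as.integer(xml2::xml_attr(n, "nacp"))),
             as.numeric(xml2::xml_attr(n, "isovalue")),
             mesh = .parse_triangulation(xml2::xml_find_first(n, "./Triangulation")))
  })
  topology(source = src, nuclei = nuclei, critical_points = cps,
           gvf = gradient_vector_field(
             molecular_graph = graph, rings = rings, cages = cages,
             atomic_surfaces = asurf, ring_surfaces = ring_surfaces,
             basins = basins, envelopes = envelopes,
             interatomic_surfaces = ias))
}
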