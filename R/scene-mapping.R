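#' Construct a material
#'
#' Materials follow the renderer defaults used for topology figures: a
#' Lambert diffuse shader at intensity 1.0 and a white Cook–Torrance
#' specular shader at intensity 0.5.
#'
#' @param name material name.
#' @param diffuse_rgb length-3 numeric in `[0,1]`.
#' @param diffuse_intensity non-negative (default 1.0).
#' @param specular_rgb length-3 numeric (default white).
#' @param specular_intensity non-negative (default 0.5).
#' @param transparency in `[0,1]` (0 = opaque).
#' @return an object of class `material`.
#' @export
material <- function(name, diffuse_rgb, diffuse_intensity = 1.0,
                     specular_rgb = c(1, 1, 1), specular_intensity = 0.5,
                     transparency = 0) {
  stopifnot(length(diffuse_rgb) == 3, all(diffuse_rgb >= 0 & diffuse_rgb <= 1),
            diffuse_intensity >= 0, specular_intensity >= 0,
            transparency >= 0, transparency <= 1)
  structure(list(name = name, diffuse_rgb = as.numeric(diffuse_rgb),
                 diffuse_intensity = diffuse_intensity,
                 specular_rgb = as.numeric(specular_rgb),
                 specular_intensity = specular_intensity,
                 transparency = transparency,
                 diffuse_shader = "lambert",
                 specular_shader = "cook-torrance"),
            class = "material")
}

.scene_object <- function(kind, material, tag, ...) {
  structure(c(list(kind = kind, material = material, tag = tag), list(...)),
            class = "scene_object")
}

#' Default material set for a topology
#'
#' One nucleus material and one surface material (transparency 0.6) per
#' unique element present, in alphabetical element order, followed by the
#' fixed set: `bcp` (red), `rcp` (blue), `ccp` (green) and `ail` (black).
#' A magenta `degenerate-cp` material is appended only when degenerate
#' critical points are present. Elements missing from the bundled color
#' table fall back to gray with a warning.
#'
#' @param topology a [topology()].
#' @param surface_transparency alpha complement for element surface
#'   materials (default 0.6).
#' @return list of [material()] objects.
#' @export
default_materials <- function(topology, surface_transparency = 0.6) {
  elements <- sort(unique(vapply(topology$nuclei, function(n) n$element,
                                 character(1))))
  mats <- list()
  for (el in elements) {
    col <- .element_color(el)
    mats[[length(mats) + 1]] <- material(paste0(el, "-nucleus"), col)
    mats[[length(mats) + 1]] <- material(paste0(el, "-surface"), col,
                                         transparency = surface_transparency)
  }
  mats[[length(mats) + 1]] <- material("bcp", c(1, 0, 0))
  mats[[length(mats) + 1]] <- material("rcp", c(0, 0, 1))
  mats[[length(mats) + 1]] <- material("ccp", c(0, 1, 0))
  mats[[length(mats) + 1]] <- material("ail", c(0, 0, 0))
  labels <- vapply(topology$critical_points, function(cp) cp$label, character(1))
  if (any(labels == "degenerate")) {
    mats[[length(mats) + 1]] <- material("degenerate-cp", c(1, 0, 1))
  }
  mats
}

#' Style options for topology-to-scene mapping
#'
#' @param vdw_scale NACP sphere radius as a fraction of the element van
#'   der Waals radius (default 0.25).
#' @param cp_radius sphere radius for all non-NACP critical points, bohr
#'   (default 0.25).
#' @param ail_radius tube radius for AIL curves, bohr (default 0.1).
#' @param path_radius tube radius for basin/ring path curves, bohr
#'   (default 0.05).
#' @param uniform_ail when `TRUE` all AIL tubes use the single black
#'   `ail` material instead of per-element colors.
#' @param differentiate when `TRUE`, AILs classified non-bonded by
#'   [differentiate_interactions()] get `nonbonded_ratio` times the AIL
#'   tube radius.
#' @param bond_scale van der Waals sum scale for the bonded test
#'   (default 0.6).
#' @param nonbonded_ratio thin-tube ratio for non-bonded AILs
#'   (default 0.25).
#' @param show_rings,show_cages draw ring-surface / cage-linked path
#'   tubes (default off).
#' @param show_basins,show_surfaces,show_envelopes draw those components
#'   when present (default on).
#' @param surface_transparency passed to [default_materials()].
#' @param background_rgb scene background (default sky blue).
#' @param stereo,stereo_angle emit a stereoscopic camera pair with the
#'   given half-angle in degrees.
#' @return a named list of style options.
#' @export
scene_style <- function(vdw_scale = 0.25, cp_radius = 0.25, ail_radius = 0.1,
                        path_radius = 0.05, uniform_ail = FALSE,
                        differentiate = FALSE, bond_scale = 0.6,
                        nonbonded_ratio = 0.25,
                        show_rings = FALSE, show_cages = FALSE,
                        show_basins = TRUE, show_surfaces = TRUE,
                        show_envelopes = TRUE,
                        surface_transparency = 0.6,
                        background_rgb = c(0.53, 0.81, 0.92),
                        stereo = FALSE, stereo_angle = 2) {
  list(vdw_scale = vdw_scale, cp_radius = cp_radius, ail_radius = ail_radius,
       path_radius = path_radius, uniform_ail = uniform_ail,
       differentiate = differentiate, bond_scale = bond_scale,
       nonbonded_ratio = nonbonded_ratio, show_rings = show_rings,
       show_cages = show_cages, show_basins = show_basins,
       show_surfaces = show_surfaces, show_envelopes = show_envelopes,
       surface_transparency = surface_transparency,
       background_rgb = background_rgb, stereo = stereo,
       stereo_angle = stereo_angle)
}

# element of the nucleus a (3,-3) CP sits on
.nacp_element <- function(topology, cp_idx) {
  cp <- topology$critical_points[[cp_idx]]
  pos <- t(vapply(topology$nuclei, function(n) n$position, numeric(3)))
  d <- sqrt(rowSums(sweep(pos, 2, cp$position, `-`)^2))
  topology$nuclei[[which.min(d)]]$element
}

#' Map a topology onto a renderer-agnostic scene graph
#'
#' Canonical mapping: every critical point becomes a sphere — nuclear
#' attractors sized by a fraction of their element's van der Waals radius
#' and colored by element, all other CPs at one fixed radius colored by
#' signature (red/blue/green, magenta for degenerate points). Each of the
#' two gradient paths of an AIL becomes a smoothed tube curve colored by
#' the element of its attractor (or uniformly black with
#' `style$uniform_ail`). Basin and ring paths become thin tubes; surface
#' and envelope triangulations become meshes with the transparent element
#' surface material. Camera, three-point lighting and render settings are
#' constructed from the critical-point cloud via [compute_frame()].
#'
#' @param topology a [topology()].
#' @param style a [scene_style()] list.
#' @return an object of class `scene_graph` with fields `objects`,
#'   `materials`, `camera` (or `camera_left`/`camera_right` in stereo
#'   mode), `lights`, `render`, `background_rgb`.
#' @export
map_topology <- function(topology, style = scene_style()) {
  mats <- default_materials(topology, style$surface_transparency)
  objects <- list()
  cps <- topology$critical_points
  labels <- vapply(cps, function(cp) cp$label, character(1))
  for (k in seq_along(cps)) {
    cp <- cps[[k]]
    if (cp$label == "NACP") {
      el <- .nacp_element(topology, k)
      vdw <- .vdw_bohr(el)
      if (is.na(vdw)) vdw <- 1
      objects[[length(objects) + 1]] <- .scene_object(
        "sphere", paste0(el, "-nucleus"), sprintf("cp:%d", k),
        center = cp$position, radius = style$vdw_scale * vdw)
    } else {
      mat <- switch(cp$label, BCP = "bcp", RCP = "rcp", CCP = "ccp",
                    degenerate = "degenerate-cp")
      objects[[length(objects) + 1]] <- .scene_object(
        "sphere", mat, sprintf("cp:%d", k),
        center = cp$position, radius = style$cp_radius)
    }
  }
  graph <- topology$gvf$molecular_graph
  nonbonded <- integer(0)
  if (style$differentiate && length(graph$ails) > 0) {
    part <- differentiate_interactions(graph, topology$nuclei,
                                       scale = style$bond_scale,
                                       topology = topology)
    nonbonded <- part$nonbonded
  }
  for (i in seq_along(graph$ails)) {
    a <- graph$ails[[i]]
    radius <- style$ail_radius *
      if (i %in% nonbonded) style$nonbonded_ratio else 1
    for (p in a$paths) {
      matname <- if (style$uniform_ail) "ail" else {
        far <- if (labels[p$cp_start] == "NACP") p$cp_start else p$cp_end
        paste0(.nacp_element(topology, far), "-nucleus")
      }
      objects[[length(objects) + 1]] <- .scene_object(
        "curve", matname, sprintf("ail:%d", i),
        points = smooth_path(p$points), radius = radius)
    }
  }
  if (style$show_rings) {
    for (rs in topology$gvf$ring_surfaces) {
      for (p in rs$paths) {
        objects[[length(objects) + 1]] <- .scene_object(
          "curve", "rcp", sprintf("ringpath:%d", rs$rcp),
          points = smooth_path(p$points), radius = style$path_radius)
      }
    }
  }
  if (style$show_basins) {
    for (b in topology$gvf$basins) {
      el <- .nacp_element(topology, b$nacp)
      for (p in b$paths) {
        objects[[length(objects) + 1]] <- .scene_object(
          "curve", paste0(el, "-nucleus"), sprintf("basin:%d", b$nacp),
          points = smooth_path(p$points), radius = style$path_radius)
      }
    }
  }
  if (style$show_surfaces) {
    ias_owner <- rep(NA_character_, length(topology$gvf$interatomic_surfaces))
    for (s in topology$gvf$atomic_surfaces) {
      el <- .nacp_element(topology, s$nacp)
      for (i in s$interatomic_surfaces) {
        if (is.na(ias_owner[i])) ias_owner[i] <- el
      }
    }
    for (i in seq_along(topology$gvf$interatomic_surfaces)) {
      s <- topology$gvf$interatomic_surfaces[[i]]
      if (is.null(s$mesh)) next
      el <- ias_owner[i]
      matname <- if (is.na(el)) "ail" else paste0(el, "-surface")
      objects[[length(objects) + 1]] <- .scene_object(
        "mesh", matname, sprintf("ias:%d", i), mesh = s$mesh)
    }
  }
  if (style$show_envelopes) {
    for (i in seq_along(topology$gvf$envelopes)) {
      e <- topology$gvf$envelopes[[i]]
      el <- .nacp_element(topology, e$nacp)
      objects[[length(objects) + 1]] <- .scene_object(
        "mesh", paste0(el, "-surface"), sprintf("envelope:%d", e$nacp),
        mesh = e$mesh)
    }
  }
  frame <- if (length(cps) > 0) compute_frame(cps) else
    scene_frame(c(0, 0, 0), 1)
  camera <- place_camera(frame)
  scene <- structure(list(objects = objects, materials = mats,
                          camera = camera,
                          lights = place_lights(frame, camera),
                          render = default_render_settings(),
                          background_rgb = style$background_rgb,
                          frame = frame),
                     class = "scene_graph")
  if (isTRUE(style$stereo)) {
    pair <- make_stereo_pair(camera, frame, style$stereo_angle)
    scene$camera_left <- pair$left
    scene$camera_right <- pair$right
  }
  scene
}

#' Smooth a polyline into sampled cubic Bézier segments
#'
#' Converts a polyline to a chain of cubic Bézier segments using
#' Catmull–Rom tangents (tension 0.5); the input points are interpolated
#' exactly, and each segment is sampled back at 8 points for export
#' tessellation. Duplicate consecutive input points are removed first.
#'
#' @param points n x 3 matrix, n >= 2 after deduplication.
#' @param samples_per_segment sample count per Bézier segment (default 8).
#' @return an m x 3 matrix of sampled curve points with exact endpoints.
#' @export
smooth_path <- function(points, samples_per_segment = 8) {
  points <- as.matrix(points)
  if (nrow(points) >= 2) {
    seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
    points <- points[c(TRUE, seg > 1e-12), , drop = FALSE]
  }
  n <- nrow(points)
  if (n < 2) stop("smooth_path needs at least 2 distinct points")
  tension <- 0.5
  tang <- matrix(0, n, 3)
  tang[1, ] <- 2 * tension * (points[2, ] - points[1, ])
  tang[n, ] <- 2 * tension * (points[n, ] - points[n - 1, ])
  if (n > 2) {
    tang[2:(n - 1), ] <- tension * (points[3:n, , drop = FALSE] -
                                    points[1:(n - 2), , drop = FALSE])
  }
  out <- list()
  ts <- seq_len(samples_per_segment - 1) / samples_per_segment
  for (i in seq_len(n - 1)) {
    p0 <- points[i, ]; p1 <- points[i + 1, ]
    b1 <- p0 + tang[i, ] / 3
    b2 <- p1 - tang[i + 1, ] / 3
    out[[length(out) + 1]] <- p0
    for (t in ts) {
      out[[length(out) + 1]] <-
        (1 - t)^3 * p0 + 3 * (1 - t)^2 * t * b1 +
        3 * (1 - t) * t^2 * b2 + t^3 * p1
    }
  }
  out[[length(out) + 1]] <- points[n, ]
  do.call(rbind, out)
}

#' Partition the AILs of a molecular graph into bonded and non-bonded
#'
#' An AIL counts as a bond when the distance between its two nuclei does
#' not exceed `scale` times the sum of their van der Waals radii; longer
#' interactions (hydrogen bonds, H–H contacts) are classified non-bonded
#' and typically drawn with thinner tubes.
#'
#' @param graph a [molecular_graph()].
#' @param nuclei list of [nucleus()] objects.
#' @param scale van der Waals sum scale (default 0.6).
#' @param topology optional [topology()] providing the NACP positions
#'   (otherwise the AIL path endpoints are used directly).
#' @return list with integer index vectors `bonded` and `nonbonded`.
#' @export
differentiate_interactions <- function(graph, nuclei, scale = 0.6,
                                       topology = NULL) {
  npos <- t(vapply(nuclei, function(n) n$position, numeric(3)))
  elems <- vapply(nuclei, function(n) n$element, character(1))
  bonded <- integer(0); nonbonded <- integer(0)
  endpoint_pos <- function(a, which_end) {
    if (!is.null(topology)) {
      return(topology$critical_points[[a$nacps[which_end]]]$position)
    }
    # fall back to the far terminal point of the corresponding path
    p <- a$paths[[which_end]]
    if (p$cp_start == a$bcp) p$points[nrow(p$points), ] else p$points[1, ]
  }
  for (i in seq_along(graph$ails)) {
    a <- graph$ails[[i]]
    p1 <- endpoint_pos(a, 1); p2 <- endpoint_pos(a, 2)
    n1 <- which.min(rowSums(sweep(npos, 2, p1, `-`)^2))
    n2 <- which.min(rowSums(sweep(npos, 2, p2, `-`)^2))
    d <- sqrt(sum((npos[n1, ] - npos[n2, ])^2))
    cutoff <- scale * (.vdw_bohr(elems[n1]) + .vdw_bohr(elems[n2]))
    if (!is.na(cutoff) && d <= cutoff) bonded <- c(bonded, i)
    else nonbonded <- c(nonbonded, i)
  }
  list(bonded = bonded, nonbonded = nonbonded)
}

#' Rescale all AIL tube radii in a scene
#'
#' @param scene a `scene_graph`.
#' @param factor positive multiplier applied to every AIL curve radius;
#'   other objects are untouched.
#' @return the modified scene.
#' @export
resize_ails <- function(scene, factor) {
  if (!is.numeric(factor) || factor <= 0) stop("factor must be > 0")
  scene$objects <- lapply(scene$objects, function(o) {
    if (o$kind == "curve" && startsWith(o$tag, "ail:")) {
      o$radius <- o$radius * factor
    }
    o
  })
  scene
}

#' @export
print.scene_graph <- function(x, ...) {
  kinds <- vapply(x$objects, function(o) o$kind, character(1))
  cat("scene graph:", length(x$objects), "objects (",
      sum(kinds == "sphere"), "spheres,", sum(kinds == "curve"), "curves,",
      sum(kinds == "mesh"), "meshes ),", length(x$materials), "materials\n")
  invisible(x)
}
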