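#' @name scene-export
#' @title Scene serialization and mesh export
#'
#' @description
#' Scenes export to a canonical deterministic JSON (scene-model units,
#' bohr) for testing and interchange, and to standard mesh formats —
#' OBJ+MTL, binary little-endian PLY with per-vertex color, and glTF 2.0
#' with embedded buffers — for rendering in external tools. Mesh exports
#' are converted to ångström (3D tools assume human-scale units) and use
#' a right-handed, +y-up convention.
NULL

# recursively order list keys and round numbers to 12 significant digits
.canonical <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- unclass(x)
    if (!is.null(names(x))) x <- x[order(names(x))]
    return(lapply(x, .canonical))
  }
  if (is.matrix(x)) {
    return(lapply(seq_len(nrow(x)), function(i) signif(unname(x[i, ]), 12)))
  }
  if (is.numeric(x)) return(signif(unname(x), 12))
  x
}

.scene_to_list <- function(scene) {
  objs <- lapply(scene$objects, function(o) {
    out <- list(kind = o$kind, material = o$material, tag = o$tag)
    if (o$kind == "sphere") {
      out$center <- o$center; out$radius <- o$radius
    } else if (o$kind == "curve") {
      out$points <- o$points; out$radius <- o$radius
    } else {
      out$vertices <- o$mesh$vertices
      out$faces <- o$mesh$faces - 1L   # 0-based in the JSON
    }
    out
  })
  cams <- if (!is.null(scene$camera_left)) {
    list(camera_left = unclass(scene$camera_left),
         camera_right = unclass(scene$camera_right))
  } else list(camera = unclass(scene$camera))
  c(list(objects = objs,
         materials = lapply(scene$materials, unclass),
         lights = lapply(scene$lights, unclass),
         render = unclass(scene$render),
         background_rgb = scene$background_rgb,
         units = "bohr"),
    cams)
}

#' Export a scene as canonical JSON
#'
#' Deterministic serialization: keys sorted, numbers at 12 significant
#' digits, so identical scenes produce byte-identical files.
#'
#' @param scene a `scene_graph` from [map_topology()].
#' @param destination output file path.
#' @return `destination`, invisibly.
#' @export
export_scene_json <- function(scene, destination) {
  lst <- .canonical(.scene_to_list(scene))
  json <- jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, destination, useBytes = TRUE)
  invisible(destination)
}

#' Tessellate a UV sphere
#'
#' `nu` longitudinal segments by `nv` latitudinal bands gives
#' `nu * (nv - 1) + 2` vertices (two poles plus `nv - 1` rings).
#'
#' @param center,radius sphere parameters.
#' @param nu,nv tessellation (defaults 32 x 16).
#' @return a [triangulation()].
#' @export
uv_sphere_mesh <- function(center, radius, nu = 32, nv = 16) {
  verts <- matrix(0, nu * (nv - 1) + 2, 3)
  verts[1, ] <- center + c(0, radius, 0)          # north pole (+y up)
  for (j in seq_len(nv - 1)) {
    phi <- pi * j / nv
    for (i in seq_len(nu)) {
      th <- 2 * pi * (i - 1) / nu
      verts[1 + (j - 1) * nu + i, ] <- center + radius *
        c(sin(phi) * cos(th), cos(phi), sin(phi) * sin(th))
    }
  }
  south <- nu * (nv - 1) + 2
  verts[south, ] <- center - c(0, radius, 0)
  ring <- function(j, i) 1 + (j - 1) * nu + ((i - 1) %% nu) + 1
  faces <- list()
  for (i in seq_len(nu)) {
    faces[[length(faces) + 1]] <- c(1, ring(1, i + 1), ring(1, i))
    faces[[length(faces) + 1]] <- c(south, ring(nv - 1, i), ring(nv - 1, i + 1))
  }
  for (j in seq_len(nv - 2)) {
    for (i in seq_len(nu)) {
      a <- ring(j, i); b <- ring(j, i + 1); cc <- ring(j + 1, i); d <- ring(j + 1, i + 1)
      faces[[length(faces) + 1]] <- c(a, b, cc)
      faces[[length(faces) + 1]] <- c(b, d, cc)
    }
  }
  triangulation(verts, faces = do.call(rbind, faces))
}

#' Tessellate a polyline as a capped tube
#'
#' Rings of `sides` vertices are laid along the curve with
#' parallel-transported frames; two cap-center vertices close the ends,
#' giving `n * sides + 2` vertices for an n-point curve.
#'
#' @param points n x 3 curve points.
#' @param radius tube radius.
#' @param sides ring vertex count (default 12).
#' @return a [triangulation()].
#' @export
tube_mesh <- function(points, radius, sides = 12) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2) stop("tube_mesh needs at least 2 points")
  tangents <- matrix(0, n, 3)
  tangents[1, ] <- points[2, ] - points[1, ]
  tangents[n, ] <- points[n, ] - points[n - 1, ]
  if (n > 2) tangents[2:(n - 1), ] <- points[3:n, , drop = FALSE] -
    points[1:(n - 2), , drop = FALSE]
  tangents <- tangents / sqrt(rowSums(tangents^2))
  # initial normal: any direction orthogonal to the first tangent
  t1 <- tangents[1, ]
  ref <- if (abs(t1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  normal <- .cross3(t1, ref); normal <- normal / sqrt(sum(normal^2))
  verts <- matrix(0, n * sides + 2, 3)
  for (k in seq_len(n)) {
    tk <- tangents[k, ]
    normal <- normal - sum(normal * tk) * tk      # parallel transport
    nn <- sqrt(sum(normal^2))
    if (nn < 1e-12) {
      ref <- if (abs(tk[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      normal <- .cross3(tk, ref); nn <- sqrt(sum(normal^2))
    }
    normal <- normal / nn
    binorm <- .cross3(tk, normal)
    for (i in seq_len(sides)) {
      a <- 2 * pi * (i - 1) / sides
      verts[(k - 1) * sides + i, ] <- points[k, ] +
        radius * (cos(a) * normal + sin(a) * binorm)
    }
  }
  cap0 <- n * sides + 1; cap1 <- n * sides + 2
  verts[cap0, ] <- points[1, ]
  verts[cap1, ] <- points[n, ]
  at <- function(k, i) (k - 1) * sides + ((i - 1) %% sides) + 1
  faces <- list()
  for (k in seq_len(n - 1)) {
    for (i in seq_len(sides)) {
      a <- at(k, i); b <- at(k, i + 1); cc <- at(k + 1, i); d <- at(k + 1, i + 1)
      faces[[length(faces) + 1]] <- c(a, b, cc)
      faces[[length(faces) + 1]] <- c(b, d, cc)
    }
  }
  for (i in seq_len(sides)) {
    faces[[length(faces) + 1]] <- c(cap0, at(1, i), at(1, i + 1))
    faces[[length(faces) + 1]] <- c(cap1, at(n, i + 1), at(n, i))
  }
  triangulation(verts, faces = do.call(rbind, faces))
}

# tessellate every scene object into (vertices-in-angstrom, faces,
# material) triples
.tessellate_scene <- function(scene, sphere_nu = 32, sphere_nv = 16,
                              tube_sides = 12) {
  lapply(seq_along(scene$objects), function(i) {
    o <- scene$objects[[i]]
    mesh <- switch(o$kind,
      sphere = uv_sphere_mesh(o$center, o$radius, sphere_nu, sphere_nv),
      curve = tube_mesh(o$points, o$radius, tube_sides),
      mesh = o$mesh)
    list(name = sprintf("%s_%03d", gsub("[^A-Za-z0-9]", "_", o$tag), i),
         vertices = bohr_to_angstrom(mesh$vertices),
         faces = mesh$faces, material = o$material)
  })
}

.scene_material <- function(scene, name) {
  for (m in scene$materials) if (m$name == name) return(m)
  material(name, c(0.5, 0.5, 0.5))
}

#' Export a scene to a standard mesh format
#'
#' Spheres are tessellated as 32 x 16 UV spheres, curves as 12-sided
#' capped tubes, triangulations passed through; all coordinates are
#' converted to ångström. `"obj"` writes a companion `.mtl` with diffuse
#' color and dissolve; `"ply"` writes binary little-endian with
#' per-vertex color; `"gltf"` writes glTF 2.0 with embedded buffers and
#' PBR-approximated materials (roughness = 1 − 0.5 × specular intensity).
#'
#' @param scene a `scene_graph`.
#' @param format one of `"obj"`, `"ply"`, `"gltf"`.
#' @param destination output path.
#' @param sphere_nu,sphere_nv,tube_sides tessellation options.
#' @return `destination`, invisibly.
#' @export
export_mesh_scene <- function(scene, format = c("obj", "ply", "gltf"),
                              destination, sphere_nu = 32, sphere_nv = 16,
                              tube_sides = 12) {
  format <- match.arg(format)
  parts <- .tessellate_scene(scene, sphere_nu, sphere_nv, tube_sides)
  switch(format,
         obj = .export_obj(scene, parts, destination),
         ply = .export_ply(scene, parts, destination),
         gltf = .export_gltf(scene, parts, destination))
  invisible(destination)
}

.export_obj <- function(scene, parts, destination) {
  mtl_path <- sub("\\.obj$", ".mtl", destination)
  if (identical(mtl_path, destination)) mtl_path <- paste0(destination, ".mtl")
  mtl <- character(0)
  for (m in scene$materials) {
    mtl <- c(mtl,
             paste("newmtl", m$name),
             paste("Kd", paste(.fmt_num(m$diffuse_rgb * m$diffuse_intensity),
                               collapse = " ")),
             paste("Ks", paste(.fmt_num(m$specular_rgb * m$specular_intensity),
                               collapse = " ")),
             paste("d", .fmt_num(1 - m$transparency)),
             "illum 2", "")
  }
  writeLines(mtl, mtl_path, useBytes = TRUE)
  con <- file(destination, "w")
  on.exit(close(con))
  writeLines(paste("mtllib", basename(mtl_path)), con)
  offset <- 0L
  for (p in parts) {
    writeLines(paste("o", p$name), con)
    writeLines(paste("usemtl", p$material), con)
    writeLines(sprintf("v %s %s %s", .fmt_num(p$vertices[, 1]),
                       .fmt_num(p$vertices[, 2]), .fmt_num(p$vertices[, 3])),
               con)
    writeLines(sprintf("f %d %d %d", p$faces[, 1] + offset,
                       p$faces[, 2] + offset, p$faces[, 3] + offset), con)
    offset <- offset + nrow(p$vertices)
  }
}

.export_ply <- function(scene, parts, destination) {
  nv <- sum(vapply(parts, function(p) nrow(p$vertices), integer(1)))
  nf <- sum(vapply(parts, function(p) nrow(p$faces), integer(1)))
  header <- c("ply", "format binary_little_endian 1.0",
              "comment rhotop scene export (angstrom, y-up)",
              paste("element vertex", nv),
              "property float x", "property float y", "property float z",
              "property uchar red", "property uchar green", "property uchar blue",
              paste("element face", nf),
              "property list uchar int vertex_indices", "end_header")
  con <- file(destination, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
  for (p in parts) {
    m <- .scene_material(scene, p$material)
    col <- as.integer(round(pmin(1, m$diffuse_rgb * m$diffuse_intensity) * 255))
    for (i in seq_len(nrow(p$vertices))) {
      writeBin(as.numeric(p$vertices[i, ]), con, size = 4, endian = "little")
      writeBin(as.raw(col), con)
    }
  }
  offset <- 0L
  for (p in parts) {
    for (i in seq_len(nrow(p$faces))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(p$faces[i, ] - 1L + offset), con, size = 4,
               endian = "little")
    }
    offset <- offset + nrow(p$vertices)
  }
}

.export_gltf <- function(scene, parts, destination) {
  mat_names <- vapply(scene$materials, function(m) m$name, character(1))
  gmats <- lapply(scene$materials, function(m) {
    out <- list(name = m$name,
                pbrMetallicRoughness = list(
                  baseColorFactor = c(pmin(1, m$diffuse_rgb * m$diffuse_intensity),
                                      1 - m$transparency),
                  metallicFactor = 0,
                  roughnessFactor = 1 - 0.5 * m$specular_intensity))
    if (m$transparency > 0) out$alphaMode <- "BLEND"
    out
  })
  buf <- raw(0)
  views <- list(); accessors <- list(); meshes <- list(); nodes <- list()
  for (k in seq_along(parts)) {
    p <- parts[[k]]
    pos <- t(p$vertices)                       # column-major -> xyz triples
    pos_raw <- writeBin(as.numeric(pos), raw(), size = 4, endian = "little")
    idx <- as.integer(t(p$faces - 1L))
    idx_raw <- writeBin(idx, raw(), size = 4, endian = "little")
    views[[length(views) + 1]] <- list(buffer = 0, byteOffset = length(buf),
                                       byteLength = length(pos_raw),
                                       target = 34962)
    buf <- c(buf, pos_raw)
    accessors[[length(accessors) + 1]] <- list(
      bufferView = length(views) - 1, componentType = 5126,
      count = nrow(p$vertices), type = "VEC3",
      min = apply(p$vertices, 2, min), max = apply(p$vertices, 2, max))
    views[[length(views) + 1]] <- list(buffer = 0, byteOffset = length(buf),
                                       byteLength = length(idx_raw),
                                       target = 34963)
    buf <- c(buf, idx_raw)
    accessors[[length(accessors) + 1]] <- list(
      bufferView = length(views) - 1, componentType = 5125,
      count = length(idx), type = "SCALAR")
    meshes[[length(meshes) + 1]] <- list(
      name = p$name,
      primitives = list(list(
        attributes = list(POSITION = 2 * (k - 1)),
        indices = 2 * (k - 1) + 1,
        material = match(p$material, mat_names) - 1)))
    nodes[[length(nodes) + 1]] <- list(mesh = k - 1, name = p$name)
  }
  b64 <- gsub("[\r\n]", "", jsonlite::base64_enc(buf))
  doc <- list(
    asset = list(version = "2.0", generator = "rhotop"),
    scene = 0,
    scenes = list(list(nodes = if (length(nodes) > 0)
      as.list(seq_along(nodes) - 1) else list())),
    nodes = nodes, meshes = meshes, materials = gmats,
    accessors = accessors, bufferViews = views,
    buffers = list(list(
      byteLength = length(buf),
      uri = paste0("data:application/octet-stream;base64,", b64))))
  if (length(nodes) == 0) {
    doc$nodes <- NULL; doc$meshes <- NULL; doc$accessors <- NULL
    doc$bufferViews <- NULL; doc$buffers <- NULL
  }
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA),
             destination, useBytes = TRUE)
}

#' Emit a builder script recreating the scene in a 3D authoring tool
#'
#' Writes a standalone Python-dialect script (Blender-style API calls)
#' that recreates the scene's materials (Lambert/Cook–Torrance settings),
#' objects, camera, three-point lighting and render settings. The script
#' is plain text and is never executed by this package.
#'
#' @param scene a `scene_graph`.
#' @param destination output path.
#' @return `destination`, invisibly.
#' @export
emit_builder_script <- function(scene, destination) {
  fmt_vec <- function(v) paste0("(", paste(.fmt_num(v), collapse = ", "), ")")
  lines <- c("# scene builder script generated by rhotop",
             "# recreates materials, objects, camera, lights and render settings",
             "import bpy", "", "# --- materials ---")
  for (m in scene$materials) {
    lines <- c(lines, sprintf(
      "make_material(%s, diffuse=%s, diffuse_intensity=%s, specular=%s, specular_intensity=%s, alpha=%s, diffuse_shader='LAMBERT', specular_shader='COOKTORR')",
      shQuote(m$name), fmt_vec(m$diffuse_rgb), .fmt_num(m$diffuse_intensity),
      fmt_vec(m$specular_rgb), .fmt_num(m$specular_intensity),
      .fmt_num(1 - m$transparency)))
  }
  lines <- c(lines, "", "# --- objects ---")
  for (o in scene$objects) {
    lines <- c(lines, switch(o$kind,
      sphere = sprintf("add_sphere(center=%s, radius=%s, material=%s)  # %s",
                       fmt_vec(o$center), .fmt_num(o$radius),
                       shQuote(o$material), o$tag),
      curve = sprintf("add_curve(points=%s, bevel_radius=%s, material=%s)  # %s",
                      paste0("[", paste(apply(o$points, 1, fmt_vec),
                                        collapse = ", "), "]"),
                      .fmt_num(o$radius), shQuote(o$material), o$tag),
      mesh = sprintf("add_mesh(vertices=%s, faces=%s, material=%s)  # %s",
                     paste0("[", paste(apply(o$mesh$vertices, 1, fmt_vec),
                                       collapse = ", "), "]"),
                     paste0("[", paste(apply(o$mesh$faces - 1L, 1, function(f)
                       fmt_vec(as.numeric(f))), collapse = ", "), "]"),
                     shQuote(o$material), o$tag)))
  }
  cam <- if (!is.null(scene$camera_left)) scene$camera_left else scene$camera
  lines <- c(lines, "", "# --- camera and lights ---",
             sprintf("add_camera(position=%s, look_at=%s, up=%s, fov_degrees=%s)",
                     fmt_vec(cam$position), fmt_vec(cam$look_at),
                     fmt_vec(cam$up), .fmt_num(cam$fov_degrees)))
  for (nm in names(scene$lights)) {
    l <- scene$lights[[nm]]
    lines <- c(lines, if (l$kind == "spot") {
      sprintf("add_spot(%s, position=%s, aim=%s, energy=%s)",
              shQuote(nm), fmt_vec(l$position), fmt_vec(l$aim),
              .fmt_num(l$energy))
    } else {
      sprintf("add_lamp(%s, position=%s, energy=%s)",
              shQuote(nm), fmt_vec(l$position), .fmt_num(l$energy))
    })
  }
  r <- scene$render
  lines <- c(lines, "", "# --- render settings ---",
             sprintf("set_render(width=%d, height=%d, antialias_samples=%d, raytrace_samples=%d, format='%s', color_depth_bits=%d, compression=%s, background=%s)",
                     r$width, r$height, r$antialias_samples,
                     r$raytrace_samples, toupper(r$output_format),
                     r$color_depth_bits,
                     if (r$compression) "True" else "False",
                     fmt_vec(scene$background_rgb)))
  writeLines(lines, destination, useBytes = TRUE)
  invisible(destination)
}
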