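#' Scene frame: center and extent of a critical-point cloud
#'
#' @param center numeric length-3 (bohr).
#' @param extent positive radius (bohr) such that all critical points lie
#'   within it.
#' @return an object of class `scene_frame`.
#' @export
scene_frame <- function(center, extent) {
  if (!is.numeric(extent) || extent <= 0) stop("extent must be > 0")
  structure(list(center = .check_pos3(center), extent = as.numeric(extent)),
            class = "scene_frame")
}

#' Compute the scene frame from critical points
#'
#' Center is the arithmetic mean of all critical-point positions; extent
#' is the radius of the smallest center-placed sphere encompassing them,
#' floored at 1 bohr for single-point (or coincident) systems.
#'
#' @param cps non-empty list of [critical_point()] objects.
#' @return a [scene_frame()].
#' @export
compute_frame <- function(cps) {
  if (length(cps) == 0) stop("compute_frame requires at least one critical point")
  pos <- t(vapply(cps, function(cp) cp$position, numeric(3)))
  center <- colMeans(pos)
  extent <- sqrt(max(rowSums(sweep(pos, 2, center, `-`)^2)))
  if (extent < 1e-12) extent <- 1
  scene_frame(center, extent)
}

#' Construct a camera
#' @param position,look_at distinct positions (bohr).
#' @param up unit up vector (default +y).
#' @param fov_degrees vertical field of view (default 49.1).
#' @return an object of class `camera`.
#' @export
camera <- function(position, look_at, up = c(0, 1, 0), fov_degrees = 49.1) {
  position <- .check_pos3(position); look_at <- .check_pos3(look_at)
  if (sqrt(sum((position - look_at)^2)) < 1e-12) {
    stop("camera position must differ from its look-at point")
  }
  up <- .check_pos3(up); up <- up / sqrt(sum(up^2))
  structure(list(position = position, look_at = look_at, up = up,
                 fov_degrees = as.numeric(fov_degrees)),
            class = "camera")
}

#' Place the default camera for a scene frame
#'
#' The camera sits at `center + (0, 0, -4 r)` — four extents behind the
#' system along z — and is oriented to look at the system center with +y
#' up.
#'
#' @param frame a [scene_frame()].
#' @return a [camera()].
#' @export
place_camera <- function(frame) {
  camera(position = frame$center + c(0, 0, -4 * frame$extent),
         look_at = frame$center)
}

#' Construct a light
#' @param kind `"spot"` (directional, requires `aim`) or `"lamp"`
#'   (non-directional).
#' @param position light position (bohr).
#' @param energy positive intensity.
#' @param aim aim point for spots (must differ from `position`).
#' @param color_rgb light color (default white).
#' @return an object of class `light`.
#' @export
light_source <- function(kind = c("spot", "lamp"), position, energy,
                         aim = NULL, color_rgb = c(1, 1, 1)) {
  kind <- match.arg(kind)
  position <- .check_pos3(position)
  if (!is.numeric(energy) || energy <= 0) stop("light energy must be > 0")
  if (kind == "spot") {
    if (is.null(aim)) stop("spot lights require an aim point")
    aim <- .check_pos3(aim)
    if (sqrt(sum((aim - position)^2)) < 1e-12) {
      stop("spot aim must differ from its position")
    }
  } else {
    aim <- NULL
  }
  structure(list(kind = kind, position = position, aim = aim,
                 energy = as.numeric(energy),
                 color_rgb = as.numeric(color_rgb)),
            class = "light")
}

# rotate p about the vertical (+y) axis through `center` by `deg` degrees;
# convention: x' = x cos + z sin, z' = -x sin + z cos
.rotate_about_vertical <- function(p, center, deg) {
  th <- deg * pi / 180
  v <- p - center
  center + c(v[1] * cos(th) + v[3] * sin(th),
             v[2],
             -v[1] * sin(th) + v[3] * cos(th))
}

#' Place the default three-point lighting
#'
#' Key and fill spotlights start at the camera position, are rotated by
#' +45° and −45° about the vertical axis through the system center,
#' raised by one extent along +y, and aimed at the center, with energies
#' 1.0 and 0.5 (the fill is dimmer than the key). A non-directional rim
#' lamp (energy 0.8) sits at `center + (0, 0, +4 r)`, directly behind the
#' system relative to the camera.
#'
#' @param frame a [scene_frame()].
#' @param camera the scene [camera()].
#' @return list of three [light_source()] objects (key, fill, rim).
#' @export
place_lights <- function(frame, camera) {
  lift <- c(0, frame$extent, 0)
  key_pos <- .rotate_about_vertical(camera$position, frame$center, 45) + lift
  fill_pos <- .rotate_about_vertical(camera$position, frame$center, -45) + lift
  list(
    key = light_source("spot", key_pos, energy = 1.0, aim = frame$center),
    fill = light_source("spot", fill_pos, energy = 0.5, aim = frame$center),
    rim = light_source("lamp", frame$center + c(0, 0, 4 * frame$extent),
                       energy = 0.8))
}

#' Default render settings
#'
#' 1000 x 1000 pixels, anti-aliasing with 8 samples, ray tracing with 6
#' samples, PNG output at 16 bits of color depth without compression, and
#' a sky-blue background.
#'
#' @return an object of class `render_settings`.
#' @export
default_render_settings <- function() {
  structure(list(width = 1000L, height = 1000L,
                 antialias_samples = 8L, raytrace_samples = 6L,
                 output_format = "png", color_depth_bits = 16L,
                 compression = FALSE,
                 background_rgb = c(0.53, 0.81, 0.92)),
            class = "render_settings")
}

#' Build a cross-eyed stereoscopic camera pair
#'
#' The two cameras are obtained by rotating the input camera by plus and
#' minus `half_angle_deg` about the vertical axis through the frame
#' center, both re-aimed at the center. The pair is ordered for
#' cross-eyed viewing: the `left` element is the right-eye view (the
#' camera displaced toward the viewer's right) and vice versa.
#'
#' @param camera the base [camera()].
#' @param frame a [scene_frame()].
#' @param half_angle_deg rotation half-angle in degrees, in `(0, 10]`
#'   (default 2).
#' @return list with [camera()] elements `left` and `right`.
#' @export
make_stereo_pair <- function(camera, frame, half_angle_deg = 2) {
  if (!is.numeric(half_angle_deg) || half_angle_deg <= 0 || half_angle_deg > 10) {
    stop("half_angle_deg must lie in (0, 10]")
  }
  rot_cam <- function(deg) {
    rhotop::camera(position = .rotate_about_vertical(camera$position,
                                                     frame$center, deg),
                   look_at = frame$center, up = camera$up,
                   fov_degrees = camera$fov_degrees)
  }
  # with the rotation convention above, a negative angle displaces a
  # camera on the -z side toward +x, i.e. toward the viewer's right
  list(left = rot_cam(-half_angle_deg), right = rot_cam(half_angle_deg))
}
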