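## Room-frame conventions
##
## Right-handed room coordinate system, lengths in mm:
##   +z  beam axis (beam travels towards +z),
##   +y  vertical up,
##   origin at the room isocenter.
## The tracker focus line (the line through the centers of the two detection
## layers) passes through the isocenter; by default it lies in the y-z plane,
## 30 degrees above the beam axis, pointing downstream and up.

vec3 <- function(x, y, z) c(x = x, y = y, z = z)

.norm3 <- function(v) sqrt(sum(v * v))

.unit3 <- function(v) {
  n <- .norm3(v)
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Rodrigues rotation of v about unit axis k by angle (radians)
.rotate_about <- function(v, k, angle) {
  v * cos(angle) + .cross3(k, v) * sin(angle) + k * sum(k * v) * (1 - cos(angle))
}

#' Construct a line in room coordinates
#'
#' A line is stored as an origin point and a unit direction. Both the fragment
#' tracks through the two detection layers and the pencil-beam lines are
#' represented this way.
#'
#' @param origin Numeric length-3 point on the line (mm, room frame).
#' @param direction Numeric length-3 direction; normalized internally.
#' @return An object of class `line3` with elements `origin` and `direction`
#'   (unit norm).
#' @export
line3 <- function(origin, direction) {
  stopifnot(length(origin) == 3, length(direction) == 3,
            all(is.finite(origin)), all(is.finite(direction)))
  structure(list(origin = as.numeric(origin),
                 direction = .unit3(as.numeric(direction))),
            class = "line3")
}

#' @export
print.line3 <- function(x, ...) {
  cat(sprintf("<line3> origin (%.3f, %.3f, %.3f) direction (%.5f, %.5f, %.5f)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' Closest approach between two 3D lines
#'
#' Finds the shortest connecting segment between two (generally skew) lines and
#' its midpoint. The midpoint of the shortest connection between a fragment
#' track and its associated pencil-beam line is the reconstructed fragmentation
#' vertex, so this is the geometric core of the vertexing step.
#'
#' @param a,b Objects of class [line3].
#' @param parallel_tol Tolerance on the cross-product norm of the two
#'   directions below which the lines are treated as parallel (degenerate).
#' @return A list with `point_on_a`, `point_on_b`, `midpoint` (length-3
#'   numerics), `distance` (mm) and `degenerate` (logical). For parallel lines
#'   `distance` is the perpendicular distance between them and the points are
#'   `NA` unless the lines coincide, in which case the shared origin of `a` is
#'   returned.
#' @export
closest_approach <- function(a, b, parallel_tol = 1e-9) {
  stopifnot(inherits(a, "line3"), inherits(b, "line3"))
  d1 <- a$direction; d2 <- b$direction
  cr <- .cross3(d1, d2)
  w0 <- a$origin - b$origin
  if (.norm3(cr) < parallel_tol) {
    # parallel: distance is the perpendicular offset of b's origin from a
    perp <- w0 - sum(w0 * d1) * d1
    dist <- .norm3(perp)
    if (dist < 1e-9) {
      return(list(point_on_a = a$origin, point_on_b = a$origin,
                  midpoint = a$origin, distance = 0, degenerate = TRUE))
    }
    return(list(point_on_a = rep(NA_real_, 3), point_on_b = rep(NA_real_, 3),
                midpoint = rep(NA_real_, 3), distance = dist,
                degenerate = TRUE))
  }
  bb <- sum(d1 * d2)
  d <- sum(d1 * w0)
  e <- sum(d2 * w0)
  den <- 1 - bb * bb
  t1 <- (bb * e - d) / den
  t2 <- (e - bb * d) / den
  pa <- a$origin + t1 * d1
  pb <- b$origin + t2 * d2
  list(point_on_a = pa, point_on_b = pb,
       midpoint = (pa + pb) / 2,
       distance = .norm3(pa - pb),
       degenerate = FALSE)
}

## Vectorized closest approach of many lines (origins o1, directions u1; rows)
## against many lines (o2, u2). Used by the vertex reconstruction hot path;
## must agree with closest_approach() pair by pair (tested).
.closest_approach_many <- function(o1, u1, o2, u2, parallel_tol = 1e-9) {
  bb <- rowSums(u1 * u2)
  w0 <- o1 - o2
  d <- rowSums(u1 * w0)
  e <- rowSums(u2 * w0)
  den <- 1 - bb * bb
  deg <- sqrt(pmax(den, 0)) < parallel_tol  # |u1 x u2|^2 = 1 - (u1.u2)^2
  den[deg] <- NA_real_
  t1 <- (bb * e - d) / den
  t2 <- (e - bb * d) / den
  pa <- o1 + t1 * u1
  pb <- o2 + t2 * u2
  list(midpoint = (pa + pb) / 2,
       distance = sqrt(rowSums((pa - pb)^2)),
       degenerate = deg)
}

#' Two-layer pixel tracker geometry
#'
#' Builds the room-frame geometry of the two-layer pixelated silicon tracker
#' ("mini-tracker"): two parallel layers perpendicular to the focus line, which
#' passes through the isocenter at `focus_angle_deg` to the beam axis. Each
#' layer carries an orthonormal in-plane basis (`e1` along pixel columns, `e2`
#' along pixel rows); a small known tilt of the tracker within its support is
#' applied as a rotation of that basis about the focus line.
#'
#' Defaults describe the device used throughout the package: 20.3 mm layer
#' separation, 55 um pixel pitch, approximately 28 mm x 14 mm active area per
#' layer (two readout chips sharing one sensor, columns continuous across the
#' chip boundary), front layer 167 mm from the isocenter, focus line 30 degrees
#' above the beam axis, 1.6 degree tilt.
#'
#' @param layer_separation Distance between the two layers along the focus
#'   line, mm.
#' @param pixel_pitch Pixel pitch, mm.
#' @param active_area Length-2 in-plane sensor extent (columns, rows), mm.
#' @param pixels_per_layer Length-2 integer pixel counts (columns, rows);
#'   default derived from `active_area / pixel_pitch` rounded down.
#' @param sensor_thickness Sensor thickness, mm (metadata only).
#' @param focus_angle_deg Angle of the focus line to the beam axis, degrees.
#' @param front_layer_distance Isocenter to front-layer center, mm.
#' @param tilt_deg In-support tilt about the focus line, degrees.
#' @param azimuth_deg Azimuth of the focus line about the beam axis, degrees;
#'   90 (default) places the tracker diagonally above the phantom (+y).
#' @return Object of class `tracker_geometry`: the inputs plus, per layer, the
#'   derived `center`, `normal` and in-plane basis vectors in room frame.
#' @export
tracker_geometry <- function(layer_separation = 20.3,
                             pixel_pitch = 0.055,
                             active_area = c(28, 14),
                             pixels_per_layer = NULL,
                             sensor_thickness = 0.5,
                             focus_angle_deg = 30,
                             front_layer_distance = 167,
                             tilt_deg = 1.6,
                             azimuth_deg = 90) {
  stopifnot(layer_separation > 0, pixel_pitch > 0, all(active_area > 0),
            front_layer_distance > 0)
  if (is.null(pixels_per_layer)) {
    pixels_per_layer <- floor(active_area / pixel_pitch)
  }
  th <- focus_angle_deg * pi / 180
  az <- azimuth_deg * pi / 180
  u <- c(cos(az) * sin(th), sin(az) * sin(th), cos(th))  # focus direction
  # in-plane basis: e1 (columns) horizontal for the default azimuth
  if (abs(sin(th)) < 1e-12) {
    e1 <- c(1, 0, 0)
  } else {
    e1 <- .unit3(.cross3(u, c(0, 0, 1)))
  }
  e2 <- .cross3(u, e1)
  tilt <- tilt_deg * pi / 180
  if (tilt != 0) {
    e1 <- .rotate_about(e1, u, tilt)
    e2 <- .rotate_about(e2, u, tilt)
  }
  layers <- list(
    front = list(center = u * front_layer_distance,
                 normal = u, e1 = e1, e2 = e2),
    back = list(center = u * (front_layer_distance + layer_separation),
                normal = u, e1 = e1, e2 = e2)
  )
  structure(list(layer_separation = layer_separation,
                 pixel_pitch = pixel_pitch,
                 active_area = active_area,
                 pixels_per_layer = as.integer(pixels_per_layer),
                 sensor_thickness = sensor_thickness,
                 focus_angle_deg = focus_angle_deg,
                 front_layer_distance = front_layer_distance,
                 tilt_deg = tilt_deg,
                 azimuth_deg = azimuth_deg,
                 focus_direction = u,
                 layers = layers),
            class = "tracker_geometry")
}

#' @export
print.tracker_geometry <- function(x, ...) {
  cat("<tracker_geometry>\n")
  cat(sprintf("  layers: %d x %d pixels, pitch %.3f mm, active %.1f x %.1f mm\n",
              x$pixels_per_layer[1], x$pixels_per_layer[2], x$pixel_pitch,
              x$active_area[1], x$active_area[2]))
  cat(sprintf("  separation %.1f mm, front layer at %.1f mm from isocenter\n",
              x$layer_separation, x$front_layer_distance))
  cat(sprintf("  focus line %.1f deg to beam axis (azimuth %.1f deg), tilt %.2f deg\n",
              x$focus_angle_deg, x$azimuth_deg, x$tilt_deg))
  invisible(x)
}

.get_layer <- function(geom, layer_id) {
  layer_id <- match.arg(layer_id, c("front", "back"))
  geom$layers[[layer_id]]
}

#' Map pixel coordinates to room coordinates
#'
#' Converts (column, row) pixel coordinates on one detection layer into a 3D
#' point on the layer's mid-sensor plane in the room frame, accounting for the
#' tracker position, orientation and tilt. Pixel centers sit at integer
#' indices; fractional values (e.g. energy-weighted cluster centroids) are
#' allowed. Index 0 is the first column/row; the pixel grid is centered on the
#' layer center, so column `(ncol - 1) / 2` at row `(nrow - 1) / 2` maps to the
#' layer center itself.
#'
#' @param col,row Pixel coordinates (vectors, fractional allowed, 0-based).
#' @param layer_id `"front"` or `"back"`.
#' @param geom A [tracker_geometry].
#' @param offset Optional length-2 sub-pixel offset added to (col, row).
#' @return Numeric matrix with one row per input and columns `x`, `y`, `z`
#'   (mm).
#' @export
sensor_to_room <- function(col, row, layer_id, geom, offset = c(0, 0)) {
  stopifnot(inherits(geom, "tracker_geometry"), length(col) == length(row))
  np <- geom$pixels_per_layer
  cf <- col + offset[1]
  rf <- row + offset[2]
  if (any(cf < -0.5 | cf > np[1] - 0.5 | rf < -0.5 | rf > np[2] - 0.5)) {
    stop(sprintf("pixel index out of range (grid %d x %d)", np[1], np[2]))
  }
  lay <- .get_layer(geom, layer_id)
  u1 <- (cf - (np[1] - 1) / 2) * geom$pixel_pitch
  u2 <- (rf - (np[2] - 1) / 2) * geom$pixel_pitch
  out <- cbind(x = lay$center[1] + u1 * lay$e1[1] + u2 * lay$e2[1],
               y = lay$center[2] + u1 * lay$e1[2] + u2 * lay$e2[2],
               z = lay$center[3] + u1 * lay$e1[3] + u2 * lay$e2[3])
  out
}

#' Inverse of [sensor_to_room]
#'
#' Projects room-frame points onto a layer's in-plane basis and returns
#' fractional pixel coordinates. Points need not lie exactly on the layer
#' plane; the in-plane components are returned regardless.
#'
#' @param points Numeric matrix (n x 3) or length-3 vector.
#' @inheritParams sensor_to_room
#' @return List with numeric vectors `col` and `row`.
#' @export
room_to_sensor <- function(points, layer_id, geom) {
  stopifnot(inherits(geom, "tracker_geometry"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  lay <- .get_layer(geom, layer_id)
  np <- geom$pixels_per_layer
  dx <- sweep(points, 2, lay$center)
  u1 <- as.vector(dx %*% lay$e1)
  u2 <- as.vector(dx %*% lay$e2)
  list(col = u1 / geom$pixel_pitch + (np[1] - 1) / 2,
       row = u2 / geom$pixel_pitch + (np[2] - 1) / 2)
}

## Intersect rays (origins o, unit directions d; n x 3 matrices) with one
## layer plane. Returns in-plane coordinates (u1, u2, mm relative to the layer
## center), the ray parameter t and a hit flag (forward intersection inside
## the active area).
.intersect_layer <- function(o, d, lay, half_extent) {
  dn <- as.vector(d %*% lay$normal)
  t <- as.vector((matrix(lay$center, nrow(o), 3, byrow = TRUE) - o) %*% lay$normal) / dn
  p <- o + d * t
  dx <- sweep(p, 2, lay$center)
  u1 <- as.vector(dx %*% lay$e1)
  u2 <- as.vector(dx %*% lay$e2)
  hit <- is.finite(t) & t > 0 &
    abs(u1) <= half_extent[1] & abs(u2) <= half_extent[2]
  list(u1 = u1, u2 = u2, t = t, hit = hit)
}

#' Monte Carlo acceptance solid angle of the tracker
#'
#' Estimates the solid angle subtended, from a given emission point, by the
#' set of directions that intersect the tracker. Directions are sampled
#' uniformly inside a cone that is guaranteed to contain both layers;
#' the estimate is the hit fraction times the cone's solid angle.
#'
#' @param geom A [tracker_geometry].
#' @param origin Emission point (length-3, mm); default isocenter.
#' @param n_samples Number of sampled directions (at least 1e4).
#' @param seed Optional integer seed.
#' @param layers `"both"` requires the direction to cross both layers
#'   (coincidence acceptance); `"front"` only the front layer.
#' @return List with `omega` (steradians), `se` (Monte Carlo standard error),
#'   `n_hits`, `n_samples` and `cone_omega`.
#' @export
acceptance_solid_angle <- function(geom, origin = c(0, 0, 0),
                                   n_samples = 1e5, seed = NULL,
                                   layers = c("both", "front")) {
  stopifnot(inherits(geom, "tracker_geometry"), n_samples >= 1e4)
  layers <- match.arg(layers)
  if (!is.null(seed)) set.seed(seed)
  half <- geom$active_area / 2
  # cone around the direction to the front-layer center covering all corners
  corners <- list()
  for (lid in c("front", "back")) {
    lay <- geom$layers[[lid]]
    if (abs(sum((lay$center - origin) * lay$normal)) < 1e-9) {
      stop("origin lies on a layer plane")
    }
    for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) {
      corners[[length(corners) + 1]] <-
        lay$center + s1 * half[1] * lay$e1 + s2 * half[2] * lay$e2 - origin
    }
  }
  axis <- .unit3(geom$layers$front$center - origin)
  ang <- vapply(corners, function(v) acos(sum(.unit3(v) * axis)), 0)
  theta_c <- min(max(ang) * 1.25 + 0.01, pi / 2)
  cone_omega <- 2 * pi * (1 - cos(theta_c))
  # orthonormal frame about the cone axis
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b1 <- .unit3(.cross3(axis, ref))
  b2 <- .cross3(axis, b1)
  ct <- stats::runif(n_samples, cos(theta_c), 1)
  st <- sqrt(1 - ct^2)
  ph <- stats::runif(n_samples, 0, 2 * pi)
  d <- outer(st * cos(ph), b1) + outer(st * sin(ph), b2) + outer(ct, axis)
  o <- matrix(origin, n_samples, 3, byrow = TRUE)
  hit_f <- .intersect_layer(o, d, geom$layers$front, half)$hit
  hit <- if (layers == "both") {
    hit_f & .intersect_layer(o, d, geom$layers$back, half)$hit
  } else hit_f
  frac <- mean(hit)
  list(omega = frac * cone_omega,
       se = sqrt(frac * (1 - frac) / n_samples) * cone_omega,
       n_hits = sum(hit), n_samples = n_samples, cone_omega = cone_omega)
}
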