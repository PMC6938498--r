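#' Spindle (lens) container geometry
#'
#' Constructs the quasi-2D spindle-shaped container used to confine hard rods:
#' the cross-section of two overlapping circles of equal radius, extruded to a
#' depth \code{h}. The major axis \code{Ly} is the distance between the two
#' cusps (vertices), the minor axis \code{Lx = Ly/aspect} is the width of the
#' lens at its waist, and the cusp opening angle follows
#' \code{alpha = 4 * arccot(Ly/Lx)}. All lengths are in units of the rod
#' diameter \code{d}.
#'
#' The coordinate convention places the origin at the container centre, the
#' major axis along y, the minor axis along x, and z in \code{[0, h]}. The two
#' arc circles have radius \code{R = (Lx^2 + Ly^2) / (4 Lx)} and centres at
#' \code{(+/- c, 0)} with \code{c = R - Lx/2}; \code{aspect = 1} degenerates to
#' a circle (\code{c = 0}, \code{alpha = 180} degrees).
#'
#' @param Ly major-axis length (distance between cusps), in units of d.
#' @param aspect aspect ratio Ly/Lx, must be >= 1.
#' @param h container depth, in units of d.
#' @return An object of class \code{"spindle_geometry"}: a list with fields
#'   \code{Ly}, \code{Lx}, \code{h}, \code{aspect}, and the derived
#'   \code{R} (arc radius), \code{c} (arc-centre offset) and \code{alpha}
#'   (cusp opening angle, degrees).
#' @examples
#' g <- spindle_geometry(90, aspect = 1.5, h = 6)
#' g$R      # 48.75
#' g$alpha  # about 134.76 degrees
#' @export
spindle_geometry <- function(Ly, aspect = 1, h = 6) {
  if (!is.numeric(Ly) || length(Ly) != 1L || !is.finite(Ly) || Ly <= 0)
    stop("'Ly' must be a positive number")
  if (!is.numeric(aspect) || length(aspect) != 1L || !is.finite(aspect) ||
      aspect < 1)
    stop("'aspect' must be a number >= 1")
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("'h' must be a positive number")
  Lx <- Ly / aspect
  R <- (Lx^2 + Ly^2) / (4 * Lx)
  structure(
    list(Ly = Ly, Lx = Lx, h = h, aspect = aspect,
         R = R, c = R - Lx / 2, alpha = alpha_from_aspect(aspect)),
    class = "spindle_geometry"
  )
}

#' @export
print.spindle_geometry <- function(x, ...) {
  cat("Spindle container (lengths in rod diameters d)\n")
  cat(sprintf("  Ly = %g, Lx = %g (aspect %.4g), h = %g\n",
              x$Ly, x$Lx, x$aspect, x$h))
  cat(sprintf("  arc radius R = %.6g, arc-centre offset c = %.6g\n", x$R, x$c))
  cat(sprintf("  cusp opening angle alpha = %.4g deg\n", x$alpha))
  invisible(x)
}

#' Cusp opening angle from aspect ratio (and back)
#'
#' The opening angle of the spindle cusps relates to the aspect ratio through
#' \code{alpha = 4 * arccot(Ly/Lx)}; \code{aspect_from_alpha} is its inverse.
#'
#' @param aspect aspect ratio Ly/Lx, >= 1 (may be a vector).
#' @return Opening angle in degrees, in (0, 180].
#' @examples
#' alpha_from_aspect(1)     # 180: a circle
#' alpha_from_aspect(7.59)  # about 30
#' @export
alpha_from_aspect <- function(aspect) {
  if (any(!is.finite(aspect)) || any(aspect < 1))
    stop("'aspect' must be >= 1")
  4 * atan(1 / aspect) * 180 / pi
}

#' @rdname alpha_from_aspect
#' @param alpha opening angle in degrees, in (0, 180].
#' @export
aspect_from_alpha <- function(alpha) {
  if (any(!is.finite(alpha)) || any(alpha <= 0) || any(alpha > 180))
    stop("'alpha' must be in (0, 180] degrees")
  1 / tan(alpha * pi / 180 / 4)
}

geom_vec <- function(geom) {
  # packed form consumed by the C++ engine
  c(geom$R, geom$c, geom$h, geom$Lx, geom$Ly)
}

#' Point-inside test for the (eroded) spindle
#'
#' Tests whether points lie inside the container eroded by \code{margin}: both
#' arc disks shrunk to radius \code{R - margin} and the slab reduced to
#' \code{[margin, h - margin]}. Because the lens is convex, the eroded lens is
#' exactly the intersection of the two eroded disks.
#'
#' @param geom a \code{\link{spindle_geometry}}.
#' @param p a length-3 vector or an n-by-3 matrix of points.
#' @param margin erosion depth, >= 0 and smaller than \code{min(Lx/2, h/2)}.
#' @return Logical vector, one entry per point.
#' @export
contains_point <- function(geom, p, margin = 0) {
  stopifnot(inherits(geom, "spindle_geometry"))
  if (margin < 0 || margin >= min(geom$Lx / 2, geom$h / 2))
    stop("'margin' must be in [0, min(Lx/2, h/2))")
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  rr <- (geom$R - margin)^2
  in_z <- p[, 3] >= margin & p[, 3] <= geom$h - margin
  in_a <- (p[, 1] - geom$c)^2 + p[, 2]^2 <= rr
  in_b <- (p[, 1] + geom$c)^2 + p[, 2]^2 <= rr
  in_z & in_a & in_b
}

#' Is a spherocylinder entirely inside the container?
#'
#' The particle-wall interaction is hard: a rod is admissible only if its full
#' spherocylinder volume is inside. Since the lens eroded by \code{d/2} is
#' convex, the capsule is inside iff both centreline endpoints are in the
#' eroded region; this test is exact and O(1), with no special-casing at the
#' cusps.
#'
#' @param geom a \code{\link{spindle_geometry}}.
#' @param r rod centre, length-3 vector.
#' @param u rod orientation, unit length-3 vector.
#' @param L cylinder length (units of d).
#' @param d rod diameter (units of d, so normally 1).
#' @return \code{TRUE} iff the rod lies entirely inside.
#' @export
capsule_inside <- function(geom, r, u, L, d = 1) {
  stopifnot(inherits(geom, "spindle_geometry"), L > 0, d > 0)
  ends <- rbind(r + (L / 2) * u, r - (L / 2) * u)
  all(contains_point(geom, ends, margin = d / 2))
}

#' Lens area, volume and rod count at a target volume fraction
#'
#' The lens cross-section area has the closed form
#' \code{2 R^2 (theta - sin(theta) cos(theta))} with
#' \code{theta = asin(Ly / (2R))}; the volume is \code{area * h}. The number
#' of rods realising a volume fraction \code{eta} is
#' \code{round(eta * volume / v_rod)} with the spherocylinder volume
#' \code{v_rod = (pi/4) d^2 L + (pi/6) d^3}.
#'
#' @param geom a \code{\link{spindle_geometry}}.
#' @return \code{lens_area}: cross-section area in d^2.
#' @export
lens_area <- function(geom) {
  stopifnot(inherits(geom, "spindle_geometry"))
  theta <- asin(min(1, geom$Ly / (2 * geom$R)))
  2 * geom$R^2 * (theta - sin(theta) * cos(theta))
}

#' @rdname lens_area
#' @export
lens_volume <- function(geom) lens_area(geom) * geom$h

#' @rdname lens_area
#' @param eta target volume fraction, in (0, 1) (0 allowed, giving 0 rods).
#' @param L cylinder length in d.
#' @param d rod diameter in d.
#' @export
count_rods <- function(geom, eta, L = 20, d = 1) {
  if (!is.numeric(eta) || length(eta) != 1L || eta < 0 || eta >= 1)
    stop("'eta' must be in [0, 1)")
  v_rod <- pi / 4 * d^2 * L + pi / 6 * d^3
  round(eta * lens_volume(geom) / v_rod)
}

#' @rdname lens_area
#' @export
rod_volume <- function(L = 20, d = 1) pi / 4 * d^2 * L + pi / 6 * d^3

# signed distance helpers used by the defect probes: project an interior point
# onto the lens boundary (the nearer arc, clamped at the cusps)
project_to_boundary <- function(geom, x, y) {
  # candidate projections on the two arcs
  best <- NULL
  bestd <- Inf
  for (cx in c(geom$c, -geom$c)) {
    v <- c(x - cx, y)
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) next
    p <- c(cx, 0) + geom$R * v / nv
    # the arc forming the boundary on the opposite side of its centre
    if (abs(p[2]) > geom$Ly / 2 || sign(p[1]) == sign(cx) && geom$c > 1e-9) {
      p <- c(0, sign(if (y == 0) 1 else y) * geom$Ly / 2)  # clamp to cusp
    }
    dd <- sqrt((p[1] - x)^2 + (p[2] - y)^2)
    if (dd < bestd) {
      bestd <- dd
      best <- p
    }
  }
  best
}
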