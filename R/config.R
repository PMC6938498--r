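#' Rod ensemble in a spindle container
#'
#' Bundles a container geometry with the positions and orientations of N
#' identical hard spherocylinders. The constructor optionally validates the
#' hard-core invariants (no rod-rod overlap, every rod inside the wall).
#'
#' @param geom a \code{\link{spindle_geometry}}.
#' @param pos N-by-3 matrix of rod centres (units of d).
#' @param orient N-by-3 matrix of unit orientations.
#' @param L cylinder length (units of d).
#' @param d rod diameter (units of d).
#' @param validate check hard-core and wall invariants (O(N^2)); default TRUE.
#' @return An object of class \code{"rod_config"} with fields \code{geom},
#'   \code{pos}, \code{orient}, \code{L}, \code{d}, \code{n} and the realised
#'   volume fraction \code{eta}.
#' @export
rod_config <- function(geom, pos, orient, L = 20, d = 1, validate = TRUE) {
  stopifnot(inherits(geom, "spindle_geometry"))
  pos <- as.matrix(pos)
  orient <- as.matrix(orient)
  if (ncol(pos) != 3L || ncol(orient) != 3L || nrow(pos) != nrow(orient))
    stop("'pos' and 'orient' must be N-by-3 matrices of equal row count")
  nrm <- sqrt(rowSums(orient^2))
  if (any(abs(nrm - 1) > 1e-9)) orient <- orient / nrm
  n <- nrow(pos)
  cfg <- structure(
    list(geom = geom, pos = pos, orient = orient, L = L, d = d, n = n,
         eta = n * rod_volume(L, d) / lens_volume(geom)),
    class = "rod_config"
  )
  if (validate && n > 0) {
    chk <- cpp_check_config(pos, orient, L, d, geom_vec(geom))
    if (chk$n_wall > 0)
      stop(sprintf("%d rod(s) violate the hard wall", chk$n_wall))
    if (chk$n_overlap > 0)
      stop(sprintf("%d overlapping rod pair(s)", chk$n_overlap))
  }
  cfg
}

#' @export
print.rod_config <- function(x, ...) {
  cat(sprintf("Rod configuration: %d spherocylinders (L = %g d, d = %g)\n",
              x$n, x$L, x$d))
  cat(sprintf("  container: Ly = %g, aspect = %.4g, h = %g\n",
              x$geom$Ly, x$geom$aspect, x$geom$h))
  cat(sprintf("  realised volume fraction eta = %.4f\n", x$eta))
  invisible(x)
}

#' Count hard-core violations in a configuration
#'
#' All-pairs overlap count plus wall violations; used as the exact (O(N^2))
#' oracle against which the cell-list-accelerated engine is checked.
#'
#' @param config a \code{\link{rod_config}}.
#' @return list with integer fields \code{n_overlap} and \code{n_wall}.
#' @export
config_violations <- function(config) {
  stopifnot(inherits(config, "rod_config"))
  cpp_check_config(config$pos, config$orient, config$L, config$d,
                   geom_vec(config$geom))
}

#' Minimum distance between two line segments
#'
#' Closed-form minimum Euclidean distance between the closed segments
#' a0-a1 and b0-b1 (either may degenerate to a point). This is the primitive
#' behind the spherocylinder overlap test: two rods of diameter d overlap iff
#' their centreline distance is below d.
#'
#' @param a0,a1 endpoints of the first segment (length-3 vectors).
#' @param b0,b1 endpoints of the second segment.
#' @return The minimum distance (scalar).
#' @examples
#' min_distance_segments(c(0, 0, 0), c(1, 0, 0), c(0, 1, 1), c(1, 1, 1)) # sqrt(2)
#' @export
min_distance_segments <- function(a0, a1, b0, b1) {
  cpp_segment_distance(as.numeric(a0), as.numeric(a1),
                       as.numeric(b0), as.numeric(b1))
}

#' Do two spherocylinders overlap?
#'
#' @param r1,u1 centre and unit orientation of the first rod.
#' @param r2,u2 centre and unit orientation of the second rod.
#' @param L cylinder length; @param d diameter (shared by both rods).
#' @return \code{TRUE} iff the centreline distance is below d.
#' @export
rods_overlap <- function(r1, u1, r2, u2, L = 20, d = 1) {
  h <- L / 2
  min_distance_segments(r1 - h * u1, r1 + h * u1,
                        r2 - h * u2, r2 + h * u2) < d
}
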