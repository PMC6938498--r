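#' Specification of an analytic director field
#'
#' Describes a director field on the lens as a superposition of point
#' disclinations: the in-plane nematic angle at position r is
#' \deqn{\theta(r) = \sum_j q_j \, \mathrm{atan2}(y - y_j, x - x_j) +
#'   \theta_0 + A \sin(2 \pi y / L_y),}
#' the standard multi-defect solution of the harmonic director equation, plus
#' an optional long-wavelength wave term (amplitude \code{wave_amplitude})
#' used to realise the wavy "S"-shaped patterns. The scalar order is 1 away
#' from the cores and ramps linearly to 0 within one cell of each core.
#'
#' @param pattern a pattern label (informational; see
#'   \code{\link{pattern_fixture}} for canonical specs).
#' @param geom a \code{\link{spindle_geometry}}.
#' @param positions k-by-2 matrix of defect positions (inside or on the
#'   boundary), or NULL for a defect-free field.
#' @param charges length-k vector of half-integer charges.
#' @param background_angle additive constant theta_0 (radians); by default
#'   chosen so the director at the container centre points along the major
#'   axis.
#' @param wave_amplitude amplitude A of the sinusoidal wave term (radians).
#' @return list of class \code{"field_spec"}.
#' @export
field_spec <- function(pattern, geom, positions = NULL, charges = NULL,
                       background_angle = NULL, wave_amplitude = 0) {
  stopifnot(inherits(geom, "spindle_geometry"))
  if (!is.null(positions)) {
    positions <- matrix(positions, ncol = 2)
    if (length(charges) != nrow(positions))
      stop("'charges' must match the number of defect positions")
    ok <- contains_point(geom,
                         cbind(positions, geom$h / 2), margin = 0)
    on_bd <- abs(sqrt((positions[, 1] - geom$c)^2 + positions[, 2]^2) -
                   geom$R) < 1e-6 |
             abs(sqrt((positions[, 1] + geom$c)^2 + positions[, 2]^2) -
                   geom$R) < 1e-6
    if (any(!ok & !on_bd))
      stop("defect positions must lie inside or on the boundary")
  }
  if (is.null(background_angle)) {
    base <- 0
    if (!is.null(positions))
      base <- sum(charges * atan2(-positions[, 2], -positions[, 1]))
    background_angle <- pi / 2 - base
  }
  structure(list(pattern = pattern, geom = geom, positions = positions,
                 charges = charges, background_angle = background_angle,
                 wave_amplitude = wave_amplitude),
            class = "field_spec")
}

#' Realise an analytic director field on a cell grid
#'
#' Samples the director field described by a \code{\link{field_spec}} on the
#' same grid of cuboidal sub-volumes used for simulation frames, so the whole
#' analysis stack (deficit maps, defect detection, pattern classification) is
#' agnostic about whether a field came from an analytic construction or from
#' a Monte Carlo configuration.
#'
#' @param spec a \code{\link{field_spec}}.
#' @param cell_size cell footprint edge in d.
#' @return a \code{\link{local_order_field}}.
#' @export
synth_field <- function(spec, cell_size = 10) {
  stopifnot(inherits(spec, "field_spec"))
  geom <- spec$geom
  nx <- max(3L, ceiling(geom$Lx / cell_size))
  ny <- max(3L, ceiling(geom$Ly / cell_size))
  x0 <- -nx * cell_size / 2
  y0 <- -ny * cell_size / 2
  xc <- x0 + (seq_len(nx) - 0.5) * cell_size
  yc <- y0 + (seq_len(ny) - 0.5) * cell_size
  S <- ang <- nzm <- matrix(NA_real_, nx, ny)
  nn <- array(NA_real_, c(nx, ny, 3))
  inside <- outer(xc, yc, function(px, py)
    (px - geom$c)^2 + py^2 <= geom$R^2 & (px + geom$c)^2 + py^2 <= geom$R^2)
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      if (!inside[i, j]) next
      th <- spec$background_angle +
        spec$wave_amplitude * sin(2 * pi * yc[j] / geom$Ly)
      s <- 1
      if (!is.null(spec$positions)) {
        for (k in seq_len(nrow(spec$positions))) {
          th <- th + spec$charges[k] *
            atan2(yc[j] - spec$positions[k, 2], xc[i] - spec$positions[k, 1])
          dk <- sqrt((xc[i] - spec$positions[k, 1])^2 +
                       (yc[j] - spec$positions[k, 2])^2)
          s <- min(s, max(0, min(1, dk / cell_size)))
        }
      }
      ang[i, j] <- th %% pi
      S[i, j] <- s
      nn[i, j, ] <- c(cos(th), sin(th), 0)
      nzm[i, j] <- 0
    }
  }
  structure(
    list(x = xc, y = yc, S = S, angle = ang, nz = nzm, n = nn,
         occupancy = ifelse(inside, 1, 0), inside = inside,
         occupied = inside, cell_size = cell_size, geom = geom),
    class = "local_order_field"
  )
}

#' Canonical fixture for each pattern class
#'
#' Builds the analytic director field realising one of the pattern classes:
#' H (homogeneous, no defects), B (bipolar in a circle), Bpar (bipolar with
#' both +1/2 defects in the cusps), Dstar (one defect in a cusp, one
#' elsewhere on the boundary), Dstarstar (both defects on the boundary but
#' outside the cusps, diagonally opposed), Dh (both defects at the ends of
#' the minor axis), S and Sstarstar (wavy director with cusp/non-cusp
#' defects), M4 (three +1/2 boundary defects and one -1/2 interior defect)
#' and M6 (four +1/2 boundary defects and two -1/2 interior defects on the
#' long axis). Every closed pattern's charges sum to +1.
#'
#' @param pattern one of "H", "B", "Bpar", "Dstar", "Dstarstar", "Dh", "S",
#'   "Sstarstar", "M4", "M6", "hedgehog" (the radial +1 field used as an
#'   initial condition, not a member of the pattern taxonomy).
#' @param geom container geometry; B and hedgehog default to a circle, the
#'   rest to aspect 1.5.
#' @param cell_size grid cell edge in d.
#' @return list with the \code{spec} and the realised \code{field}.
#' @export
pattern_fixture <- function(pattern, geom = NULL, cell_size = 10) {
  circle_default <- pattern %in% c("B", "hedgehog")
  if (is.null(geom))
    geom <- spindle_geometry(90, aspect = if (circle_default) 1 else 1.5,
                             h = 6)
  Ly <- geom$Ly; Lx <- geom$Lx
  arc_pt <- function(yy, side = 1) {
    c(side * (sqrt(geom$R^2 - yy^2) - geom$c), yy)
  }
  spec <- switch(
    pattern,
    H = field_spec("H", geom),
    B = field_spec("B", geom, rbind(c(0, Ly / 2), c(0, -Ly / 2)),
                   c(0.5, 0.5)),
    Bpar = field_spec("Bpar", geom, rbind(c(0, Ly / 2), c(0, -Ly / 2)),
                      c(0.5, 0.5)),
    Dstar = field_spec("Dstar", geom,
                       rbind(c(0, Ly / 2), arc_pt(-0.35 * Ly)),
                       c(0.5, 0.5)),
    Dstarstar = field_spec("Dstarstar", geom,
                           rbind(arc_pt(0.35 * Ly, -1), arc_pt(-0.35 * Ly)),
                           c(0.5, 0.5)),
    Dh = field_spec("Dh", geom, rbind(c(Lx / 2, 0), c(-Lx / 2, 0)),
                    c(0.5, 0.5), background_angle = pi / 2),
    S = field_spec("S", geom, rbind(c(0, Ly / 2), c(0, -Ly / 2)),
                   c(0.5, 0.5), wave_amplitude = 35 * pi / 180),
    Sstarstar = field_spec("Sstarstar", geom,
                           rbind(arc_pt(0.35 * Ly, -1), arc_pt(-0.35 * Ly)),
                           c(0.5, 0.5), wave_amplitude = 35 * pi / 180),
    M4 = field_spec("M4", geom,
                    rbind(c(0, -Ly / 2), arc_pt(0.25 * Ly),
                          arc_pt(0.25 * Ly, -1), c(0, 0.15 * Ly)),
                    c(0.5, 0.5, 0.5, -0.5)),
    M6 = field_spec("M6", geom,
                    rbind(arc_pt(0.25 * Ly), arc_pt(0.25 * Ly, -1),
                          arc_pt(-0.25 * Ly), arc_pt(-0.25 * Ly, -1),
                          c(0, 0.17 * Ly), c(0, -0.17 * Ly)),
                    c(0.5, 0.5, 0.5, 0.5, -0.5, -0.5)),
    hedgehog = field_spec("hedgehog", geom, rbind(c(0, 0)), 1,
                          background_angle = 0),
    stop("unknown pattern '", pattern, "'")
  )
  list(spec = spec, field = synth_field(spec, cell_size))
}

#' Add angular noise to a director field
#'
#' Adds independent Gaussian noise to the in-plane director angle of every
#' occupied cell; used to probe the robustness of defect detection and
#' pattern classification. Zero noise is the identity.
#'
#' @param field a \code{\link{local_order_field}}.
#' @param noise_sd angular noise standard deviation (radians), >= 0.
#' @param seed RNG seed.
#' @return the perturbed field.
#' @export
perturb_field <- function(field, noise_sd, seed = 1L) {
  stopifnot(inherits(field, "local_order_field"), noise_sd >= 0)
  if (noise_sd == 0) return(field)
  set.seed(seed)
  idx <- which(field$occupied, arr.ind = TRUE)
  eps <- stats::rnorm(nrow(idx), 0, noise_sd)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    th <- (field$angle[i, j] + eps[r]) %% pi
    field$angle[i, j] <- th
    # rotate the in-plane part of the director, keep any tilt
    nz <- field$n[i, j, 3]
    inp <- sqrt(max(0, 1 - nz^2))
    field$n[i, j, ] <- c(inp * cos(th), inp * sin(th), nz)
  }
  field
}
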