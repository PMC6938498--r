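#' Global nematic tensor order parameter
#'
#' Computes the standard tensor order parameter of an orientation ensemble,
#' \deqn{Q = (1/N) \sum_i (3/2 \, u_i u_i^T - 1/2 \, I_3),}
#' its largest eigenvalue (the scalar order parameter S, 1 for perfect
#' alignment, 0 in the isotropic limit, -1/2 for planar-degenerate order) and
#' the corresponding eigenvector (the director, defined up to sign). The
#' out-of-plane tilt of the ensemble can be monitored through the z component
#' of the director.
#'
#' @param orient N-by-3 matrix of unit orientations (or a
#'   \code{\link{rod_config}}).
#' @return list of class \code{"nematic_order"} with fields \code{Q}
#'   (symmetric traceless 3x3), \code{S} and \code{n} (unit director).
#' @examples
#' global_Q(matrix(rep(c(0, 1, 0), 5), ncol = 3, byrow = TRUE))$S  # 1
#' @export
global_Q <- function(orient) {
  if (inherits(orient, "rod_config")) orient <- orient$orient
  orient <- as.matrix(orient)
  if (nrow(orient) < 1) stop("need at least one orientation")
  Q <- 1.5 * crossprod(orient) / nrow(orient) - 0.5 * diag(3)
  eg <- eigen(Q, symmetric = TRUE)
  structure(list(Q = Q, S = eg$values[1], n = eg$vectors[, 1]),
            class = "nematic_order")
}

#' @export
print.nematic_order <- function(x, ...) {
  cat(sprintf("Nematic order: S = %.4f, director = (%.3f, %.3f, %.3f)\n",
              x$S, x$n[1], x$n[2], x$n[3]))
  invisible(x)
}

#' Length of a segment clipped to an axis-aligned cuboid
#'
#' Exact parametric slab clipping of the segment p0-p1 against the box; the
#' clipped lengths are additive across any partition of space, so summed over
#' a grid of sub-volumes they recover the full centreline length of every rod
#' inside the domain.
#'
#' @param p0,p1 segment endpoints (length-3).
#' @param box 2-by-3 matrix: row 1 the lower corner, row 2 the upper corner.
#' @return clipped length (scalar, >= 0).
#' @export
segment_length_in_box <- function(p0, p1, box) {
  box <- as.matrix(box)
  d <- p1 - p0
  t0 <- 0
  t1 <- 1
  for (k in 1:3) {
    if (abs(d[k]) < 1e-14) {
      if (p0[k] < box[1, k] || p0[k] > box[2, k]) return(0)
    } else {
      ta <- (box[1, k] - p0[k]) / d[k]
      tb <- (box[2, k] - p0[k]) / d[k]
      if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
      t0 <- max(t0, ta)
      t1 <- min(t1, tb)
    }
  }
  if (t1 <= t0) return(0)
  (t1 - t0) * sqrt(sum(d^2))
}

#' Local length-weighted tensor order parameter field
#'
#' Divides the container bounding box into cuboidal sub-volumes of identical
#' square footprint \code{cell_size} and full container height, and builds in
#' each sub-volume k the length-weighted tensor order parameter
#' \deqn{Q^k = (1/\sum_i l_i^k) \sum_i l_i^k (3/2 \, u_i u_i^T - 1/2 \, I_3),}
#' where \eqn{l_i^k} is the length of the centreline of rod i inside
#' sub-volume k. Each occupied cell carries the local scalar order, director
#' and in-plane director angle from the eigen-decomposition of \eqn{Q^k}.
#'
#' @param config a \code{\link{rod_config}}.
#' @param cell_size sub-volume footprint edge, in \code{[d, L]}; the default
#'   L/2 resolves defect cores (which extend over about one rod length) with
#'   at least two cells.
#' @return An object of class \code{"local_order_field"}: list with cell
#'   centre coordinates \code{x}, \code{y}, matrices \code{S}, \code{angle}
#'   (in-plane nematic angle, radians in [0, pi)), \code{nz}, \code{occupancy}
#'   (total clipped length per cell), logical \code{inside} (cell centre
#'   inside the lens) and \code{occupied}, the director array \code{n}
#'   (nx x ny x 3), \code{cell_size} and the \code{geom}.
#' @export
local_Q_field <- function(config, cell_size = config$L / 2) {
  stopifnot(inherits(config, "rod_config"))
  if (cell_size < config$d || cell_size > config$L)
    stop("'cell_size' must be in [d, L]")
  geom <- config$geom
  nx <- max(3L, ceiling(geom$Lx / cell_size))
  ny <- max(3L, ceiling(geom$Ly / cell_size))
  x0 <- -nx * cell_size / 2
  y0 <- -ny * cell_size / 2
  acc <- cpp_local_Q(config$pos, config$orient, config$L, x0, y0, cell_size,
                     nx, ny)
  build_field_from_acc(acc, nx, ny, x0, y0, cell_size, geom)
}

build_field_from_acc <- function(acc, nx, ny, x0, y0, cell_size, geom) {
  xc <- x0 + (seq_len(nx) - 0.5) * cell_size
  yc <- y0 + (seq_len(ny) - 0.5) * cell_size
  S <- ang <- nz <- matrix(NA_real_, nx, ny)
  nn <- array(NA_real_, c(nx, ny, 3))
  occ <- matrix(acc$wsum, nx, ny)  # cell index c = iy*nx + ix (0-based)
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      ci <- (iy - 1) * nx + ix
      w <- acc$Q[ci, ]
      l <- occ[ix, iy]
      if (l <= 0) next
      Qk <- matrix(c(w[1], w[4], w[5],
                     w[4], w[2], w[6],
                     w[5], w[6], w[3]) / l, 3, 3)
      eg <- eigen(Qk, symmetric = TRUE)
      S[ix, iy] <- eg$values[1]
      v <- eg$vectors[, 1]
      nn[ix, iy, ] <- v
      nz[ix, iy] <- abs(v[3])
      ang[ix, iy] <- atan2(v[2], v[1]) %% pi
    }
  }
  inside <- outer(xc, yc, function(px, py)
    (px - geom$c)^2 + py^2 <= geom$R^2 & (px + geom$c)^2 + py^2 <= geom$R^2)
  structure(
    list(x = xc, y = yc, S = S, angle = ang, nz = nz, n = nn,
         occupancy = occ, inside = inside, occupied = occ > 0 & inside,
         cell_size = cell_size, geom = geom),
    class = "local_order_field"
  )
}

#' @export
print.local_order_field <- function(x, ...) {
  cat(sprintf("Local order field: %d x %d cells of %.3g d, %d occupied\n",
              length(x$x), length(x$y), x$cell_size, sum(x$occupied)))
  if (any(x$occupied))
    cat(sprintf("  scalar order S in [%.3f, %.3f]\n",
                min(x$S[x$occupied]), max(x$S[x$occupied])))
  invisible(x)
}

#' @export
plot.local_order_field <- function(x, what = c("director", "S", "delta"),
                                   ...) {
  what <- match.arg(what)
  geom <- x$geom
  graphics::plot(NA, xlim = range(x$x) + c(-1, 1) * x$cell_size,
                 ylim = range(x$y) + c(-1, 1) * x$cell_size, asp = 1,
                 xlab = "x [d]", ylab = "y [d]", ...)
  tt <- seq(-asin(geom$Ly / (2 * geom$R)), asin(geom$Ly / (2 * geom$R)),
            length.out = 200)
  graphics::lines(geom$R * cos(tt) - geom$c, geom$R * sin(tt))
  graphics::lines(-(geom$R * cos(tt) - geom$c), geom$R * sin(tt))
  idx <- which(x$occupied, arr.ind = TRUE)
  if (what == "director") {
    len <- 0.4 * x$cell_size
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      a <- x$angle[i, j]
      graphics::segments(x$x[i] - len * cos(a), x$y[j] - len * sin(a),
                         x$x[i] + len * cos(a), x$y[j] + len * sin(a))
    }
  } else {
    z <- if (what == "S") x$S else angular_deficit(x)
    zr <- range(z, na.rm = TRUE)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      if (is.na(z[i, j])) next
      f <- if (diff(zr) > 0) (z[i, j] - zr[1]) / diff(zr) else 0
      graphics::rect(x$x[i] - x$cell_size / 2, x$y[j] - x$cell_size / 2,
                     x$x[i] + x$cell_size / 2, x$y[j] + x$cell_size / 2,
                     col = grDevices::gray(1 - f), border = NA)
    }
  }
  invisible(x)
}

# fold an angle difference into (-pi/2, pi/2] (nematic head-tail symmetry)
fold_nematic <- function(dth) dth - pi * round(dth / pi)

#' Angular deficit map
#'
#' For each cell with four occupied neighbours, the angular deficit is the sum
#' of the minimum (nematic) angles between the opposite neighbour directors,
#' \deqn{\delta = \min\angle(n_W, n_E) + \min\angle(n_S, n_N),}
#' where the minimum angle between two directors folds the head-tail symmetry
#' into [0, pi/2]. The deficit vanishes (in radians) for uniform and smoothly
#' bent director fields and is maximal at defect cores; it does not resolve
#' the sign of the defect charge.
#'
#' @param field a \code{\link{local_order_field}}.
#' @return matrix of deficits (radians); NA where fewer than four occupied
#'   neighbours are available.
#' @export
angular_deficit <- function(field) {
  stopifnot(inherits(field, "local_order_field"))
  occ <- field$occupied
  if (sum(occ) < 9) stop("need at least a 3x3 occupied patch")
  nx <- length(field$x); ny <- length(field$y)
  delta <- matrix(NA_real_, nx, ny)
  minang <- function(n1, n2) acos(min(1, abs(sum(n1 * n2))))
  for (j in 2:(ny - 1)) {
    for (i in 2:(nx - 1)) {
      if (!occ[i, j] || !occ[i - 1, j] || !occ[i + 1, j] ||
          !occ[i, j - 1] || !occ[i, j + 1]) next
      delta[i, j] <- minang(field$n[i - 1, j, ], field$n[i + 1, j, ]) +
        minang(field$n[i, j - 1, ], field$n[i, j + 1, ])
    }
  }
  delta
}

# nematic winding number on every 2x2 plaquette of occupied cells; returns an
# (nx-1) x (ny-1) matrix (NA where a corner is unoccupied)
plaquette_winding <- function(field, angle = field$angle) {
  occ <- field$occupied
  nx <- length(field$x); ny <- length(field$y)
  w <- matrix(NA_real_, nx - 1, ny - 1)
  for (j in seq_len(ny - 1)) {
    for (i in seq_len(nx - 1)) {
      if (!occ[i, j] || !occ[i + 1, j] || !occ[i + 1, j + 1] ||
          !occ[i, j + 1]) next
      a <- angle[i, j]; b <- angle[i + 1, j]
      cc <- angle[i + 1, j + 1]; d <- angle[i, j + 1]
      w[i, j] <- (fold_nematic(b - a) + fold_nematic(cc - b) +
                  fold_nematic(d - cc) + fold_nematic(a - d)) / (2 * pi)
    }
  }
  w
}

# Q-tensor smoothing of the director field over occupied 3x3 neighbourhoods;
# gauge-safe (works on n n^T, so director sign flips are irrelevant)
smooth_directors <- function(field) {
  occ <- field$occupied
  nx <- length(field$x); ny <- length(field$y)
  ang <- field$angle
  nn <- field$n
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      if (!occ[i, j]) next
      M <- matrix(0, 3, 3)
      for (dj in -1:1) for (di in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > nx || jj < 1 || jj > ny || !occ[ii, jj]) next
        v <- field$n[ii, jj, ]
        M <- M + tcrossprod(v)
      }
      v <- eigen(M, symmetric = TRUE)$vectors[, 1]
      nn[i, j, ] <- v
      ang[i, j] <- atan2(v[2], v[1]) %% pi
    }
  }
  field$n <- nn
  field$angle <- ang
  field
}

#' Detect topological defects by winding number
#'
#' Finds the point disclinations of a director field. Interior defects are
#' located by the nematic winding number of every 2x2 plaquette of occupied
#' cells (angle increments folded into (-pi/2, pi/2], summed around the loop
#' and divided by 2 pi); plaquettes with |winding| >= 1/4 are clustered into
#' defects whose charge is the cluster winding rounded to the nearest
#' half-integer. Defects whose core sits on the container boundary (including
#' the cusps, where the core can lie outside the occupied grid entirely) are
#' recovered by boundary probes: the occupied cells around a probe point on
#' the wall are ordered by angle, the director rotation is accumulated along
#' the largest interior arc available, and the charge is the rotation per unit
#' swept angle rounded to the nearest half-integer. Boundary candidates must
#' be corroborated by a co-localised depression of the local scalar order
#' (defect cores melt), which suppresses spurious detections driven by
#' distant defects.
#'
#' @param field a \code{\link{local_order_field}}.
#' @param geom container geometry (defaults to the field's own).
#' @param smooth apply gauge-safe 3x3 director smoothing before winding
#'   analysis (default TRUE; recommended for noisy simulation frames).
#' @param probe_radius radius (in d) of the cell neighbourhood used by
#'   boundary probes; default 2.5 cells.
#' @param resid_tol acceptance tolerance (radians RMS) for the boundary-probe
#'   linearity test: a genuine boojum at the probe makes the director angle
#'   grow linearly with the swept azimuth (default 0.30).
#' @param s_dip boundary candidates additionally require a co-localised
#'   depression of the local scalar order (defect cores melt): the minimum S
#'   within two cells of the probe must fall below the median occupied-cell
#'   S by at least this much (default 0.08).
#' @param min_occ_frac cells with occupancy below this fraction of the median
#'   occupied-cell occupancy are ignored: sliver cells crossed by a single
#'   rod tip carry meaningless directors (default 0.15).
#' @return data.frame of class \code{"defect_set"} with columns \code{x},
#'   \code{y}, \code{charge}, \code{locale} (cusp/boundary/interior), sorted
#'   by distance from the container centre. May have zero rows.
#' @export
detect_defects <- function(field, geom = field$geom, smooth = TRUE,
                           probe_radius = 2.5 * field$cell_size,
                           resid_tol = 0.30, s_dip = 0.08,
                           min_occ_frac = 0.15) {
  stopifnot(inherits(field, "local_order_field"))
  if (any(field$occupied)) {
    med_occ <- stats::median(field$occupancy[field$occupied])
    field$occupied <- field$occupied &
      field$occupancy >= min_occ_frac * med_occ
  }
  sm <- if (smooth) smooth_directors(field) else field
  w <- plaquette_winding(sm)
  cs <- field$cell_size

  # --- interior defects: cluster super-threshold plaquettes ---------------
  hits <- which(!is.na(w) & abs(w) >= 0.25, arr.ind = TRUE)
  interior <- list()
  if (nrow(hits) > 0) {
    lab <- integer(nrow(hits))
    nlab <- 0L
    key <- paste(hits[, 1], hits[, 2])
    for (r in seq_len(nrow(hits))) {
      if (lab[r] > 0) next
      nlab <- nlab + 1L
      queue <- r
      lab[r] <- nlab
      while (length(queue)) {
        cur <- queue[[1]]
        queue <- queue[-1]
        nb <- which(abs(hits[, 1] - hits[cur, 1]) <= 1 &
                    abs(hits[, 2] - hits[cur, 2]) <= 1 & lab == 0L)
        lab[nb] <- nlab
        queue <- c(queue, nb)
      }
    }
    for (g in seq_len(nlab)) {
      rows <- which(lab == g)
      ws <- w[cbind(hits[rows, 1], hits[rows, 2])]
      charge <- round(2 * sum(ws)) / 2
      if (charge == 0) next
      px <- field$x[hits[rows, 1]] + cs / 2
      py <- field$y[hits[rows, 2]] + cs / 2
      wt <- abs(ws) / sum(abs(ws))
      interior[[length(interior) + 1L]] <-
        list(x = sum(px * wt), y = sum(py * wt), charge = charge,
             strength = sum(abs(ws)))
    }
  }

  # --- boundary / cusp probes --------------------------------------------
  occ_idx <- which(field$occupied, arr.ind = TRUE)
  med_S <- stats::median(field$S[field$occupied])
  cellx <- field$x[occ_idx[, 1]]
  celly <- field$y[occ_idx[, 2]]
  # probes use the raw angles: 3x3 smoothing flattens the field inside the
  # narrow cusp wedge and would wash out the very rotation being measured
  angs <- field$angle[field$occupied]  # same ordering as occ_idx

  boundary_cells <- boundary_cell_indices(field)
  probes <- list(c(0, geom$Ly / 2), c(0, -geom$Ly / 2))
  for (r in seq_len(nrow(boundary_cells))) {
    i <- boundary_cells[r, 1]; j <- boundary_cells[r, 2]
    p <- project_to_boundary(geom, field$x[i], field$y[j])
    if (!is.null(p)) probes[[length(probes) + 1L]] <- p
  }
  # probes in the cusp region follow the cusp convention: the wall tangent
  # turns by pi - alpha across the cusp, so a defect-free wall-aligned field
  # already carries an apparent negative rotation there; only the +1/2
  # boojum of the bipolar family is a genuine singularity at a cusp
  probe_is_cusp <- vapply(probes, function(p)
    locale_of(p, geom) == "cusp", logical(1))

  cand <- list()
  for (pi_ in seq_along(probes)) {
    p <- probes[[pi_]]
    dx <- cellx - p[1]; dy <- celly - p[2]
    dd <- sqrt(dx^2 + dy^2)
    sel <- dd <= probe_radius & dd > 1e-9
    if (sum(sel) < 4) next
    s_near <- field$S[field$occupied][dd <= 2 * cs + 1e-9]
    if (!length(s_near) || min(s_near) > med_S - s_dip) next
    phi <- atan2(dy[sel], dx[sel])
    o <- order(phi)
    phi <- phi[o]
    th <- angs[sel][o]
    gaps <- diff(c(phi, phi[1] + 2 * pi))
    gmax <- which.max(gaps)
    if (gaps[gmax] < pi / 3) next  # probe is effectively interior
    ord <- seq_along(phi)
    if (gmax < length(phi)) ord <- c((gmax + 1):length(phi), 1:gmax)
    dphi <- 2 * pi - gaps[gmax]
    if (dphi < pi / 3) next  # arc too narrow to estimate a charge
    # unwrapped swept azimuth and accumulated director rotation along the arc
    gaps_along <- gaps[ord][-length(ord)]
    phiu <- cumsum(c(0, gaps_along))
    cum <- cumsum(c(0, fold_nematic(diff(th[ord]))))
    q_ls <- stats::cov(phiu, cum) / stats::var(phiu)
    rms <- sqrt(mean((cum - mean(cum) - q_ls * (phiu - mean(phiu)))^2))
    q <- max(-1, min(1, round(2 * q_ls) / 2))
    if (probe_is_cusp[pi_]) q <- if (q >= 0.5) 0.5 else 0
    if (q == 0 || rms > resid_tol) next
    cand[[length(cand) + 1L]] <-
      list(x = p[1], y = p[2], charge = q, strength = abs(cum[length(cum)]))
  }

  # merge boundary candidates (greedy, strongest first), then drop any that
  # duplicates an interior cluster
  merged <- list()
  if (length(cand)) {
    cand <- cand[order(-vapply(cand, `[[`, numeric(1), "strength"))]
    taken <- logical(length(cand))
    for (a in seq_along(cand)) {
      if (taken[a]) next
      taken[a] <- TRUE
      grp <- cand[[a]]
      for (b in seq_along(cand)) {
        if (taken[b]) next
        if (sqrt((cand[[b]]$x - grp$x)^2 + (cand[[b]]$y - grp$y)^2) <=
            1.6 * cs) taken[b] <- TRUE
      }
      near_int <- any(vapply(interior, function(d)
        sqrt((d$x - grp$x)^2 + (d$y - grp$y)^2) <= 1.6 * cs, logical(1)))
      if (!near_int) merged[[length(merged) + 1L]] <- grp
    }
  }

  all_def <- c(interior, merged)
  if (!length(all_def)) {
    out <- data.frame(x = numeric(0), y = numeric(0), charge = numeric(0),
                      locale = character(0), stringsAsFactors = FALSE)
    class(out) <- c("defect_set", "data.frame")
    return(out)
  }
  out <- data.frame(
    x = vapply(all_def, `[[`, numeric(1), "x"),
    y = vapply(all_def, `[[`, numeric(1), "y"),
    charge = vapply(all_def, `[[`, numeric(1), "charge"),
    stringsAsFactors = FALSE
  )
  out$locale <- vapply(seq_len(nrow(out)), function(k)
    locale_of(c(out$x[k], out$y[k]), geom), character(1))
  out <- out[order(sqrt(out$x^2 + out$y^2)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("defect_set", "data.frame")
  out
}

boundary_cell_indices <- function(field) {
  occ <- field$occupied
  nx <- nrow(occ); ny <- ncol(occ)
  res <- which(occ, arr.ind = TRUE)
  keep <- vapply(seq_len(nrow(res)), function(r) {
    i <- res[r, 1]; j <- res[r, 2]
    if (i == 1 || i == nx || j == 1 || j == ny) return(TRUE)
    !(occ[i - 1, j] && occ[i + 1, j] && occ[i, j - 1] && occ[i, j + 1])
  }, logical(1))
  res[keep, , drop = FALSE]
}

#' Total topological charge of a defect list
#'
#' For any complete pattern on the lens the charges must sum to +1, matching
#' the Euler characteristic of the (disk-topology) container.
#'
#' @param defects a \code{\link{detect_defects}} result (or any data.frame
#'   with a \code{charge} column).
#' @return sum of charges (half-integer; 0 for an empty list).
#' @export
total_charge <- function(defects) {
  if (is.null(defects) || nrow(defects) == 0) return(0)
  sum(defects$charge)
}
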