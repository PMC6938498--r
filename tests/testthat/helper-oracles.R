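# independent oracles used across the suite; deliberately brute-force and
# unrelated to the package's own implementation paths

# minimum distance between two segments by dense parameter-grid search
grid_segment_distance <- function(a0, a1, b0, b1, step = 1e-3) {
  s <- seq(0, 1, by = step)
  t <- seq(0, 1, by = step)
  pa <- outer(s, a1 - a0)  # |s| x 3
  pa <- sweep(pa, 2, a0, "+")
  pb <- outer(t, b1 - b0)
  pb <- sweep(pb, 2, b0, "+")
  best <- Inf
  # block over t to bound memory
  chunk <- 200L
  for (k in seq(1, length(t), by = chunk)) {
    idx <- k:min(length(t), k + chunk - 1L)
    d2 <- outer(pa[, 1], pb[idx, 1], "-")^2 +
      outer(pa[, 2], pb[idx, 2], "-")^2 +
      outer(pa[, 3], pb[idx, 3], "-")^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

# all-pairs hard-core check written against the exported primitives only
allpairs_valid <- function(config) {
  n <- config$n
  h <- config$L / 2
  for (i in seq_len(n)) {
    if (!capsule_inside(config$geom, config$pos[i, ], config$orient[i, ],
                        config$L, config$d))
      return(FALSE)
    if (i < n) {
      for (j in (i + 1):n) {
        if (rods_overlap(config$pos[i, ], config$orient[i, ],
                         config$pos[j, ], config$orient[j, ],
                         config$L, config$d))
          return(FALSE)
      }
    }
  }
  TRUE
}

# hit-or-miss Monte Carlo estimate of the lens cross-section area
mc_lens_area <- function(geom, n = 1e6, seed = 42) {
  set.seed(seed)
  px <- runif(n, -geom$Lx / 2, geom$Lx / 2)
  py <- runif(n, -geom$Ly / 2, geom$Ly / 2)
  hit <- (px - geom$c)^2 + py^2 <= geom$R^2 &
    (px + geom$c)^2 + py^2 <= geom$R^2
  bbox <- geom$Lx * geom$Ly
  p <- mean(hit)
  list(area = bbox * p, se = bbox * sqrt(p * (1 - p) / n))
}

# dense boundary sampling of the lens (xy arcs), for erosion cross-checks
lens_boundary_points <- function(geom, n = 4000) {
  th <- asin(geom$Ly / (2 * geom$R))
  tt <- seq(-th, th, length.out = n)
  rbind(cbind(geom$R * cos(tt) - geom$c, geom$R * sin(tt)),
        cbind(-(geom$R * cos(tt) - geom$c), geom$R * sin(tt)))
}

# build a bare local_order_field from an angle matrix (uniform occupancy)
field_from_angles <- function(ang, cell_size = 10,
                              geom = spindle_geometry(90, 1.5, 6)) {
  nx <- nrow(ang); ny <- ncol(ang)
  nn <- array(NA_real_, c(nx, ny, 3))
  for (j in seq_len(ny)) for (i in seq_len(nx))
    nn[i, j, ] <- c(cos(ang[i, j]), sin(ang[i, j]), 0)
  structure(
    list(x = (seq_len(nx) - (nx + 1) / 2) * cell_size,
         y = (seq_len(ny) - (ny + 1) / 2) * cell_size,
         S = matrix(1, nx, ny), angle = ang %% pi,
         nz = matrix(0, nx, ny), n = nn,
         occupancy = matrix(1, nx, ny),
         inside = matrix(TRUE, nx, ny),
         occupied = matrix(TRUE, nx, ny),
         cell_size = cell_size, geom = geom),
    class = "local_order_field")
}

# mirror a field through x -> -x or y -> -y (directors transform accordingly)
mirror_field <- function(field, axis = c("x", "y")) {
  axis <- match.arg(axis)
  flip <- function(m, margin) {
    if (margin == 1) m[rev(seq_len(nrow(m))), , drop = FALSE]
    else m[, rev(seq_len(ncol(m))), drop = FALSE]
  }
  mar <- if (axis == "x") 1 else 2
  field$S <- flip(field$S, mar)
  field$angle <- (pi - flip(field$angle, mar)) %% pi
  field$nz <- flip(field$nz, mar)
  field$occupancy <- flip(field$occupancy, mar)
  field$inside <- flip(field$inside, mar)
  field$occupied <- flip(field$occupied, mar)
  nn <- field$n
  idx <- if (axis == "x") rev(seq_len(dim(nn)[1])) else seq_len(dim(nn)[1])
  jdx <- if (axis == "y") rev(seq_len(dim(nn)[2])) else seq_len(dim(nn)[2])
  nn <- nn[idx, jdx, , drop = FALSE]
  sgn <- if (axis == "x") c(-1, 1, 1) else c(1, -1, 1)
  for (k in 1:3) nn[, , k] <- nn[, , k] * sgn[k]
  field$n <- nn
  field
}
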