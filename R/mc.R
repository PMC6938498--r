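#' Monte Carlo move parameters
#'
#' Single-particle trial moves combine a uniform displacement in
#' \code{[-dr_max, dr_max]^3} with a rotation by a uniform angle in
#' \code{[0, dtheta_max]} about a uniformly random axis. The defaults target a
#' 30-50 percent acceptance rate at the working volume fraction eta = 0.16.
#' One sweep is N trial moves with the particle chosen uniformly at random,
#' so the sweep count serves as the time proxy of the simulation.
#'
#' @param dr_max translation amplitude (units of d).
#' @param dtheta_max rotation amplitude (radians).
#' @param sweeps number of sweeps to run.
#' @param seed RNG seed recorded into the trajectory.
#' @param sample_every store a frame every this many sweeps.
#' @return list of class \code{"mc_params"}.
#' @export
mc_params <- function(dr_max = 0.5, dtheta_max = 0.1, sweeps = 1000L,
                      seed = 1L, sample_every = 100L) {
  stopifnot(dr_max > 0, dtheta_max > 0, sweeps >= 0, sample_every >= 1)
  structure(list(dr_max = dr_max, dtheta_max = dtheta_max,
                 sweeps = as.integer(sweeps), seed = as.integer(seed),
                 sample_every = as.integer(sample_every)),
            class = "mc_params")
}

#' Attempt one single-particle trial move
#'
#' Reference (pure-R) implementation of the Metropolis step for hard
#' particles: propose displacement + rotation, accept iff no wall violation
#' and no overlap with any other rod. The configuration is returned unchanged
#' on rejection. Uses R's RNG; seed with \code{set.seed}.
#'
#' @param config a \code{\link{rod_config}}.
#' @param index rod index to move (1-based).
#' @param params an \code{\link{mc_params}}.
#' @return list with fields \code{config} (possibly updated) and
#'   \code{accepted} (logical).
#' @export
trial_move <- function(config, index, params = mc_params()) {
  stopifnot(inherits(config, "rod_config"))
  if (index < 1 || index > config$n) stop("'index' out of range")
  r_new <- config$pos[index, ] + stats::runif(3, -params$dr_max, params$dr_max)
  axis <- random_unit_axis()
  ang <- stats::runif(1, 0, params$dtheta_max)
  u_new <- rotate_vec(config$orient[index, ], axis, ang)
  if (!capsule_inside(config$geom, r_new, u_new, config$L, config$d))
    return(list(config = config, accepted = FALSE))
  h <- config$L / 2
  a0 <- r_new - h * u_new
  a1 <- r_new + h * u_new
  for (j in seq_len(config$n)) {
    if (j == index) next
    b0 <- config$pos[j, ] - h * config$orient[j, ]
    b1 <- config$pos[j, ] + h * config$orient[j, ]
    if (min_distance_segments(a0, a1, b0, b1) < config$d)
      return(list(config = config, accepted = FALSE))
  }
  config$pos[index, ] <- r_new
  config$orient[index, ] <- u_new
  list(config = config, accepted = TRUE)
}

random_unit_axis <- function() {
  repeat {
    v <- stats::runif(2, -1, 1)
    s <- sum(v^2)
    if (s < 1 && s > 0) {
      f <- 2 * sqrt(1 - s)
      return(c(v[1] * f, v[2] * f, 1 - 2 * s))
    }
  }
}

rotate_vec <- function(u, k, t) {
  out <- u * cos(t) + cross3(k, u) * sin(t) + k * sum(k * u) * (1 - cos(t))
  out / sqrt(sum(out^2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Run Monte Carlo sweeps and record a trajectory
#'
#' Runs \code{params$sweeps} sweeps of the hard-particle Monte Carlo (one
#' sweep = N single-particle trial moves, cell-list accelerated) and records a
#' frame every \code{params$sample_every} sweeps, always including the initial
#' and final state. The hard-core and inside-wall invariants hold for every
#' emitted frame by construction; runs are reproducible given the seed.
#'
#' @param config a valid \code{\link{rod_config}} starting state.
#' @param params an \code{\link{mc_params}}.
#' @return An object of class \code{"rod_trajectory"}: list with
#'   \code{frames} (each a list with \code{sweep}, \code{pos}, \code{orient}),
#'   \code{geom}, \code{L}, \code{d}, \code{eta}, \code{seed},
#'   \code{acceptance}.
#' @export
run_sweeps <- function(config, params = mc_params()) {
  stopifnot(inherits(config, "rod_config"), inherits(params, "mc_params"))
  if (config$n < 1) stop("refusing to run: empty configuration")
  set.seed(params$seed)
  res <- cpp_run_sweeps(config$pos, config$orient, config$L, config$d,
                        geom_vec(config$geom), params$sweeps, params$dr_max,
                        params$dtheta_max, params$sample_every)
  frames <- lapply(seq_along(res$frame_sweep), function(i) {
    list(sweep = res$frame_sweep[i], pos = res$frames_pos[[i]],
         orient = res$frames_u[[i]])
  })
  structure(
    list(frames = frames, geom = config$geom, L = config$L, d = config$d,
         eta = config$eta, seed = params$seed, params = params,
         acceptance = res$acceptance),
    class = "rod_trajectory"
  )
}

#' @export
print.rod_trajectory <- function(x, ...) {
  ns <- vapply(x$frames, function(f) f$sweep, numeric(1))
  cat(sprintf("MC trajectory: %d frames, sweeps 0..%d, %d rods\n",
              length(x$frames), max(ns), nrow(x$frames[[1]]$pos)))
  cat(sprintf("  container Ly = %g aspect = %.4g h = %g; eta = %.4f; seed = %d\n",
              x$geom$Ly, x$geom$aspect, x$geom$h, x$eta, x$seed))
  if (!is.na(x$acceptance))
    cat(sprintf("  move acceptance = %.3f\n", x$acceptance))
  invisible(x)
}

#' Extract one frame of a trajectory as a configuration
#'
#' @param traj a \code{\link{rod_trajectory}}.
#' @param i frame index (default: last frame).
#' @param validate re-check hard-core invariants (O(N^2)).
#' @return a \code{\link{rod_config}}.
#' @export
frame_config <- function(traj, i = length(traj$frames), validate = FALSE) {
  f <- traj$frames[[i]]
  rod_config(traj$geom, f$pos, f$orient, traj$L, traj$d, validate = validate)
}

#' Global scalar order parameter time series of a trajectory
#'
#' @param traj a \code{\link{rod_trajectory}}.
#' @return data.frame with columns \code{sweep}, \code{S} (global scalar
#'   order), \code{angle_to_y} (angle between the global director and the
#'   major axis, degrees) and \code{nz} (out-of-plane director component).
#' @export
order_series <- function(traj) {
  rows <- lapply(traj$frames, function(f) {
    go <- global_Q(f$orient)
    data.frame(sweep = f$sweep, S = go$S,
               angle_to_y = angle_to_axis_deg(go$n, c(0, 1, 0)),
               nz = abs(go$n[3]))
  })
  do.call(rbind, rows)
}

angle_to_axis_deg <- function(n, axis) {
  ca <- abs(sum(n * axis)) / sqrt(sum(n^2))
  acos(min(1, ca)) * 180 / pi
}
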