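#' Locale of a defect within the container
#'
#' Assigns a detected defect to one of three locales: \code{"cusp"} if it lies
#' within \code{cusp_tol} of a cusp vertex (0, +/- Ly/2), \code{"boundary"} if
#' it lies within \code{boundary_tol} of the lens arc, and \code{"interior"}
#' otherwise. The default tolerances reflect that defect cores and wall
#' layers extend over roughly one rod length.
#'
#' @param p defect position, length-2 vector (x, y).
#' @param geom a \code{\link{spindle_geometry}}.
#' @param cusp_tol distance tolerance around the cusps; default
#'   \code{max(10, 0.05 * Ly)} (half a rod length for the working L = 20 d).
#' @param boundary_tol distance tolerance from the wall; default 10 d.
#' @return one of "cusp", "boundary", "interior".
#' @export
locale_of <- function(p, geom, cusp_tol = max(10, 0.05 * geom$Ly),
                      boundary_tol = 10) {
  stopifnot(cusp_tol > 0, boundary_tol > 0)
  d_cusp <- min(sqrt(p[1]^2 + (p[2] - geom$Ly / 2)^2),
                sqrt(p[1]^2 + (p[2] + geom$Ly / 2)^2))
  if (d_cusp <= cusp_tol) return("cusp")
  d_wall <- min(geom$R - sqrt((p[1] - geom$c)^2 + p[2]^2),
                geom$R - sqrt((p[1] + geom$c)^2 + p[2]^2))
  if (abs(d_wall) <= boundary_tol) return("boundary")
  "interior"
}

# does the director waver ("S"-shape) along the major axis? The signed
# deviation from the major axis, averaged over the cell columns straddling
# x = 0, must change sign with excursions beyond s_wave_tol on both sides.
s_criterion <- function(field, s_wave_tol = 15 * pi / 180) {
  sel <- abs(field$x) <= field$cell_size
  dev <- vapply(seq_along(field$y), function(j) {
    a <- field$angle[sel, j]
    a <- a[!is.na(a)]
    if (!length(a)) return(NA_real_)
    mean(fold_nematic(a - pi / 2))
  }, numeric(1))
  dev <- dev[!is.na(dev)]
  length(dev) > 0 && max(dev) > s_wave_tol && min(dev) < -s_wave_tol
}

#' Classify a director field into the pattern taxonomy
#'
#' Decision tree over the detected defects and the director field:
#' \itemize{
#'   \item 0 defects and mean nematic angle to the major axis below
#'     \code{angle_tol}: homogeneous \code{H}.
#'   \item 2 defects, both at the cusps: bipolar -- \code{B} in a circle
#'     (aspect 1), otherwise \code{S} if the wavy-director criterion fires,
#'     else \code{Bpar}.
#'   \item 2 defects at opposite ends of the minor axis (within
#'     \code{minor_tol}): \code{Dh}.
#'   \item 2 defects with exactly one outside a cusp: \code{Dstar} (or
#'     \code{Sstarstar} when wavy); both outside: \code{Dstarstar} (or
#'     \code{Sstarstar}).
#'   \item more than 2 defects: multi-domain \code{M4} / \code{M6} (other
#'     counts reported as \code{Mn}).
#'   \item anything else: \code{UNKNOWN}.
#' }
#' The wavy ("S") criterion samples the signed director deviation from the
#' major axis along the axis and requires sign-changing excursions beyond
#' \code{s_wave_tol} on both sides.
#'
#' @param field a \code{\link{local_order_field}}.
#' @param geom container geometry (defaults to the field's).
#' @param defects optional precomputed \code{\link{detect_defects}} result.
#' @param angle_tol homogeneous-alignment tolerance, degrees (default 10).
#' @param minor_tol tolerance for the Dh minor-axis test, in d (default
#'   0.1 Lx).
#' @param s_wave_tol wavy-excursion threshold, degrees (default 15).
#' @param ... passed to \code{\link{detect_defects}}.
#' @return list of class \code{"pattern_label"} with fields \code{label},
#'   \code{n_defects} and the \code{defects} table.
#' @export
classify_pattern <- function(field, geom = field$geom, defects = NULL,
                             angle_tol = 10, minor_tol = 0.1 * geom$Lx,
                             s_wave_tol = 15, ...) {
  stopifnot(inherits(field, "local_order_field"))
  if (sum(field$occupied) < 9) stop("field not analyzable (< 3x3 cells)")
  if (is.null(defects)) defects <- detect_defects(field, geom, ...)
  nd <- nrow(defects)
  label <- "UNKNOWN"
  if (nd == 0) {
    devs <- abs(fold_nematic(field$angle[field$occupied] - pi / 2))
    if (mean(devs) * 180 / pi < angle_tol) label <- "H"
  } else if (nd == 2) {
    wavy <- s_criterion(field, s_wave_tol * pi / 180)
    loc <- defects$locale
    ends <- rbind(c(geom$Lx / 2, 0), c(-geom$Lx / 2, 0))
    d_end <- function(k) min(sqrt((defects$x[k] - ends[, 1])^2 +
                                    (defects$y[k] - ends[, 2])^2))
    # the freshly formed Dh pair has not always settled exactly onto the
    # minor-axis ends; two wall defects facing each other across the waist
    # count as Dh as well
    near_waist <- all(loc != "cusp") & all(loc != "interior") &
      all(abs(defects$y) <= 0.25 * geom$Ly)
    at_minor <- sign(defects$x[1]) != sign(defects$x[2]) &&
      ((d_end(1) <= minor_tol && d_end(2) <= minor_tol) || near_waist)
    if (all(loc == "cusp")) {
      label <- if (geom$aspect == 1) "B" else if (wavy) "S" else "Bpar"
    } else if (at_minor) {
      label <- "Dh"
    } else if (sum(loc == "cusp") == 1) {
      label <- if (wavy) "Sstarstar" else "Dstar"
    } else {
      label <- if (wavy) "Sstarstar" else "Dstarstar"
    }
  } else if (nd > 2) {
    label <- if (nd %in% c(4, 6)) paste0("M", nd) else "Mn"
  }
  structure(list(label = label, n_defects = nd, defects = defects),
            class = "pattern_label")
}

#' @export
print.pattern_label <- function(x, ...) {
  cat(sprintf("Pattern: %s (%d defect%s, total charge %+g)\n", x$label,
              x$n_defects, if (x$n_defects == 1) "" else "s",
              total_charge(x$defects)))
  invisible(x)
}

#' Classify an equilibration pathway
#'
#' Classifies the route from the early two-defect (Dh-like) state to the
#' bipolar equilibrium by the metastable intermediates it passes through,
#' read off a majority-filtered defect-count trace: a sustained six-defect
#' multi-domain intermediate marks the \code{"melt"} pathway (a central
#' nematic drop bounded by defect lines), a sustained four-defect
#' intermediate marks \code{"slide"} (defects collectively sliding toward a
#' cusp), and a trace that never exceeds two defects while the defect-pair
#' axis rotates marks \code{"turn"}. Anything else is \code{"other"}.
#'
#' @param counts integer time series of detected defect counts (one entry per
#'   sampled frame, starting after the initial Dh formation and ending at
#'   equilibrium).
#' @param labels optional character series of per-frame pattern labels; used
#'   for the turn test when no axis series is given (a rotating sequence
#'   passes through Dstarstar states).
#' @param axis_angles optional series of the defect-pair axis angle (radians,
#'   nematic) for frames with two defects; the turn pathway requires a net
#'   rotation of at least \code{turn_min_rot}.
#' @param window majority-filter window (odd number of samples, default 3 --
#'   long enough to suppress single-frame detection noise without erasing
#'   short-lived genuine intermediates).
#' @param turn_min_rot minimum net axis rotation for "turn", radians
#'   (default pi/6).
#' @return one of "melt", "slide", "turn", "other".
#' @export
classify_pathway <- function(counts, labels = NULL, axis_angles = NULL,
                             window = 3, turn_min_rot = pi / 6) {
  if (length(counts) < window)
    stop("defect-count series shorter than the majority-filter window")
  filt <- stats::runmed(counts, k = window, endrule = "median")
  m <- max(filt)
  if (m >= 6) return("melt")
  if (m >= 4) return("slide")
  if (m <= 2) {
    if (!is.null(axis_angles)) {
      aa <- axis_angles[is.finite(axis_angles)]
      if (length(aa) >= 2 &&
          abs(sum(fold_nematic(diff(aa)))) >= turn_min_rot)
        return("turn")
      return("other")
    }
    if (!is.null(labels) && any(labels %in% c("Dstarstar", "Sstarstar")))
      return("turn")
  }
  "other"
}

#' Equilibration criteria
#'
#' A trajectory counts as equilibrated once the global scalar order and the
#' global director both look like the bipolar-along-the-major-axis state:
#' S at least \code{S_min} and the director within \code{director_tol}
#' degrees of the major axis, sustained for \code{hold_window} consecutive
#' samples. The defaults make a homogeneous start in a high-aspect spindle
#' register as equilibrated almost immediately.
#'
#' @param S_min scalar-order threshold in (0, 1) (default 0.6).
#' @param director_tol director alignment tolerance, degrees (default 5).
#' @param hold_window number of consecutive samples required (default 10).
#' @return list of class \code{"equilibration_criteria"}.
#' @export
equilibration_criteria <- function(S_min = 0.6, director_tol = 5,
                                   hold_window = 10) {
  stopifnot(S_min > 0, S_min < 1, director_tol > 0, hold_window >= 1)
  structure(list(S_min = S_min, director_tol = director_tol,
                 hold_window = hold_window),
            class = "equilibration_criteria")
}

#' Equilibration time of a trajectory
#'
#' First sweep index at which the global order meets the
#' \code{\link{equilibration_criteria}} and keeps meeting them for
#' \code{hold_window} consecutive samples; \code{Inf} if never.
#'
#' @param traj a \code{\link{rod_trajectory}}, or a data.frame with columns
#'   \code{sweep}, \code{S}, \code{angle_to_y} (as from
#'   \code{\link{order_series}}).
#' @param criteria an \code{\link{equilibration_criteria}}.
#' @return sweep index (numeric; Inf sentinel if never equilibrated).
#' @export
equilibration_time <- function(traj, criteria = equilibration_criteria()) {
  os <- if (inherits(traj, "rod_trajectory")) order_series(traj) else traj
  ok <- os$S >= criteria$S_min & os$angle_to_y <= criteria$director_tol
  hw <- criteria$hold_window
  n <- length(ok)
  if (n == 0) return(Inf)
  if (n < hw) return(if (all(ok)) os$sweep[1] else Inf)
  for (i in seq_len(n - hw + 1)) {
    if (all(ok[i:(i + hw - 1)])) return(os$sweep[i])
  }
  Inf
}

#' Per-frame order and pattern analysis of a trajectory
#'
#' Runs the full analysis stack on every sampled frame: the local
#' length-weighted order field, winding-number defect detection, pattern
#' classification, global order, and the defect-pair axis angle (for
#' two-defect frames).
#'
#' @param traj a \code{\link{rod_trajectory}}.
#' @param cell_size analysis cell edge (default L/2).
#' @param frames indices of frames to analyse (default all).
#' @param ... passed to \code{\link{detect_defects}}.
#' @return data.frame with one row per analysed frame: \code{sweep},
#'   \code{S}, \code{angle_to_y}, \code{n_defects}, \code{charge},
#'   \code{label}, \code{axis} (radians; NA unless two defects) and
#'   \code{dh_sig} (TRUE when a +1/2 wall defect sits in the waist band
#'   |y| <= Ly/4 outside the cusps -- the birth signature of the Dh pair).
#' @export
analyze_trajectory <- function(traj, cell_size = traj$L / 2,
                               frames = seq_along(traj$frames), ...) {
  stopifnot(inherits(traj, "rod_trajectory"))
  rows <- lapply(frames, function(i) {
    cfg <- frame_config(traj, i)
    fld <- local_Q_field(cfg, cell_size)
    def <- detect_defects(fld, traj$geom, ...)
    lab <- classify_pattern(fld, traj$geom, defects = def)
    go <- global_Q(cfg$orient)
    axis <- NA_real_
    if (nrow(def) == 2)
      axis <- atan2(def$y[2] - def$y[1], def$x[2] - def$x[1]) %% pi
    dh_sig <- nrow(def) > 0 &&
      any(def$charge == 0.5 & def$locale != "cusp" &
            abs(def$y) <= 0.25 * traj$geom$Ly)
    data.frame(sweep = traj$frames[[i]]$sweep, S = go$S,
               angle_to_y = angle_to_axis_deg(go$n, c(0, 1, 0)),
               n_defects = nrow(def), charge = total_charge(def),
               label = lab$label, axis = axis, dh_sig = dh_sig,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate and classify one relaxation run from the minor-axis start
#'
#' Convenience wrapper used by the pathway statistics: builds the
#' rods-along-the-minor-axis initial state, runs the Monte Carlo, analyses
#' every sampled frame, measures the formation time of the early Dh pattern
#' and the equilibration time, and classifies the pathway on the slice of the
#' series between the two.
#'
#' @param geom a \code{\link{spindle_geometry}}.
#' @param seed run seed.
#' @param sweeps,sample_every Monte Carlo schedule.
#' @param L,d,eta particle parameters.
#' @param criteria an \code{\link{equilibration_criteria}}.
#' @param cell_size analysis cell edge.
#' @return list with \code{analysis} (per-frame table), \code{t_dh},
#'   \code{t_eq} (sweeps; Inf sentinels if never reached), \code{pathway}
#'   and the \code{trajectory}.
#' @export
pathway_run <- function(geom, seed = 1L, sweeps = 200000L,
                        sample_every = 500L, L = 20, d = 1, eta = 0.16,
                        criteria = equilibration_criteria(),
                        cell_size = L / 2) {
  cfg <- build_initial(geom, "along_minor", eta = eta, L = L, d = d,
                       seed = seed)
  traj <- run_sweeps(cfg, mc_params(sweeps = sweeps, seed = seed + 1L,
                                    sample_every = sample_every))
  an <- analyze_trajectory(traj, cell_size)
  t_eq <- equilibration_time(an, criteria)
  # formation of the Dh state is dated from the birth of its defect
  # signature; the strict per-frame "Dh" label needs both cores above the
  # detection threshold simultaneously, which lags the visible pattern
  sig_idx <- which(an$dh_sig | an$label == "Dh")
  t_dh <- if (length(sig_idx)) an$sweep[sig_idx[1]] else Inf
  dh_idx <- which(an$label == "Dh")
  pathway <- "other"
  lo <- if (length(dh_idx)) dh_idx[1] else 1L
  hi <- if (is.finite(t_eq)) which(an$sweep >= t_eq)[1] else nrow(an)
  if (is.finite(t_eq) && hi - lo + 1 >= 5) {
    sl <- lo:hi
    pathway <- classify_pathway(an$n_defects[sl], labels = an$label[sl],
                                axis_angles = an$axis[sl])
  }
  list(analysis = an, t_dh = t_dh, t_eq = t_eq, pathway = pathway,
       trajectory = traj)
}

#' Pathway frequencies across container sizes
#'
#' Runs \code{n_runs} independently seeded relaxation runs from the
#' minor-axis-aligned start for each container size and tabulates the
#' empirical frequency of the melt/slide/turn/other pathways. Runs that fail
#' to equilibrate within the sweep budget are recorded as "other", never
#' dropped, so frequencies sum to 1 for every geometry.
#'
#' @param Ly_over_L container sizes as multiples of the rod length.
#' @param aspect container aspect ratio (default 1.5).
#' @param n_runs independent runs per size.
#' @param base_seed seeds are \code{base_seed + run index} (distinct per
#'   size).
#' @param L,d,eta,h particle and container parameters.
#' @param sweeps,sample_every Monte Carlo schedule per run.
#' @param criteria an \code{\link{equilibration_criteria}}.
#' @return data.frame with columns \code{Ly_over_L}, \code{pathway},
#'   \code{freq} (frequencies sum to 1 per size), plus attribute
#'   \code{"runs"} holding the per-run records.
#' @export
pathway_statistics <- function(Ly_over_L = c(4.5, 6), aspect = 1.5,
                               n_runs = 3, base_seed = 1L, L = 20, d = 1,
                               eta = 0.16, h = 6, sweeps = 200000L,
                               sample_every = 500L,
                               criteria = equilibration_criteria()) {
  stopifnot(n_runs >= 1)
  runs <- list()
  for (si in seq_along(Ly_over_L)) {
    geom <- spindle_geometry(Ly_over_L[si] * L, aspect = aspect, h = h)
    for (r in seq_len(n_runs)) {
      seed <- base_seed + (si - 1L) * 1000L + r
      pw <- tryCatch(
        pathway_run(geom, seed = seed, sweeps = sweeps,
                    sample_every = sample_every, L = L, d = d, eta = eta,
                    criteria = criteria)$pathway,
        error = function(e) "other")
      runs[[length(runs) + 1L]] <-
        data.frame(Ly_over_L = Ly_over_L[si], run = r, seed = seed,
                   pathway = pw, stringsAsFactors = FALSE)
    }
  }
  runs <- do.call(rbind, runs)
  out <- do.call(rbind, lapply(split(runs, runs$Ly_over_L), function(g) {
    data.frame(
      Ly_over_L = g$Ly_over_L[1],
      pathway = c("melt", "slide", "turn", "other"),
      freq = vapply(c("melt", "slide", "turn", "other"),
                    function(p) mean(g$pathway == p), numeric(1)),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "runs") <- runs
  out
}
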