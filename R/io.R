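#' Run configuration files
#'
#' A run is described by a YAML file with five blocks (all lengths in rod
#' diameters d): \code{geometry} (Ly, aspect, h), \code{particle} (L, d,
#' eta), \code{mc} (dr_max, dtheta_max, sweeps, sample_every, seed),
#' \code{init} (mode, seed) and \code{analysis} (cell_size). Missing keys are
#' filled with the package defaults (which mirror the working parameters:
#' L/d = 20, eta = 0.16, h/d = 6); unknown keys are rejected by name so typos
#' cannot silently change a run.
#'
#' @param path file path.
#' @return \code{read_run_config}: a validated list of class
#'   \code{"run_config"}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param cfg a run-config list (validated on write).
#' @export
write_run_config <- function(cfg, path) {
  cfg <- validate_run_config(unclass(cfg))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

run_config_defaults <- function() {
  list(
    geometry = list(Ly = 90, aspect = 1.5, h = 6),
    particle = list(L = 20, d = 1, eta = 0.16),
    mc = list(dr_max = 0.5, dtheta_max = 0.1, sweeps = 1000L,
              sample_every = 100L, seed = 1L),
    init = list(mode = "along_minor", seed = 1L),
    analysis = list(cell_size = 10)
  )
}

#' @rdname read_run_config
#' @export
validate_run_config <- function(cfg) {
  defaults <- run_config_defaults()
  bad_blocks <- setdiff(names(cfg), names(defaults))
  if (length(bad_blocks))
    stop("unknown config block(s): ", paste(bad_blocks, collapse = ", "))
  out <- defaults
  for (blk in names(cfg)) {
    bad <- setdiff(names(cfg[[blk]]), names(defaults[[blk]]))
    if (length(bad))
      stop("unknown key(s) in block '", blk, "': ",
           paste(bad, collapse = ", "))
    for (key in names(cfg[[blk]])) out[[blk]][[key]] <- cfg[[blk]][[key]]
  }
  with(out$geometry, {
    if (!is.numeric(Ly) || Ly <= 0) stop("geometry.Ly must be positive")
    if (!is.numeric(aspect) || aspect < 1)
      stop("geometry.aspect must be >= 1")
    if (!is.numeric(h) || h <= 0) stop("geometry.h must be positive")
  })
  if (out$particle$eta <= 0 || out$particle$eta >= 1)
    stop("particle.eta must be in (0, 1)")
  if (out$particle$L <= 0 || out$particle$d <= 0)
    stop("particle.L and particle.d must be positive")
  if (!out$init$mode %in% c("along_major", "along_minor", "tilt45",
                            "hedgehog"))
    stop("init.mode must be one of along_major/along_minor/tilt45/hedgehog")
  if (out$mc$sweeps < 0 || out$mc$sample_every < 1)
    stop("mc.sweeps must be >= 0 and mc.sample_every >= 1")
  structure(out, class = "run_config")
}

#' Extended-XYZ trajectory files
#'
#' Each frame is written as: line 1, the rod count N; line 2, space-separated
#' \code{key=value} tokens (sweep, Ly, aspect, h, L, d, eta, seed); then N
#' lines \code{x y z ux uy uz} at full double precision (17 significant
#' digits), so a read-write cycle is bit-identical.
#'
#' @param traj a \code{\link{rod_trajectory}}.
#' @param path output file path.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "rod_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  g <- traj$geom
  for (f in traj$frames) {
    n <- nrow(f$pos)
    header <- sprintf(
      "sweep=%d Ly=%.17g aspect=%.17g h=%.17g L=%.17g d=%.17g eta=%.17g seed=%d",
      f$sweep, g$Ly, g$aspect, g$h, traj$L, traj$d, traj$eta, traj$seed)
    writeLines(as.character(n), con)
    writeLines(header, con)
    m <- cbind(f$pos, f$orient)
    writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r),
                                             collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @return \code{read_trajectory}: a \code{\link{rod_trajectory}}
#'   reconstructed from the file.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  i <- 1L
  frames <- list()
  meta <- NULL
  fidx <- 0L
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop(sprintf("parse error at line %d (after frame %d): expected count",
                   i, fidx))
    n <- as.integer(lines[i])
    fidx <- fidx + 1L
    if (i + 1L > length(lines) || i + 1L + n > length(lines))
      stop(sprintf("truncated file: frame %d incomplete (last good frame %d)",
                   fidx, fidx - 1L))
    toks <- strsplit(strsplit(lines[i + 1L], "\\s+")[[1]], "=")
    kv <- stats::setNames(vapply(toks, `[`, character(1), 2),
                          vapply(toks, `[`, character(1), 1))
    body <- lines[(i + 2L):(i + 1L + n)]
    vals <- lapply(strsplit(trimws(body), "\\s+"), as.numeric)
    if (any(vapply(vals, length, integer(1)) != 6L))
      stop(sprintf("parse error in frame %d: short data line", fidx))
    m <- do.call(rbind, vals)
    frames[[fidx]] <- list(sweep = as.integer(as.numeric(kv[["sweep"]])),
                           pos = m[, 1:3, drop = FALSE],
                           orient = m[, 4:6, drop = FALSE])
    if (is.null(meta)) meta <- kv
    i <- i + 2L + n
  }
  if (!length(frames)) stop("no frames found in ", path)
  geom <- spindle_geometry(as.numeric(meta[["Ly"]]),
                           as.numeric(meta[["aspect"]]),
                           as.numeric(meta[["h"]]))
  structure(
    list(frames = frames, geom = geom, L = as.numeric(meta[["L"]]),
         d = as.numeric(meta[["d"]]), eta = as.numeric(meta[["eta"]]),
         seed = as.integer(as.numeric(meta[["seed"]])), params = NULL,
         acceptance = NA_real_),
    class = "rod_trajectory"
  )
}

#' Field and defect table dumps
#'
#' Writes a local order field as a TSV table (one row per occupied cell:
#' x, y, S, angle, delta, occupancy) with a one-line header, and a defect
#' list as a TSV with columns x, y, charge, locale.
#'
#' @param field a \code{\link{local_order_field}}.
#' @param path output path.
#' @export
write_field_tsv <- function(field, path) {
  stopifnot(inherits(field, "local_order_field"))
  delta <- angular_deficit(field)
  idx <- which(field$occupied, arr.ind = TRUE)
  df <- data.frame(
    x = field$x[idx[, 1]], y = field$y[idx[, 2]],
    S = field$S[idx], angle = field$angle[idx], delta = delta[idx],
    occupancy = field$occupancy[idx])
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_field_tsv
#' @param geom geometry used to rebuild the field grid.
#' @param cell_size cell edge of the dumped field.
#' @return \code{read_field_tsv}: a \code{\link{local_order_field}} (the
#'   angular-deficit column is recomputed on demand and ignored on read).
#' @export
read_field_tsv <- function(path, geom, cell_size) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  nx <- max(3L, ceiling(geom$Lx / cell_size))
  ny <- max(3L, ceiling(geom$Ly / cell_size))
  x0 <- -nx * cell_size / 2
  y0 <- -ny * cell_size / 2
  xc <- x0 + (seq_len(nx) - 0.5) * cell_size
  yc <- y0 + (seq_len(ny) - 0.5) * cell_size
  S <- ang <- nzm <- matrix(NA_real_, nx, ny)
  occ <- matrix(0, nx, ny)
  nn <- array(NA_real_, c(nx, ny, 3))
  for (r in seq_len(nrow(df))) {
    i <- which.min(abs(xc - df$x[r]))
    j <- which.min(abs(yc - df$y[r]))
    S[i, j] <- df$S[r]
    ang[i, j] <- df$angle[r]
    occ[i, j] <- df$occupancy[r]
    nn[i, j, ] <- c(cos(df$angle[r]), sin(df$angle[r]), 0)
    nzm[i, j] <- 0
  }
  inside <- outer(xc, yc, function(px, py)
    (px - geom$c)^2 + py^2 <= geom$R^2 & (px + geom$c)^2 + py^2 <= geom$R^2)
  structure(
    list(x = xc, y = yc, S = S, angle = ang, nz = nzm, n = nn,
         occupancy = occ, inside = inside, occupied = occ > 0 & inside,
         cell_size = cell_size, geom = geom),
    class = "local_order_field"
  )
}

#' @rdname write_field_tsv
#' @param defects a \code{\link{detect_defects}} table.
#' @export
write_defects_tsv <- function(defects, path) {
  utils::write.table(as.data.frame(defects), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
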