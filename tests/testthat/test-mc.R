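test_that("segment-segment distance matches closed forms and a grid oracle", {
  expect_equal(min_distance_segments(c(0, 0, 0), c(1, 0, 0),
                                     c(0, 1, 1), c(1, 1, 1)), sqrt(2))
  expect_equal(min_distance_segments(c(0, 0, 0), c(2, 0, 0),
                                     c(1, -1, 1), c(1, 1, 1)), 1)
  # degenerate segments (points)
  expect_equal(min_distance_segments(c(0, 0, 0), c(0, 0, 0),
                                     c(3, 4, 0), c(3, 4, 0)), 5)
  set.seed(11)
  for (k in 1:5) {
    a0 <- runif(3, -2, 2); a1 <- runif(3, -2, 2)
    b0 <- runif(3, -2, 2); b1 <- runif(3, -2, 2)
    got <- min_distance_segments(a0, a1, b0, b1)
    expect_equal(got, min_distance_segments(b0, b1, a0, a1))  # symmetry
    expect_lt(abs(got - grid_segment_distance(a0, a1, b0, b1)), 1e-3)
  }
})

test_that("spherocylinder overlap criterion is distance below d", {
  r <- c(0, 0, 3); u <- c(0, 1, 0)
  expect_true(rods_overlap(r, u, r, u, L = 20, d = 1))
  expect_false(rods_overlap(r, u, r + c(1.001, 0, 0), u, L = 20, d = 1))
  expect_true(rods_overlap(r, u, r + c(0.999, 0, 0), u, L = 20, d = 1))
})

test_that("trial moves respect walls and overlaps", {
  g <- spindle_geometry(90, aspect = 1.5, h = 6)
  lone <- rod_config(g, matrix(c(0, 0, 3), 1), matrix(c(0, 1, 0), 1))
  set.seed(1)
  res <- trial_move(lone, 1, mc_params(dr_max = 0.1, dtheta_max = 0.01))
  expect_true(res$accepted)

  # rod parked against the waist: a huge proposed displacement must be
  # rejected and leave the configuration untouched
  hug <- rod_config(g, matrix(c(26, 0, 3), 1), matrix(c(0, 1, 0), 1))
  set.seed(2)
  rejected <- FALSE
  for (k in 1:20) {
    res <- trial_move(hug, 1, mc_params(dr_max = 40, dtheta_max = 0.01))
    if (!res$accepted) {
      rejected <- TRUE
      expect_identical(res$config$pos, hug$pos)
      expect_identical(res$config$orient, hug$orient)
    }
    hug <- res$config
  }
  expect_true(rejected)
  expect_error(trial_move(lone, 5), "out of range")

  # vanishing amplitudes: acceptance approaches one even at working density
  cfg <- build_initial(spindle_geometry(45, 1.5, 6), "along_major", seed = 4)
  set.seed(5)
  acc <- 0
  for (k in 1:200) {
    res <- trial_move(cfg, sample.int(cfg$n, 1),
                      mc_params(dr_max = 1e-7, dtheta_max = 1e-7))
    acc <- acc + res$accepted
    cfg <- res$config
  }
  expect_equal(acc, 200)
})

test_that("sweeps preserve hard-core invariants and are reproducible", {
  g <- spindle_geometry(45, aspect = 1.5, h = 6)
  cfg <- build_initial(g, "along_major", eta = 0.16, seed = 9)
  expect_gt(cfg$n, 40)

  p0 <- mc_params(sweeps = 0, seed = 3)
  t0 <- run_sweeps(cfg, p0)
  expect_length(t0$frames, 1)
  expect_identical(t0$frames[[1]]$pos, cfg$pos)

  p <- mc_params(sweeps = 200, seed = 3, sample_every = 40)
  t1 <- run_sweeps(cfg, p)
  t2 <- run_sweeps(cfg, p)
  expect_identical(t1$frames, t2$frames)  # bitwise determinism

  # acceptance strictly inside (0, 1) at the working volume fraction
  expect_gt(t1$acceptance, 0)
  expect_lt(t1$acceptance, 1)

  # every emitted frame passes the all-pairs oracle built on the exported
  # primitives (cross-checks the cell-list acceleration)
  for (i in seq_along(t1$frames)) {
    expect_true(allpairs_valid(frame_config(t1, i)))
    v <- config_violations(frame_config(t1, i))
    expect_equal(v$n_overlap + v$n_wall, 0)
  }
})

test_that("a dilute gas in a circular container samples space uniformly", {
  g <- spindle_geometry(60, aspect = 1, h = 6)  # R = 30
  cfg <- build_initial(g, "along_major", eta = 0.01, seed = 21)
  traj <- run_sweeps(cfg, mc_params(sweeps = 6000, seed = 22,
                                    sample_every = 60))
  # centre-of-mass radii, pooled over frames after a burn-in; restrict to
  # the disk every orientation can reach (r < R - L/2 - d/2)
  rmax <- 30 - 10.5
  rr <- unlist(lapply(traj$frames[-(1:20)], function(f)
    sqrt(f$pos[, 1]^2 + f$pos[, 2]^2)))
  rr <- rr[rr < rmax]
  nb <- 4
  edges <- sqrt(seq(0, rmax^2, length.out = nb + 1))  # equal-area annuli
  counts <- tabulate(findInterval(rr, edges, rightmost.closed = TRUE),
                     nbins = nb)
  expected <- length(rr) / nb
  # 3 sigma of counting noise, inflated for frame-to-frame correlation
  sigma <- sqrt(expected * (1 - 1 / nb)) * 2
  expect_true(all(abs(counts - expected) < 3 * sigma))
})
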