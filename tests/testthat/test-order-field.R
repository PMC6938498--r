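test_that("global tensor order parameter reproduces hand-worked cases", {
  uy <- matrix(rep(c(0, 1, 0), 10), ncol = 3, byrow = TRUE)
  go <- global_Q(uy)
  expect_equal(go$S, 1, tolerance = 1e-12)
  expect_equal(abs(go$n), c(0, 1, 0), tolerance = 1e-8)
  expect_equal(sum(diag(go$Q)), 0, tolerance = 1e-10)

  # 50/50 mix of x and y: eigenvalues (1/4, 1/4, -1/2)
  mix <- rbind(matrix(rep(c(1, 0, 0), 5), ncol = 3, byrow = TRUE), uy[1:5, ])
  gm <- global_Q(mix)
  expect_equal(sort(eigen(gm$Q, symmetric = TRUE)$values),
               c(-0.5, 0.25, 0.25), tolerance = 1e-12)
  expect_equal(gm$S, 0.25, tolerance = 1e-12)

  # isotropic limit: S decays like N^(-1/2)
  set.seed(8)
  v <- matrix(rnorm(3e4), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  expect_lte(global_Q(v)$S, 0.05)

  expect_error(global_Q(matrix(numeric(0), ncol = 3)), "at least one")
})

test_that("segment clipping is exact and additive over a partition", {
  box <- rbind(c(0, 0, 0), c(1, 1, 1))
  expect_equal(segment_length_in_box(c(0.2, 0.5, 0.5), c(0.8, 0.5, 0.5), box),
               0.6)
  # crossing one face at its midpoint: half the length survives
  expect_equal(segment_length_in_box(c(0.5, 0.5, 0.5), c(1.5, 0.5, 0.5), box),
               0.5)
  expect_equal(segment_length_in_box(c(2, 2, 2), c(3, 3, 3), box), 0)

  set.seed(13)
  for (k in 1:5) {
    p0 <- runif(3, -0.5, 1.5); p1 <- runif(3, -0.5, 1.5)
    # numerical-sampling oracle
    tt <- seq(0, 1, length.out = 2e5)
    pts <- outer(tt, p1 - p0); pts <- sweep(pts, 2, p0, "+")
    inb <- pts[, 1] >= 0 & pts[, 1] <= 1 & pts[, 2] >= 0 & pts[, 2] <= 1 &
      pts[, 3] >= 0 & pts[, 3] <= 1
    oracle <- mean(inb) * sqrt(sum((p1 - p0)^2))
    expect_lt(abs(segment_length_in_box(p0, p1, box) - oracle), 1e-3)

    # additivity across the 8 octants of a larger box
    tot <- 0
    for (ix in 0:1) for (iy in 0:1) for (iz in 0:1) {
      sub <- rbind(c(-0.5 + ix, -0.5 + iy, -0.5 + iz),
                   c(0.5 + ix, 0.5 + iy, 0.5 + iz))
      tot <- tot + segment_length_in_box(p0, p1, sub)
    }
    expect_equal(tot, segment_length_in_box(p0, p1,
                                            rbind(c(-0.5, -0.5, -0.5),
                                                  c(1.5, 1.5, 1.5))),
                 tolerance = 1e-10)
  }
})

test_that("local order field conserves length weights and tracks alignment", {
  g <- spindle_geometry(90, aspect = 1.5, h = 6)
  cfg <- build_initial(g, "along_major", seed = 31)
  fld <- local_Q_field(cfg)
  # Eq.-2 weight conservation: total clipped length = N * L
  expect_equal(sum(fld$occupancy), cfg$n * cfg$L, tolerance = 1e-6 * cfg$n)
  occ <- fld$occupied
  expect_true(all(fld$S[occ] > 0.9))
  # local directors agree with the global one in every occupied cell
  ny_dev <- acos(pmin(1, abs(fld$n[, , 2])))[occ] * 180 / pi
  expect_lt(max(ny_dev), 5)

  # a single rod spanning two cells equally: both carry weight L/2 and the
  # same local Q
  one <- rod_config(g, matrix(c(-5, -5, 3), 1), matrix(c(0, 1, 0), 1))
  f1 <- local_Q_field(one, cell_size = 10)
  w <- f1$occupancy[f1$occupancy > 0]
  expect_equal(sort(w), c(10, 10))
  idx <- which(f1$occupancy > 0, arr.ind = TRUE)
  expect_equal(f1$angle[idx[1, 1], idx[1, 2]],
               f1$angle[idx[2, 1], idx[2, 2]], tolerance = 1e-10)

  expect_error(local_Q_field(cfg, cell_size = 0.5), "cell_size")
  expect_error(local_Q_field(cfg, cell_size = 50), "cell_size")

  # random mixed configuration conserves weights too
  cfg2 <- build_initial(g, "tilt45", seed = 32)
  tr <- run_sweeps(cfg2, mc_params(sweeps = 50, seed = 33, sample_every = 50))
  f2 <- local_Q_field(frame_config(tr))
  expect_equal(sum(f2$occupancy), cfg2$n * cfg2$L, tolerance = 1e-6 * cfg2$n)
})

test_that("angular deficit vanishes on uniform fields and peaks at cores", {
  h <- pattern_fixture("H")
  dH <- angular_deficit(h$field)
  expect_true(all(abs(dH[!is.na(dH)]) < 1e-10))

  # hand-worked plaquette: opposite-pair angles 90 deg apart give delta = pi
  ang <- matrix(pi / 2, 3, 3)
  ang[1, 2] <- pi / 2   # W
  ang[3, 2] <- 0        # E
  ang[2, 1] <- 3 * pi / 4  # S
  ang[2, 3] <- pi / 4      # N
  f <- field_from_angles(ang, cell_size = 10)
  expect_equal(angular_deficit(f)[2, 2], pi, tolerance = 1e-12)

  # deficit maxima co-localise with the winding maxima at interior cores
  hh <- pattern_fixture("hedgehog")
  dh <- angular_deficit(hh$field)
  best <- which(dh == max(dh, na.rm = TRUE), arr.ind = TRUE)
  def <- detect_defects(hh$field)
  expect_lt(sqrt((hh$field$x[best[1, 1]] - def$x[1])^2 +
                   (hh$field$y[best[1, 2]] - def$y[1])^2),
            2 * hh$field$cell_size + 1e-9)
})

test_that("winding is zero away from defects and gauge invariant", {
  b <- pattern_fixture("Bpar")$field
  w <- tactoidMC:::plaquette_winding(b)
  expect_true(all(abs(w[!is.na(w)]) < 0.249))  # no interior singularity

  hh <- pattern_fixture("hedgehog")$field
  wh <- tactoidMC:::plaquette_winding(hh)
  expect_equal(sum(wh[!is.na(wh) & abs(wh) >= 0.25]), 1, tolerance = 1e-9)

  # nematic gauge invariance: flipping director signs changes nothing
  flipped <- hh
  set.seed(99)
  idx <- which(flipped$occupied, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    if (runif(1) < 0.5) {
      i <- idx[r, 1]; j <- idx[r, 2]
      flipped$n[i, j, ] <- -flipped$n[i, j, ]
    }
  }
  expect_equal(angular_deficit(flipped), angular_deficit(hh))
  d1 <- detect_defects(hh)
  d2 <- detect_defects(flipped)
  expect_equal(d2$charge, d1$charge)
  expect_equal(d2$x, d1$x)

  # local S always within the physical eigenvalue range
  g <- spindle_geometry(90, 1.5, 6)
  f <- local_Q_field(build_initial(g, "hedgehog", seed = 41))
  expect_true(all(f$S[f$occupied] >= -0.5 & f$S[f$occupied] <= 1 + 1e-12))
})

test_that("the winding detector finds seeded synthetic singularities", {
  g <- spindle_geometry(90, aspect = 1.5, h = 6)
  # single +1/2 seeded in the interior: theta = phi / 2
  sp <- field_spec("seeded", g, rbind(c(0, 0)), 0.5, background_angle = 0)
  f <- synth_field(sp, cell_size = 10)
  d <- detect_defects(f, g)
  expect_equal(nrow(d), 1)
  expect_equal(d$charge, 0.5)
  expect_lt(sqrt(d$x^2 + d$y^2), 10)

  expect_equal(nrow(detect_defects(pattern_fixture("H")$field)), 0)
  expect_equal(total_charge(detect_defects(pattern_fixture("H")$field)), 0)
})
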