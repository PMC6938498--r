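test_that("spindle construction derives the two-circle geometry", {
  g <- spindle_geometry(90, aspect = 1.5, h = 6)
  expect_equal(g$Lx, 60)
  expect_equal(g$R, 48.75)
  expect_equal(g$c, 18.75)
  # the vertices lie on both circles, each waist point on its far circle
  for (p in list(c(0, 45), c(0, -45))) {
    expect_equal(sqrt((p[1] - g$c)^2 + p[2]^2), g$R, tolerance = 1e-12)
    expect_equal(sqrt((p[1] + g$c)^2 + p[2]^2), g$R, tolerance = 1e-12)
  }
  expect_equal(sqrt((30 + g$c)^2), g$R, tolerance = 1e-12)
  expect_equal(sqrt((-30 - g$c)^2), g$R, tolerance = 1e-12)
  g2 <- spindle_geometry(300, aspect = 1.5, h = 6)
  expect_equal(g2$R, 162.5)
  expect_equal(g2$c, 62.5)

  circ <- spindle_geometry(2 * 37, aspect = 1, h = 6)
  expect_equal(circ$c, 0)
  expect_equal(circ$R, 37)
  expect_equal(circ$alpha, 180)

  expect_error(spindle_geometry(90, aspect = 0.5), "aspect")
  expect_error(spindle_geometry(-1, aspect = 2), "Ly")
  expect_error(spindle_geometry(90, 1.5, h = 0), "h")
})

test_that("opening angle relation matches the printed values and inverts", {
  expect_equal(alpha_from_aspect(1), 180)
  expect_equal(alpha_from_aspect(7.59), 30, tolerance = 0.03)
  expect_equal(alpha_from_aspect(1.5), 4 * atan(2 / 3) * 180 / pi,
               tolerance = 1e-12)
  # monotone decreasing
  a <- alpha_from_aspect(seq(1, 20, length.out = 50))
  expect_true(all(diff(a) < 0))
  # inverse identity on [1, 20]
  asp <- seq(1, 20, length.out = 97)
  expect_equal(aspect_from_alpha(alpha_from_aspect(asp)), asp,
               tolerance = 1e-10)
  expect_error(alpha_from_aspect(0.9), "aspect")
  expect_error(aspect_from_alpha(200), "alpha")
})

test_that("point and capsule containment honour the eroded convex region", {
  g <- spindle_geometry(90, aspect = 1.5, h = 6)
  expect_true(contains_point(g, c(0, 0, 3)))
  expect_false(contains_point(g, c(0, 45, 3), margin = 0.5))  # cusp erodes away
  expect_true(contains_point(g, c(0, 45, 3), margin = 0))
  expect_false(contains_point(g, c(60, 0, 3)))  # beyond the waist half-width
  expect_false(contains_point(g, c(0, 0, -1)))

  # rod of L = 20 along the major axis at the centre fits
  expect_true(capsule_inside(g, c(0, 0, 3), c(0, 1, 0), L = 20, d = 1))
  # same rod standing up cannot fit in a 6d-deep slab
  expect_false(capsule_inside(g, c(0, 0, 3), c(0, 0, 1), L = 20, d = 1))
  # one endpoint pushed past a cusp
  expect_false(capsule_inside(g, c(0, 38, 3), c(0, 1, 0), L = 20, d = 1))
})

test_that("erosion test agrees with a dense boundary-distance oracle", {
  g <- spindle_geometry(70, aspect = 2, h = 6)
  bd <- lens_boundary_points(g, 6000)
  set.seed(3)
  n <- 300
  px <- runif(n, -g$Lx / 2, g$Lx / 2)
  py <- runif(n, -g$Ly / 2, g$Ly / 2)
  for (m in c(0.5, 2)) {
    got <- contains_point(g, cbind(px, py, g$h / 2), margin = m)
    inside0 <- contains_point(g, cbind(px, py, g$h / 2), margin = 0)
    dmin <- vapply(seq_len(n), function(k)
      min(sqrt((bd[, 1] - px[k])^2 + (bd[, 2] - py[k])^2)), numeric(1))
    want <- inside0 & dmin >= m
    # exclude probes within a hair of the decision surface (finite boundary
    # sampling cannot resolve them)
    sure <- abs(dmin - m) > 1e-3
    expect_equal(got[sure], want[sure])
  }
})

test_that("lens area, volume and rod counts follow the closed forms", {
  circ <- spindle_geometry(60, aspect = 1, h = 6)
  expect_equal(lens_area(circ), pi * 30^2, tolerance = 1e-10)
  expect_equal(lens_volume(circ), pi * 30^2 * 6, tolerance = 1e-10)

  g <- spindle_geometry(300, aspect = 1.5, h = 6)
  est <- mc_lens_area(g, n = 1e6)
  expect_lt(abs(lens_area(g) - est$area), 3 * est$se)

  # rod count at the working volume fraction lands in the thousands
  N <- count_rods(g, 0.16, L = 20, d = 1)
  N_oracle <- round(0.16 * est$area * g$h / (pi / 4 * 20 + pi / 6))
  expect_lt(abs(N - N_oracle), 6)
  expect_gt(N, 2400)
  expect_lt(N, 2700)

  expect_equal(count_rods(g, 0), 0)
  expect_error(count_rods(g, 1.2), "eta")
})
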