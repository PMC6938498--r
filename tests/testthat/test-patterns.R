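test_that("defect locales follow the geometry-aware tolerances", {
  g <- spindle_geometry(90, aspect = 1.5, h = 6)
  expect_equal(locale_of(c(0, 45), g), "cusp")
  expect_equal(locale_of(c(30, 0), g), "boundary")
  expect_equal(locale_of(c(0, 0), g), "interior")
})

test_that("the classifier labels the full fixture suite perfectly", {
  for (pat in c("H", "B", "Bpar", "Dstar", "Dstarstar", "Dh", "S",
                "Sstarstar", "M4", "M6")) {
    fx <- pattern_fixture(pat)
    lab <- classify_pattern(fx$field)
    expect_equal(lab$label, pat)
    expect_equal(total_charge(lab$defects), if (pat == "H") 0 else 1,
                 label = pat)
  }
})

test_that("classification is invariant under mirrors and gauge flips", {
  for (pat in c("Bpar", "Dh", "Dstarstar", "M6")) {
    f <- pattern_fixture(pat)$field
    base <- classify_pattern(f)$label
    expect_equal(classify_pattern(mirror_field(f, "x"))$label, base,
                 label = paste(pat, "mirror x"))
    expect_equal(classify_pattern(mirror_field(f, "y"))$label, base,
                 label = paste(pat, "mirror y"))
    # global director sign flip
    flip <- f
    flip$n <- -flip$n
    expect_equal(classify_pattern(flip)$label, base,
                 label = paste(pat, "gauge"))
  }
})

test_that("the wavy-director criterion separates S from Bpar", {
  expect_true(tactoidMC:::s_criterion(pattern_fixture("S")$field))
  expect_false(tactoidMC:::s_criterion(pattern_fixture("Bpar")$field))
  expect_false(tactoidMC:::s_criterion(pattern_fixture("H")$field))
})

test_that("pathways are read off the filtered defect-count trace", {
  expect_equal(classify_pathway(c(2, 6, 6, 6, 2, 2)), "melt")
  expect_equal(classify_pathway(c(2, 4, 4, 2, 2)), "slide")
  expect_equal(classify_pathway(c(2, 2, 2, 2),
                                axis_angles = c(0.2, 0.5, 0.9, 1.3)),
               "turn")
  expect_equal(classify_pathway(c(2, 2, 2, 2),
                                axis_angles = rep(1.2, 4)), "other")
  expect_equal(classify_pathway(c(2, 2, 2, 2),
                                labels = c("Dh", "Dstarstar", "Dstarstar",
                                           "Bpar")), "turn")
  # single-frame blips are filtered out
  expect_equal(classify_pathway(c(2, 2, 6, 2, 2, 2),
                                axis_angles = rep(0.1, 6)), "other")
  expect_error(classify_pathway(c(2, 2)), "shorter")
})

test_that("equilibration time is the first sustained threshold crossing", {
  crit <- equilibration_criteria(S_min = 0.6, director_tol = 5,
                                 hold_window = 3)
  ok <- data.frame(sweep = seq(0, 900, by = 100),
                   S = rep(0.9, 10), angle_to_y = rep(1, 10))
  expect_equal(equilibration_time(ok, crit), 0)

  never <- transform(ok, S = 0.2)
  expect_equal(equilibration_time(never, crit), Inf)

  ramp <- data.frame(sweep = seq(0, 900, by = 100),
                     S = c(0.1, 0.2, 0.3, 0.5, 0.65, 0.7, 0.75, 0.8, 0.85,
                           0.9),
                     angle_to_y = rep(2, 10))
  expect_equal(equilibration_time(ramp, crit), 400)

  # a transient excursion above threshold does not count
  blip <- ramp
  blip$S[2] <- 0.9
  expect_equal(equilibration_time(blip, crit), 400)
})

test_that("pathway statistics are proper frequencies", {
  g <- spindle_geometry(90, aspect = 1.5, h = 6)
  # deliberately far-too-short runs: the point is the bookkeeping, and every
  # unequilibrated run must land in "other" rather than being dropped
  tab <- pathway_statistics(Ly_over_L = 4.5, n_runs = 1, base_seed = 77,
                            sweeps = 600L, sample_every = 200L)
  expect_equal(sum(tab$freq), 1)
  expect_true(all(tab$freq %in% c(0, 1)))
  expect_equal(tab$freq[tab$pathway == "other"], 1)
})
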