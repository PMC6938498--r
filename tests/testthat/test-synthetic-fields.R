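fixture_truth <- list(
  H = list(n = 0, q = 0),
  B = list(n = 2, q = 1), Bpar = list(n = 2, q = 1),
  Dstar = list(n = 2, q = 1), Dstarstar = list(n = 2, q = 1),
  Dh = list(n = 2, q = 1),
  S = list(n = 2, q = 1), Sstarstar = list(n = 2, q = 1),
  M4 = list(n = 4, q = 1), M6 = list(n = 6, q = 1)
)

test_that("every pattern fixture carries its specified defect content", {
  for (pat in names(fixture_truth)) {
    fx <- pattern_fixture(pat)
    if (pat != "H") expect_equal(sum(fx$spec$charges), 1)
    d <- detect_defects(fx$field)
    expect_equal(nrow(d), fixture_truth[[pat]]$n, label = pat)
    expect_equal(total_charge(d), fixture_truth[[pat]]$q, label = pat)
  }
  # the multi-domain fixtures realise the printed charge inventories
  m4 <- detect_defects(pattern_fixture("M4")$field)
  expect_equal(sum(m4$charge == 0.5 & m4$locale != "interior"), 3)
  expect_equal(sum(m4$charge == -0.5 & m4$locale == "interior"), 1)
  m6 <- detect_defects(pattern_fixture("M6")$field)
  expect_equal(sum(m6$charge == 0.5 & m6$locale != "interior"), 4)
  expect_equal(sum(m6$charge == -0.5 & m6$locale == "interior"), 2)
})

test_that("field specs validate their defect inventories", {
  g <- spindle_geometry(90, aspect = 1.5, h = 6)
  expect_error(field_spec("bad", g, rbind(c(200, 0)), 0.5), "boundary")
  expect_error(field_spec("bad", g, rbind(c(0, 0)), c(0.5, 0.5)), "charges")
  expect_error(pattern_fixture("nosuch"), "unknown pattern")
})

test_that("angular noise perturbation is the identity at zero and degrades gracefully", {
  b <- pattern_fixture("Bpar")$field
  expect_identical(perturb_field(b, 0), b)

  # 5-degree noise: classification unchanged in at least 95% of seeds
  keep <- 0
  for (s in 1:100) {
    noisy <- perturb_field(b, 5 * pi / 180, seed = s)
    lab <- classify_pattern(noisy)$label
    keep <- keep + (lab == "Bpar")
  }
  expect_gte(keep, 95)

  # 90-degree-scale noise destroys the pattern; any label (incl. UNKNOWN)
  # is acceptable, but classification must not error
  wild <- perturb_field(b, pi / 2, seed = 1)
  expect_no_error(classify_pattern(wild))
})
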