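test_that("dose arithmetic matches the published protocols", {
  expect_equal(dose(illumination_protocol(3.83, 60))$per_cycle, 229.8)
  add <- dose(illumination_protocol(3.83, 4, cycles = 15))
  expect_equal(add$per_cycle, 15.32)
  expect_equal(add$total, 229.8)
  expect_equal(dose(illumination_protocol(3.83, 0))$total, 0)
})

test_that("dose is bilinear in intensity and exposure", {
  base <- dose(illumination_protocol(2, 30))$total
  expect_equal(dose(illumination_protocol(4, 30))$total, 2 * base)
  expect_equal(dose(illumination_protocol(2, 60))$total, 2 * base)
})

test_that("min-max normalization pins 0/1 and is affine invariant", {
  s <- normalize_series(c(-1, 0, 2, 8), c(0, 10, 18, 20))
  expect_equal(s$height_norm, c(0, 0.5, 0.9, 1))
  expect_equal(s$height_pct, c(0, 50, 90, 100))
  s2 <- normalize_series(c(-1, 0, 2, 8), 3 * c(0, 10, 18, 20) + 7)
  expect_equal(s2$height_norm, s$height_norm, tolerance = 1e-12)
  expect_error(normalize_series(c(0, 1), c(5, 5)),
               class = "drusenmorph_invalid")
  expect_error(normalize_series(c(1, 0), c(1, 2)),
               class = "drusenmorph_invalid")
})

test_that("saturating kinetics plateau by 8 h for tau = 2 h", {
  s <- generate_swelling_series(100, 2, c(0, 8, 24))
  ns <- normalize_series(s$time_h, s$height_um)
  expect_gte(ns$height_norm[ns$time_h == 8], 0.98)
})

test_that("apex height recovers a 20 um bulge within one z-step", {
  ref <- generate_focus_stack(76, 0, texture_seed = 7, seed = 1)
  post <- generate_focus_stack(76, 20, texture_seed = 7, seed = 2)
  h <- apex_height(ref, post)
  expect_lt(abs(h$height_um - 20), 4)
  # identical stacks -> zero
  same <- apex_height(ref, ref)
  expect_equal(same$height_um, 0)
  # featureless window errors
  flat <- image_stack(array(1, c(30, 30, 5)), 2, 4)
  expect_error(apex_height(flat, flat), class = "drusenmorph_invalid")
})
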