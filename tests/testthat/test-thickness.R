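test_that("reslice positions follow the 10% rule with 5% offset", {
  st <- image_stack(array(1, c(1000, 20, 3)), 1, 1)
  pl <- reslice_stack(st)
  expect_length(pl, 10)
  expect_equal(vapply(pl, `[[`, 0L, "row"),
               c(50L, 150L, 250L, 350L, 450L, 550L, 650L, 750L, 850L, 950L))
  # degenerate 10-row frame still yields 10 planes, rows by round-half-down
  st10 <- image_stack(array(1, c(10, 20, 3)), 1, 1)
  expect_equal(vapply(reslice_stack(st10), `[[`, 0L, "row"), 0:9)
  # plane count is independent of z depth
  st2 <- image_stack(array(1, c(1000, 20, 7)), 1, 1)
  expect_length(reslice_stack(st2), 10)
  expect_error(reslice_stack(image_stack(array(1, c(9, 20, 3)), 1, 1)),
               class = "drusenmorph_invalid")
})

test_that("profile_height agrees with a literal scan oracle", {
  z_step <- 0.5
  z <- (0:79) * z_step
  set.seed(42)
  for (k in 1:10) {
    b <- runif(1, 3, 8)
    t <- runif(1, 8, 20)
    prof <- exp(-(z - b)^2 / 0.5) + exp(-(z - b - t)^2 / 0.5) +
      rnorm(80, sd = 0.02)
    got <- profile_height(prof, z_step, interpolate = FALSE)
    want <- profile_height_oracle(prof, z_step)
    expect_equal(got[["basal_z"]], want[["basal"]])
    expect_equal(got[["apical_z"]], want[["apical"]])
  }
})

test_that("profile_height handles two-band, flat and single-band profiles", {
  z_step <- 0.25
  z <- seq(0, 40, by = z_step)
  prof <- exp(-(z - 4)^2 / (2 * 0.35^2)) + exp(-(z - 16)^2 / (2 * 0.35^2))
  hz <- profile_height(prof, z_step)
  expect_lt(abs(hz[["basal_z"]] - 4), 1.5)
  expect_lt(abs(hz[["apical_z"]] - 16), 1.5)
  # symmetric bands: height centered on the true 12 um separation
  expect_lt(abs((hz[["apical_z"]] - hz[["basal_z"]]) - 12), 2 * 1.5)
  expect_null(profile_height(rep(0, 100), z_step))
  expect_null(profile_height(rep(3.7, 100), z_step))
  single <- exp(-(z - 10)^2 / (2 * 0.35^2))
  h1 <- profile_height(single, z_step)
  expect_true(is.null(h1) || (h1[["apical_z"]] - h1[["basal_z"]]) < 2)
})

test_that("threshold rule is intensity-scale invariant", {
  z_step <- 0.25
  z <- seq(0, 40, by = z_step)
  set.seed(7)
  prof <- exp(-(z - 6)^2 / 0.4) + exp(-(z - 19)^2 / 0.4) +
    abs(rnorm(length(z), sd = 0.01))
  a <- profile_height(prof, z_step)
  b <- profile_height(prof * 37.5, z_step)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("flat noiseless phantom is measured exactly within one z-step", {
  gen <- flat_phantom(thickness = 12, noise = FALSE)
  m <- measure_monolayer(gen$stack, gen$truth$geometry)
  expect_equal(nrow(m), 100)
  expect_true(all(abs(m$height_um - mean(m$height_um)) < 0.5))
  # central measurement has distance zero
  expect_true(any(m$distance_um == 0))
  # uniform scaling of the phantom scales every height (monotonicity)
  gen2 <- flat_phantom(thickness = 15, noise = FALSE)
  m2 <- measure_monolayer(gen2$stack, gen2$truth$geometry)
  ratio <- m2$height_um / m$height_um
  expect_true(all(abs(ratio - mean(ratio)) < 0.02))
  expect_gt(mean(m2$height_um), mean(m$height_um))
})

test_that("normalize_heights gives per-replicate mean of exactly one", {
  df <- data.frame(replicate_id = rep(c("a", "b"), c(3, 4)),
                   height_um = c(10, 12, 14, 9, 10, 11, 12))
  out <- normalize_heights(df)
  expect_equal(out$height_norm[1:3], c(10, 12, 14) / 12)
  means <- tapply(out$height_norm, out$replicate_id, mean)
  expect_equal(as.numeric(means), c(1, 1), tolerance = 1e-14)
  one <- normalize_heights(data.frame(replicate_id = "x", height_um = 7))
  expect_equal(one$height_norm, 1)
  expect_error(normalize_heights(df[0, ]), class = "drusenmorph_invalid")
})

test_that("medium preset recovers the Top multiplier noiselessly", {
  pre <- drusen_preset("medium-drusen", seed = 1, noise_sd = 0,
                       poisson_noise = FALSE)
  gen <- generate_monolayer_stack(pre$params, pre$geometry)
  m <- normalize_heights(measure_monolayer(gen$stack, pre$geometry))
  s <- region_height_summary(m)
  ratio <- s$mean[s$region == "Top"] / s$mean[s$region == "Outside"]
  expect_lt(abs(ratio - 1.05), 0.01)
})
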