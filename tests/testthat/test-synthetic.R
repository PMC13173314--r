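test_that("generators are pure functions of (params, seed)", {
  pre <- drusen_preset("medium-drusen", seed = 3, frame_size_xy = 100)
  a <- generate_monolayer_stack(pre$params, pre$geometry)
  b <- generate_monolayer_stack(pre$params, pre$geometry)
  expect_identical(a$stack$voxels, b$stack$voxels)

  mp <- mosaic_params(n_cells = 60, frame_size = 150, seed = 9)
  g <- drusen_geometry(c(75, 75), 100)
  expect_identical(generate_cell_mosaic(mp, g)$mask$labels,
                   generate_cell_mosaic(mp, g)$mask$labels)

  tf <- synthetic_traction_field(n = 32, seed = 4)
  p1 <- generate_bead_pair(tf, seed = 5)
  p2 <- generate_bead_pair(tf, seed = 5)
  expect_identical(p1$reference, p1$reference)
  expect_identical(p1$deformed, p2$deformed)

  s1 <- generate_swelling_series(20, 2, c(0, 4, 8), noise_sd = 0.5, seed = 2)
  s2 <- generate_swelling_series(20, 2, c(0, 4, 8), noise_sd = 0.5, seed = 2)
  expect_identical(s1, s2)

  # and the global RNG stream is left untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_monolayer_stack(pre$params, pre$geometry))
  expect_identical(runif(1), before)
})

test_that("phantom ground truth carries the preset effect sizes exactly", {
  for (cond in c("medium-drusen", "large-drusen")) {
    pre <- drusen_preset(cond, seed = 1)
    gen <- generate_monolayer_stack(pre$params, pre$geometry)
    tr <- gen$truth
    mods <- pre$params$thickness_modifiers
    top_mean <- mean(tr$thickness[tr$region == "Top"])
    out_mean <- mean(tr$thickness[tr$region == "Outside"])
    expect_equal(top_mean / out_mean, mods$Top, tolerance = 1e-12)
    edge_mean <- mean(tr$thickness[tr$region == "Edge"])
    expect_equal(edge_mean / out_mean, mods$Edge, tolerance = 1e-12)
  }
  # all modifiers 1, noise off -> thickness everywhere equals baseline
  p <- monolayer_params(frame_size_xy = 100, noise_sd = 0,
                        poisson_noise = FALSE, seed = 1)
  g <- drusen_geometry(c(50, 50), 100)
  gen <- generate_monolayer_stack(p, g)
  expect_true(all(gen$truth$thickness == p$baseline_thickness))
})

test_that("stack generation rejects unrepresentable apex heights", {
  p <- monolayer_params(frame_size_xy = 100, z_depth = 20,
                        bulge_apex_height = 30, seed = 1)
  g <- drusen_geometry(c(50, 50), 100)
  expect_error(generate_monolayer_stack(p, g),
               class = "drusenmorph_invalid")
})

test_that("mosaic ground truth has the stated orientation structure", {
  g <- drusen_geometry(c(150, 150), 100)
  ring <- generate_cell_mosaic(
    mosaic_params(n_cells = 300, frame_size = 300, seed = 11,
                  orientation_field = "circumferential_ring",
                  ring_radii = c(25, 50)), g)
  oriented <- ring$truth[ring$truth$class == "oriented", ]
  expect_gt(nrow(oriented), 5)
  expect_gte(median(oriented$angle_to_origin), 80)

  cap <- generate_cell_mosaic(
    mosaic_params(n_cells = 300, frame_size = 300, seed = 11,
                  orientation_field = "radial_cap", cap_radius = 40), g)
  cap_cells <- cap$truth[cap$truth$class == "oriented", ]
  expect_lte(median(cap_cells$angle_to_origin), 10)

  # unimodal generator areas classify as unimodal
  uni <- generate_cell_mosaic(
    mosaic_params(n_cells = 400, frame_size = 340, seed = 13), g)
  cls <- classify_modality(uni$truth$target_area_um2 /
                             mean(uni$truth$target_area_um2))
  expect_equal(cls$classification, "unimodal")
})

test_that("mosaic realized areas match the recorded ground truth", {
  g <- drusen_geometry(c(100, 100), 100)
  mos <- generate_cell_mosaic(
    mosaic_params(n_cells = 120, frame_size = 200, seed = 21), g)
  rec <- measure_cells(mos$mask, g)
  m <- merge(rec[!rec$border, ], mos$truth, by = "label")
  expect_gt(nrow(m), 50)
  expect_lt(max(abs(m$area / m$area_um2 - 1)), 0.02)
})

test_that("zero traction gives identical noiseless bead images", {
  tf <- list(tx = matrix(0, 32, 32), ty = matrix(0, 32, 32), spacing = 4)
  bp <- generate_bead_pair(tf, noise_sd = 0, seed = 31)
  expect_identical(bp$reference, bp$deformed)
})

test_that("a central pressure disc displaces beads radially, decaying outward", {
  n <- 64; sp <- 4
  ax <- (seq_len(n) - 1) * sp
  ctr <- (n - 1) * sp / 2
  X <- outer(rep(1, n), ax) - ctr
  Y <- outer(ax, rep(1, n)) - ctr
  r <- sqrt(X^2 + Y^2)
  amp <- 100 * exp(-r^2 / (2 * 20^2))
  rr <- pmax(r, 1e-9)
  # inward radial traction disc
  d <- forward_displacement(-amp * X / rr, -amp * Y / rr, sp, 4000, 0.5)
  mag <- sqrt(d$ux^2 + d$uy^2)
  # radially binned magnitude decays beyond the disc rim
  bins <- cut(as.vector(r), breaks = seq(40, 120, by = 10))
  prof <- tapply(as.vector(mag), bins, mean)
  expect_true(all(diff(prof) < 0))
})

test_that("swelling and indentation generators satisfy their closed forms", {
  s <- generate_swelling_series(100, 2, c(0, 1e6))
  expect_equal(s$height_um[1], 0)
  expect_equal(s$height_um[2], 100, tolerance = 1e-9)
  cur <- generate_indentation_curve(4000, 10, 3.5)
  expect_equal(cur$force_nN[1], 0)
  # hand-computed closed form at full depth: (4/3)*4000*sqrt(1e-5)*(3.5e-6)^1.5
  expect_equal(max(cur$force_nN), 110.4335, tolerance = 1e-4)
  cur2 <- generate_indentation_curve(8000, 10, 3.5)
  expect_equal(cur2$force_nN, 2 * cur$force_nN, tolerance = 1e-12)
})
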