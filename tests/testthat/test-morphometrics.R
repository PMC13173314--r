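test_that("shape factor hits closed forms for square and disc", {
  g <- drusen_geometry(c(1000, 1000), 100)
  sq <- measure_cells(label_mask(square_mask(40, 10, 16, 16), 1), g)
  expect_equal(sq$area, 100)
  expect_lt(abs(sq$shape_factor - 4) / 4, 0.05)

  dc <- measure_cells(label_mask(disc_mask(120, 50), 1), g)
  expect_lt(abs(dc$shape_factor - 2 * sqrt(pi)) / (2 * sqrt(pi)), 0.05)
})

test_that("shape factor is scale invariant within pixelation tolerance", {
  g <- drusen_geometry(c(1000, 1000), 100)
  s1 <- measure_cells(label_mask(disc_mask(80, 25), 1), g)$shape_factor
  s2 <- measure_cells(label_mask(disc_mask(160, 50), 1), g)$shape_factor
  expect_lt(abs(s2 / s1 - 1), 0.02)
})

test_that("angle_to_origin spans [0, 90] with the documented limits", {
  # axis along the centroid->center line -> 0; perpendicular -> 90
  expect_equal(angle_to_origin(0, c(50, 100), c(100, 100)), 0)
  expect_equal(angle_to_origin(90, c(50, 100), c(100, 100)), 90)
  # axial equivalence: 170 deg is the same axis as -10
  expect_equal(angle_to_origin(170, c(50, 100), c(100, 100)),
               angle_to_origin(10, c(50, 100), c(100, 100)))
  # dense orientation grid stays inside [0, 90]; with the centroid offset
  # along an axis the 1-degree grid contains the exact extremes
  th <- angle_to_origin(0:179, matrix(rep(c(30, 100), 180), ncol = 2,
                                      byrow = TRUE), c(100, 100))
  expect_true(all(th >= 0 & th <= 90))
  expect_equal(max(th), 90)
  expect_equal(min(th), 0)
  # undefined at the center
  expect_true(is.na(angle_to_origin(45, c(100, 100), c(100, 100))))
})

test_that("mean angle under uniform random orientations approaches 45 deg", {
  set.seed(5)
  th <- runif(1e5, 0, 180)
  ang <- angle_to_origin(th, matrix(rep(c(10, 10), 1e5), ncol = 2,
                                    byrow = TRUE), c(300, 250))
  expect_lt(abs(mean(ang) - 45), 1)
})

test_that("orientation and angle metric are invariant under 90-deg rotation", {
  g0 <- drusen_geometry(c(20, 20), 100)
  mos <- generate_cell_mosaic(
    mosaic_params(n_cells = 40, frame_size = 120, seed = 17,
                  elongation = 2.5), drusen_geometry(c(60, 60), 100))
  lab <- mos$mask$labels
  # rotation about the array center: physical fixed point of a 240-px
  # frame at pitch 1 is (119.5, 119.5)
  ctr <- rep((nrow(lab) - 1) / 2, 2)
  rec <- measure_cells(label_mask(lab, 1), drusen_geometry(ctr, 100))
  lab90 <- t(lab)[rev(seq_len(ncol(lab))), ]
  rec90 <- measure_cells(label_mask(lab90, 1), drusen_geometry(ctr, 100))
  m <- merge(rec, rec90, by = "label", suffixes = c("", ".rot"))
  # orientation is only defined for anisotropic cells
  m <- m[!m$border & !m$border.rot & !is.na(m$angle_to_origin) &
           m$aspect_ratio > 1.3, ]
  expect_gt(nrow(m), 10)
  expect_lt(max(abs(m$angle_to_origin - m$angle_to_origin.rot)), 2)
  expect_equal(m$area, m$area.rot)
})

test_that("region counts partition assigned cells without double counting", {
  g <- drusen_geometry(c(150, 150), 100)
  mos <- generate_cell_mosaic(
    mosaic_params(n_cells = 250, frame_size = 300, seed = 23), g)
  rec <- measure_cells(mos$mask, g)
  tab <- table(rec$region)
  expect_equal(sum(tab), nrow(rec))
  expect_setequal(setdiff(names(tab), "unassigned"),
                  c("Top", "Edge", "Outside"))
})

test_that("measure_cells handles empty and tiny labels", {
  g <- drusen_geometry(c(10, 10), 100)
  empty <- measure_cells(label_mask(matrix(0L, 20, 20), 1), g)
  expect_equal(nrow(empty), 0)
  tiny <- matrix(0L, 20, 20); tiny[5, 5] <- 1L; tiny[10:13, 10:13] <- 2L
  rec <- measure_cells(label_mask(tiny, 1), g)
  expect_equal(rec$label, 2L)
  expect_equal(attr(rec, "n_skipped"), 1L)
})

test_that("area_distribution normalizes and finds modes", {
  set.seed(31)
  rec <- data.frame(area = rlnorm(400, log(200), 0.25), border = FALSE,
                    region = "Top")
  rec <- normalize_areas(rec)
  ad <- area_distribution(rec, region = "Top")
  expect_equal(sum(ad$rel_freq), 1, tolerance = 1e-9)
  expect_equal(count_density_modes(ad$density, min_prominence = 0.2), 1)
  # well separated mixture shows two modes (evaluable analytically)
  x <- c(rlnorm(300, log(0.6), 0.12), rlnorm(300, log(1.8), 0.12))
  rec2 <- data.frame(area = x, area_normalized = x / mean(x),
                     border = FALSE, region = "Top")
  ad2 <- area_distribution(rec2, region = "Top")
  expect_equal(count_density_modes(ad2$density, min_prominence = 0.2), 2)
})
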