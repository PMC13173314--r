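test_that("region specs match the two characterized conditions", {
  s100 <- make_region_spec(100)
  expect_equal(s100$name, c("Top", "Edge", "Outside"))
  expect_equal(s100$inner, c(0, 25, 150))
  expect_equal(s100$outer, c(25, 50, 175))

  s300 <- make_region_spec(300)
  expect_equal(s300$inner, c(0, 125, 150))
  expect_equal(s300$outer, c(25, 150, 175))
})

test_that("generic diameter rule applies and rejects Top/Edge collisions", {
  s200 <- make_region_spec(200)
  expect_equal(s200$inner[s200$name == "Edge"], 75)
  expect_equal(s200$outer[s200$name == "Edge"], 100)
  expect_error(make_region_spec(50), class = "drusenmorph_invalid")
  expect_error(make_region_spec(40), class = "drusenmorph_invalid")
  expect_error(make_region_spec(-10), class = "drusenmorph_invalid")
})

test_that("assign_region bins by distance with half-open boundaries", {
  g <- drusen_geometry(c(0, 0), 100)
  s <- make_region_spec(100)
  expect_equal(assign_region(c(10, 0), g, s), "Top")
  expect_equal(assign_region(c(0, -130), drusen_geometry(c(0, 0), 300),
                             make_region_spec(300)), "Edge")
  expect_equal(assign_region(c(200, 0), g, s), "unassigned")
  # boundary exactly at 25 um belongs to Edge, never Top
  expect_equal(assign_region(c(25, 0), g, s), "Edge")
  expect_equal(assign_region(c(0, 175), g, s), "unassigned")
})

test_that("annuli are disjoint on a fine radius grid and rotation invariant", {
  for (D in c(100, 300)) {
    s <- make_region_spec(D)
    r <- seq(0, 200, by = 0.1)
    hits <- sapply(seq_len(nrow(s)),
                   function(i) r >= s$inner[i] & r < s$outer[i])
    expect_true(all(rowSums(hits) <= 1))
  }
  g <- drusen_geometry(c(50, 50), 100)
  s <- make_region_spec(100)
  for (ang in seq(0, 2 * pi, length.out = 13)) {
    p <- c(50 + 30 * cos(ang), 50 + 30 * sin(ang))
    expect_equal(assign_region(p, g, s), "Edge")
  }
})

test_that("region_spec validates overlap and ordering", {
  expect_error(region_spec(c("A", "B"), c(0, 20), c(25, 40)),
               class = "drusenmorph_invalid")
  expect_error(region_spec("A", 10, 10), class = "drusenmorph_invalid")
  expect_error(region_spec(c("A", "A"), c(0, 30), c(25, 40)),
               class = "drusenmorph_invalid")
  expect_s3_class(region_spec(c("A", "B"), c(0, 25), c(25, 50)),
                  "region_spec")
})
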