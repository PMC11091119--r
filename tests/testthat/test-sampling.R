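test_that("grid points sit half a spacing inside the extent", {
  ext <- c(xmin = 0, ymin = 0, xmax = 400, ymax = 400)
  g <- make_grid(ext, 200)
  expect_identical(nrow(g), 4L)
  expect_setequal(paste(g$x, g$y),
                  c("100 100", "100 300", "300 100", "300 300"))

  # halving the spacing roughly quadruples the count
  big <- c(xmin = 0, ymin = 0, xmax = 5000, ymax = 5000)
  n200 <- nrow(make_grid(big, 200))
  n100 <- nrow(make_grid(big, 100))
  expect_gt(n100 / n200, 3.5)
  expect_lt(n100 / n200, 4.5)

  # all points strictly inside
  g2 <- make_grid(c(xmin = 3, ymin = -7, xmax = 1003, ymax = 493), 150)
  expect_true(all(g2$x > 3 & g2$x < 1003 & g2$y > -7 & g2$y < 493))

  expect_warning(make_grid(c(xmin = 0, ymin = 0, xmax = 90, ymax = 90), 200),
                 "single-point")
  expect_error(make_grid(c(xmin = 0, ymin = 0, xmax = 0, ymax = 90), 200),
               "degenerate")
})

test_that("elevation extraction equals containing-cell lookup", {
  z <- matrix(as.numeric(1:20), 4, 5)
  dem <- elevation_grid(z, cell_size = 10, xll = 100, yll = 200)
  # a point at a cell centre takes that cell's value
  pt <- data.frame(point_id = 1L, x = 105, y = 235)   # col 1, top row
  expect_equal(extract_elevation(pt, dem)$elevation, z[1, 1])

  cdem <- elevation_grid(matrix(7, 3, 3), 5)
  pts <- data.frame(point_id = 1:4, x = c(1, 7, 13, 8), y = c(1, 7, 13, 2))
  expect_true(all(extract_elevation(pts, cdem)$elevation == 7))

  # brute-force index arithmetic oracle on random points
  set.seed(42)
  rp <- data.frame(point_id = 1:100,
                   x = stats::runif(100, 100, 150),
                   y = stats::runif(100, 200, 240))
  got <- extract_elevation(rp, dem)
  oracle <- vapply(seq_len(nrow(rp)), function(i) {
    col <- floor((rp$x[i] - 100) / 10) + 1
    row <- 4 - floor((rp$y[i] - 200) / 10)
    z[row, col]
  }, numeric(1))
  expect_equal(got$elevation, oracle)

  # points outside the footprint are dropped with a message
  expect_message(
    out <- extract_elevation(data.frame(point_id = 1:2,
                                        x = c(105, 9999), y = c(235, 235)),
                             dem),
    "dropping 1")
  expect_identical(nrow(out), 1L)
})

test_that("aspect of tilted planes matches the closed-form gradient", {
  n <- 11
  # plane dipping due south: z increases northward (row 1 highest)
  south <- elevation_grid(outer(seq(100, 0, length.out = n), rep(1, n)), 10)
  a <- compute_aspect(south)
  expect_true(all(abs(a$z[2:(n - 1), 2:(n - 1)] - 180) < 1e-9))

  # plane dipping due east: z decreases with column
  east <- elevation_grid(outer(rep(1, n), seq(100, 0, length.out = n)), 10)
  a2 <- compute_aspect(east)
  expect_true(all(abs(a2$z[2:(n - 1), 2:(n - 1)] - 90) < 1e-9))

  # horizontal plane is flat everywhere
  flat <- compute_aspect(elevation_grid(matrix(5, n, n), 10))
  expect_true(all(is.na(flat$z)))

  expect_error(compute_aspect(elevation_grid(matrix(NA_real_, 5, 5), 10)),
               "nodata")
  expect_error(compute_aspect(elevation_grid(matrix(1:4, 2, 2), 10)),
               "3 x 3")
})

test_that("sunny covers [112.5, 292.5) and flat is shady", {
  expect_identical(classify_aspect(180), "sunny")
  expect_identical(classify_aspect(0), "shady")
  expect_identical(classify_aspect(NA_real_), "shady")
  expect_identical(classify_aspect(112.5), "sunny")
  expect_identical(classify_aspect(292.5), "shady")
  expect_identical(classify_aspect(112.4999), "shady")
  expect_identical(classify_aspect(292.4999), "sunny")
})

test_that("unit assignment uses left-closed elevation classes and zones", {
  scheme <- structure(list(
    deciduous_broadleaf = structure(
      list(forest_type = "deciduous_broadleaf", main_range = c(250, 1050),
           threshold_pct = 26.32, core = c(550, 900),
           lower = c(-Inf, 550), upper = c(900, Inf)),
      class = "zone_entry")),
    class = "zone_scheme")
  pts <- data.frame(
    elevation = c(549.9, 550, 716, 901, 1100, 1350),
    aspect_class = c("sunny", "shady", "sunny", "shady", "sunny", "shady"),
    forest_type = "deciduous_broadleaf")
  out <- assign_units(pts, scheme = scheme)
  expect_identical(out$elev_class,
                   c("<550", "550-900", "550-900", "900-1100", "1100-1350",
                     ">=1350"))
  expect_identical(out$zone[3], "core")
  expect_identical(out$zone[1], "lower")
  expect_identical(out$zone[4], "upper")
  expect_identical(out$unit_id[1], "<550|sunny")
})

test_that("unit counts agree with a brute-force group-by", {
  set.seed(8)
  pts <- data.frame(
    elevation = stats::runif(500, 200, 1500),
    aspect_class = sample(c("sunny", "shady"), 500, replace = TRUE),
    forest_type = sample(forest_types(), 500, replace = TRUE))
  out <- assign_units(pts)
  got <- table(out$unit_id)
  edges <- default_elev_classes()
  lab <- c("<550", "550-900", "900-1100", "1100-1350", ">=1350")
  brute <- table(paste(lab[findInterval(pts$elevation, edges) + 1],
                       pts$aspect_class, sep = "|"))
  expect_equal(as.vector(got[names(brute)]), as.vector(brute))
})

test_that("shifting DEM and extent together preserves extracted elevations", {
  cfg <- synthetic_config(n_rows = 40, n_cols = 40, seed = 3)
  dem <- generate_dem(cfg)
  shifted <- dem
  shifted$xll <- dem$xll + 1234
  shifted$yll <- dem$yll - 567
  a <- extract_elevation(make_grid(grid_extent(dem), 120), dem)
  b <- extract_elevation(make_grid(grid_extent(shifted), 120), shifted)
  expect_equal(sort(a$elevation), sort(b$elevation))
})

test_that("sample_points builds a complete attributed table", {
  cfg <- synthetic_config(n_rows = 80, n_cols = 80, seed = 4)
  dem <- generate_dem(cfg)
  st <- classify_stand_map(generate_stand_map(cfg, dem))
  prof <- bin_proportions(st, dem)
  scheme <- suppressWarnings(zone_scheme(prof))
  pts <- sample_points(dem, st, scheme, spacing = 100)
  expect_true(all(c("point_id", "x", "y", "elevation", "aspect_deg",
                    "aspect_class", "forest_type", "elev_class", "unit_id",
                    "zone") %in% names(pts)))
  expect_true(all(pts$aspect_class %in% c("sunny", "shady")))
  expect_true(all(is.na(pts$zone) == (pts$forest_type == "nonforest")))
  # zone labels agree with the scheme at each point's elevation
  for (tp in names(scheme)) {
    sel <- pts$forest_type == tp
    expect_identical(pts$zone[sel], zone_of(pts$elevation[sel], scheme[[tp]]))
  }
})
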