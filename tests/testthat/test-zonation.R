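test_that("bin proportions count type areas per 50 m bin", {
  dem <- elevation_grid(matrix(c(510, 560, 560, 610), 1, 4), 10)
  st <- make_stand_map(rep("x", 4), 1, 4, dominant = rep("PIN", 4),
                       forest_type = c("temperate_conifer",
                                       "temperate_conifer",
                                       "deciduous_broadleaf", "mixed"))
  st$composition <- c("10PIN", "10PIN", "10QUE", "5QUE5PIN")
  prof <- bin_proportions(st, dem)
  get <- function(low, tp) {
    prof$area_pct[prof$bin_low_m == low & prof$forest_type == tp]
  }
  expect_equal(get(500, "temperate_conifer"), 100)
  expect_equal(get(550, "temperate_conifer"), 50)
  expect_equal(get(550, "deciduous_broadleaf"), 50)
  expect_equal(get(600, "mixed"), 100)
  expect_equal(get(500, "mixed"), 0)
})

test_that("bin proportions are zero on nonforest maps and scale-invariant", {
  dem <- elevation_grid(matrix(c(510, 560, 560, 610), 1, 4), 10)
  st <- make_stand_map(rep("", 4), 1, 4,
                       forest_type = rep("nonforest", 4))
  prof <- bin_proportions(st, dem)
  expect_true(all(prof$area_pct == 0))

  # duplicating every cell leaves percentages unchanged
  dem2 <- elevation_grid(matrix(rep(c(510, 560, 560, 610), 2), 1, 8), 10)
  st2 <- make_stand_map(rep("x", 8), 1, 8, dominant = rep("PIN", 8),
                        forest_type = rep(c("temperate_conifer",
                                            "temperate_conifer",
                                            "deciduous_broadleaf", "mixed"),
                                          2))
  st1 <- make_stand_map(rep("x", 4), 1, 4, dominant = rep("PIN", 4),
                        forest_type = c("temperate_conifer",
                                        "temperate_conifer",
                                        "deciduous_broadleaf", "mixed"))
  p1 <- bin_proportions(st1, dem)
  p2 <- bin_proportions(st2, dem2)
  expect_equal(p1$area_pct, p2$area_pct)
})

test_that("main range picks the longest qualifying run with tie-breaks", {
  prof <- make_profile(list(a = c(2, 15, 30, 28, 3)))
  expect_equal(main_range(prof, "a", floor_pct = 10), c(550, 700))

  # uniform above floor -> the whole profile
  prof2 <- make_profile(list(a = rep(20, 5)))
  expect_equal(main_range(prof2, "a", floor_pct = 10), c(500, 750))

  # equal-length runs: the one holding the higher peak wins
  prof3 <- make_profile(list(a = c(15, 20, 5, 15, 40, 5)))
  expect_equal(main_range(prof3, "a", floor_pct = 10), c(650, 750))
  # fully tied -> lower elevation run
  prof4 <- make_profile(list(a = c(15, 40, 5, 15, 40, 5)))
  expect_equal(main_range(prof4, "a", floor_pct = 10), c(500, 600))

  expect_error(main_range(prof, "a", floor_pct = 60), "floor_pct")
  # explicit override is passed through (bin-edge aligned)
  expect_equal(main_range(prof, "a", override = c(550, 700)), c(550, 700))
  expect_error(main_range(prof, "a", override = c(551, 700)), "bin edges")
})

test_that("zone threshold is the unweighted mean unless fixed", {
  prof <- make_profile(list(a = c(10, 30, 40, 20)))
  expect_equal(zone_threshold(prof, "a", c(500, 700)), 25)
  expect_equal(zone_threshold(prof, "a", c(500, 700), fixed = 30), 30)
  profc <- make_profile(list(a = rep(17.5, 6)))
  expect_equal(zone_threshold(profc, "a", c(500, 800)), 17.5)

  set.seed(11)
  pct <- stats::runif(16, 0, 60)
  prof16 <- make_profile(list(a = pct))
  expect_equal(zone_threshold(prof16, "a", c(500, 500 + 16 * 50)),
               sum(pct) / 16)
  expect_error(zone_threshold(prof, "a", c(500, 500)), "zero bins")
})

test_that("delineation yields core flanked by open extension zones", {
  prof <- make_profile(list(a = c(10, 30, 40, 20)))
  e <- delineate_zones(prof, "a", c(500, 700), 25)
  expect_equal(e$core, c(550, 650))
  expect_equal(e$lower, c(-Inf, 550))
  expect_equal(e$upper, c(650, Inf))

  # all bins above threshold -> core covers the whole range
  e2 <- delineate_zones(prof, "a", c(500, 700), 5)
  expect_equal(e2$core, c(500, 700))

  expect_error(delineate_zones(prof, "a", c(500, 700), 50), "exceeds")

  # isolated super-threshold bin outside the core run is warned about
  prof3 <- make_profile(list(a = c(30, 5, 10, 30, 40, 20)))
  expect_warning(e3 <- delineate_zones(prof3, "a", c(500, 800), 25),
                 "outside the core run")
  expect_equal(e3$core, c(650, 750))
})

test_that("a profile shaped like a low-mountain broadleaf belt cores at 550-900", {
  # unimodal profile over 250-1050 m whose bins exceed the 26.32% mean
  # threshold exactly between 550 and 900 m
  pct <- c(5, 9, 13, 16, 20, 24, 30, 35, 39.21, 38, 33, 29, 27, 12, 9, 4)
  prof <- make_profile(list(deciduous_broadleaf = pct), origin = 250)
  e <- delineate_zones(prof, "deciduous_broadleaf", c(250, 1050), 26.32)
  expect_equal(e$core, c(550, 900))
  expect_equal(zone_of(716, e), "core")
  expect_equal(zone_of(460, e), "lower")
  expect_equal(zone_of(940, e), "upper")
})

test_that("zones partition elevations and respond monotonely to threshold", {
  prof <- make_profile(list(a = c(8, 22, 31, 47, 36, 18, 6)))
  rng <- c(500, 850)
  # partition: every elevation lands in exactly one zone
  e <- delineate_zones(prof, "a", rng, zone_threshold(prof, "a", rng))
  z <- zone_of(seq(300, 1200, by = 7), e)
  expect_true(all(z %in% c("core", "upper", "lower")))
  counts <- (seq(300, 1200, by = 7) < e$core[1]) +
    (seq(300, 1200, by = 7) >= e$core[2])
  expect_true(all(counts <= 1))

  # raising the threshold never widens the core
  prev_width <- Inf
  for (thr in c(10, 20, 30, 40, 46)) {
    ei <- delineate_zones(prof, "a", rng, thr)
    width <- ei$core[2] - ei$core[1]
    expect_lte(width, prev_width)
    prev_width <- width
  }

  # idempotence: delineating the core restricted to itself returns it
  core_rng <- e$core
  e_again <- delineate_zones(prof, "a", core_rng, e$threshold_pct)
  expect_equal(e_again$core, e$core)
})

test_that("noise-free synthetic belts are recovered within one bin", {
  cfg <- noise_off_config(n = 201L, seed = 2L)
  dem <- generate_dem(cfg)
  st <- classify_stand_map(generate_stand_map(cfg, dem))
  prof <- bin_proportions(st, dem)
  scheme <- suppressWarnings(zone_scheme(prof))
  truth <- generate_truth(cfg)
  for (tp in names(scheme)) {
    expect_lte(max(abs(scheme[[tp]]$core - truth$cores[[tp]])), 50)
  }
})
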