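test_that("urban demand arithmetic follows persons x per-capita area", {
  expect_equal(project_urban_demand(530000, 450), 23850)
  expect_equal(project_urban_demand(530000, 450, fraction = 0.1), 2385)
  expect_equal(project_urban_demand(0, 450), 0)
})

test_that("population projection compounds annually", {
  expect_equal(project_population(250000, 0, 25), 250000)
  expect_equal(project_population(100000, 0.0108, 1), 101080)
  expect_equal(project_population(100000, 0.0108, 30),
               round(100000 * 1.0108^30))   # = 138025
})

test_that("compact transform matches the published coefficient anchors", {
  base1 <- coefficient_set(6, 45, 30, 60, 12)
  c1 <- compact_coefficients(base1)
  expect_equal(c1$slope_resistance, 90)
  expect_equal(c1$diffusion, 3)
  expect_equal(c1$road_gravity, 6)
  expect_equal(c1$spread, 30)          # spread unchanged

  base2 <- coefficient_set(29, 47, 20, 24, 30)
  c2 <- compact_coefficients(base2)
  expect_equal(c2$slope_resistance, 36)
  expect_equal(c2$road_gravity, 15)
  expect_equal(c2$diffusion, 15)       # 14.5 rounds half-up
  expect_equal(c2$spread, 20)

  # rounding mode is configurable where halves are ambiguous
  expect_equal(compact_coefficients(base1, rounding = "floor")$breed, 22)
  expect_equal(compact_coefficients(base1, rounding = "half-up")$breed, 23)

  ident <- compact_coefficients(base1, reduce_ratio = 1, slope_increase = 1)
  expect_equal(ident[1:5], base1[1:5])

  # results always stay inside [0, 100]
  hi <- compact_coefficients(coefficient_set(99, 99, 99, 99, 99))
  expect_true(all(unlist(hi[1:5]) >= 0 & unlist(hi[1:5]) <= 100))
})

test_that("cardinal zone partition covers the grid with correct ties", {
  g <- grid(matrix(0, 9, 9), 90)
  z <- zone_partition(g)
  expect_equal(z$values[1, 5], 1)    # due north
  expect_equal(z$values[5, 9], 2)    # due east
  expect_equal(z$values[9, 5], 3)    # due south
  expect_equal(z$values[5, 1], 4)    # due west
  expect_true(all(z$values %in% 1:4))

  z2 <- zone_partition(grid(matrix(0, 2, 2), 90))
  expect_setequal(as.vector(z2$values), 1:4)   # one cell per zone
  expect_equal(z2$values[1, 2], 1)   # NE diagonal -> north
  expect_equal(z2$values[2, 2], 2)   # SE -> east
  expect_equal(z2$values[2, 1], 3)   # SW -> south
  expect_equal(z2$values[1, 1], 4)   # NW -> west
})

test_that("equity weights rank zones by green provisioning", {
  # perfectly symmetric landscape: tie broken north, west, south, east
  lulc <- matrix(1, 20, 20)
  lulc[c(1, 20), ] <- 2; lulc[, c(1, 20)] <- 2      # green ring
  lulc[c(10, 11), c(10, 11)] <- 4                   # central urban
  urban <- (lulc == 4) * 1
  g <- grid(lulc, 90, kind = "categorical", codes = 1:6)
  zones <- zone_partition(g)
  pop <- c(north = 100, west = 100, south = 100, east = 100)
  zw <- equity_weights(g, bin_grid(urban), zones, pop)
  expect_equal(unname(zw$weights[c("north", "west", "south", "east")]),
               c(0.4, 0.3, 0.2, 0.1))

  # a green-poor, crowded east ranks last
  lulc2 <- lulc
  east <- zones$values == 2
  lulc2[east & lulc == 2] <- 1
  pop2 <- c(north = 100, west = 100, south = 100, east = 5000)
  zw2 <- equity_weights(grid(lulc2, 90, kind = "categorical", codes = 1:6),
                        bin_grid(urban), zones, pop2)
  expect_equal(unname(zw2$weights[["east"]]), 0.1)
  expect_equal(unname(zw2$weights[["north"]]), 0.4)
})

test_that("zone weighting rescales likelihood by relative weight", {
  g <- grid(matrix(100, 8, 8), 90)
  zones <- zone_partition(g)
  w <- c(north = 0.4, west = 0.3, south = 0.2, east = 0.1)
  suit <- apply_weights(g, zones, w)
  expect_equal(max(suit$values), 100)
  expect_true(all(suit$values[zones$values == 1] == 100))
  expect_true(all(suit$values[zones$values == 2] == 25))

  uniform <- apply_weights(g, zones, c(north = 0.25, west = 0.25,
                                       south = 0.25, east = 0.25))
  expect_equal(uniform$values, g$values)

  zeroed <- apply_weights(g, zones, c(north = 0.5, west = 0.5,
                                      south = 0.5, east = 0))
  expect_true(all(zeroed$values[zones$values == 2] == 0))
})

test_that("polygon selection honours thresholds, ranking and caps", {
  cs <- 1000   # 1 cell = 100 ha simplifies area bookkeeping
  v <- matrix(0, 12, 12)
  expect_equal(select_polygons(grid(matrix(40, 5, 5), cs))$total_ha, 0)

  # three separated blocks, 400 ha each, suitabilities 90/80/70
  v[2:3, 2:3] <- 90; v[2:3, 8:9] <- 80; v[9:10, 2:3] <- 70
  g <- grid(v, cs)
  top <- select_polygons(g, min_suit = 50, min_area_ha = 30,
                         mode = list(type = "top_n", n = 10))
  expect_equal(nrow(top$table), 3)
  expect_equal(top$table$mean_suit, c(90, 80, 70))

  cap <- select_polygons(g, min_suit = 50, min_area_ha = 30,
                         mode = list(type = "area_cap", cap_ha = 800,
                                     fill_cells = FALSE))
  expect_equal(cap$total_ha, 800)
  expect_equal(nrow(cap$table), 2)
  expect_true(all(cap$labels$values[v == 70] == 0))

  # pixel fill tops the cap up from the next-ranked polygon
  fill <- select_polygons(g, min_suit = 50, min_area_ha = 30,
                          mode = list(type = "area_cap", cap_ha = 1000,
                                      fill_cells = TRUE))
  expect_equal(fill$total_ha, 1000)

  # raising min_suit never adds cells
  s60 <- select_polygons(g, min_suit = 60, min_area_ha = 30,
                         mode = list(type = "top_n", n = 10))
  expect_true(all(top$labels$values[s60$labels$values > 0] > 0))

  # min area filter
  small <- select_polygons(g, min_suit = 50, min_area_ha = 500,
                           mode = list(type = "top_n", n = 10))
  expect_equal(small$total_ha, 0)
})

test_that("the scenario factory emits the 2x2x2 design", {
  tab <- scenario_table()
  expect_equal(nrow(tab), 8)
  expect_equal(tab$exclusion, rep(c("exclusion1", "exclusion2"), each = 4))
  expect_equal(tab$coefficients, rep(c("calibrated", "compact"), 4))
  expect_equal(tab$weighting,
               rep(rep(c("unweighted", "equity-weighted"), each = 2), 2))
  expect_equal(tab$name[1], "Usual Growth")
  expect_equal(tab$name[8], "MSPA-Informed Compact-Social Equity Growth")
})
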