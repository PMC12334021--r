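test_that("conductance assembly respects class values and overrides", {
  lulc <- grid(matrix(2, 4, 4), kind = "categorical", codes = 1:6)
  cond <- build_conductance(lulc)
  expect_true(all(cond$values == default_conductance()[["forest"]]))

  # a bridge connector over agriculture takes the bridge value
  ag <- grid(matrix(1, 11, 18), kind = "categorical", codes = 1:6)
  seg <- mspa_segment(bin_grid(bridged_squares()))
  cond <- build_conductance(ag, seg)
  bridge_cells <- seg$map$values == mspa_classes()[["bridge"]]
  expect_true(all(cond$values[bridge_cells] ==
                    default_conductance()[["bridge"]]))

  # declared ordering of the default table
  dc <- default_conductance()
  expect_true(dc[["forest"]] > dc[["wetland"]],
              dc[["wetland"]] > dc[["water"]])
  expect_true(all(dc[c("islet", "branch", "loop", "bridge")] > dc[["forest"]]))
  expect_true(dc[["islet"]] < dc[["branch"]] &&
                dc[["branch"]] < dc[["loop"]] && dc[["loop"]] < dc[["bridge"]])

  bad <- grid(matrix(c(1, 7), 1, 2), kind = "continuous")
  expect_error(build_conductance(bad), "unmapped")
})

test_that("a uniform strip carries unit current everywhere", {
  cm <- solve_pair_current(grid(matrix(2, 1, 8), 90), c(1, 1), c(1, 8))
  expect_equal(cm$current$values, matrix(1, 1, 8), tolerance = 1e-10)
})

test_that("equal parallel paths split the current evenly", {
  v <- matrix(0, 3, 4)
  v[1, ] <- 1; v[3, ] <- 1; v[2, 1] <- 1; v[2, 4] <- 1
  cm <- solve_pair_current(grid(v, 90), c(2, 1), c(2, 4))
  expect_equal(cm$current$values[1, 2], 0.5, tolerance = 1e-10)
  expect_equal(cm$current$values[3, 2], 0.5, tolerance = 1e-10)
  expect_equal(cm$current$values[2, 1], 1)
  expect_equal(cm$current$values[2, 2], 0)  # zero conductance, zero current
})

test_that("sparse solver matches a dense direct solve on random grids", {
  set.seed(13)
  for (i in 1:12) {
    v <- matrix(runif(16, 0.2, 5), 4, 4)
    cm <- solve_pair_current(grid(v, 90), c(1, 1), c(4, 4))
    expect_equal(cm$current$values, brute_pair_current(v, c(1, 1), c(4, 4)),
                 tolerance = 1e-8, label = paste("grid", i))
  }
})

test_that("Kirchhoff conservation holds at every interior node", {
  set.seed(3)
  v <- matrix(runif(100, 0.5, 3), 10, 10)
  lap <- greengrowth:::lattice_laplacian(v)
  cm <- solve_pair_current(grid(v, 90), c(1, 1), c(10, 10))
  # recompute signed net currents from the voltages implied by the solve
  s <- lap$node[1]; t <- lap$node[100]
  comp <- greengrowth:::lap_components(lap)
  keep <- setdiff(which(comp == comp[s]), t)
  b <- numeric(nrow(lap$L)); b[s] <- 1
  volt <- numeric(nrow(lap$L))
  volt[keep] <- as.numeric(Matrix::solve(
    Matrix::Cholesky(lap$L[keep, keep], LDL = FALSE), b[keep]))
  net <- as.numeric(lap$L %*% volt)
  expect_true(all(abs(net[-c(s, t)]) < 1e-8))
  expect_equal(net[s], 1, tolerance = 1e-8)
  expect_equal(net[t], -1, tolerance = 1e-8)
})

test_that("currents are invariant to conductance scaling", {
  set.seed(17)
  v <- matrix(runif(36, 0.2, 2), 6, 6)
  a <- solve_pair_current(grid(v, 90), c(1, 1), c(6, 6))
  b <- solve_pair_current(grid(v * 7.3, 90), c(1, 1), c(6, 6))
  expect_equal(a$current$values, b$current$values, tolerance = 1e-9)
})

test_that("barriers block current and disconnection raises", {
  v <- matrix(1, 5, 5)
  v[, 3] <- 0
  expect_error(solve_pair_current(grid(v, 90), c(3, 1), c(3, 5)), "no path")
  v[3, 3] <- 1   # single gap
  cm <- solve_pair_current(grid(v, 90), c(3, 1), c(3, 5))
  expect_true(all(cm$current$values[v == 0] == 0))
  expect_equal(cm$current$values[3, 3], 1, tolerance = 1e-8)
})

test_that("cumulative current superposes pairs and is deterministic", {
  v <- matrix(1, 3, 13)
  lab <- matrix(0L, 3, 13)
  lab[2, 2] <- 1L; lab[2, 7] <- 2L; lab[2, 12] <- 3L
  cores <- structure(list(
    labels = grid(lab, 90),
    area_ha = rep(0.81, 3),
    rep_points = cbind(row = c(2, 2, 2), col = c(2, 7, 12)),
    n = 3), class = "gg_cores")
  cc <- cumulative_current(grid(v, 90), cores, pair_budget = 10, seed = 1)
  expect_equal(cc$n_pairs, 3)
  # raw sum equals the superposition of the three pairwise solves
  manual <- solve_pair_current(grid(v, 90), c(2, 2), c(2, 7))$current$values +
    solve_pair_current(grid(v, 90), c(2, 2), c(2, 12))$current$values +
    solve_pair_current(grid(v, 90), c(2, 7), c(2, 12))$current$values
  expect_equal(cc$current$values, manual, tolerance = 1e-8)
  # middle segment outranks what any one pair alone carries there
  one_pair <- solve_pair_current(grid(v, 90), c(2, 7), c(2, 12))
  expect_gt(max(cc$current$values[2, 8:11]),
            max(one_pair$current$values[2, 8:11]))
  expect_equal(max(cc$byte$values), 255)

  cc2 <- cumulative_current(grid(v, 90), cores, pair_budget = 10, seed = 1)
  expect_identical(cc$current$values, cc2$current$values)

  # two nodes: cumulative equals the single pair, rescaled
  cores2 <- cores
  cores2$n <- 2
  cores2$rep_points <- cores$rep_points[1:2, ]
  cores2$area_ha <- cores$area_ha[1:2]
  cc3 <- cumulative_current(grid(v, 90), cores2, pair_budget = 10, seed = 1)
  single <- solve_pair_current(grid(v, 90), c(2, 2), c(2, 7))$current$values
  expect_equal(cc3$byte$values, single / max(single) * 255, tolerance = 1e-8)
})
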