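flat <- function(n) matrix(0, n, n)

test_that("zero coefficients and full exclusion both freeze the landscape", {
  u <- matrix(0, 12, 12); u[6, 6] <- 1
  co0 <- coefficient_set(0, 0, 0, 0, 0)
  set.seed(1)
  expect_identical(ca_step(u, co0, flat(12), flat(12), flat(12)), u == 1)

  wall <- matrix(100, 12, 12)
  set.seed(2)
  for (i in 1:5) {
    co <- coefficient_set(sample(0:100, 1), sample(0:100, 1),
                          sample(0:100, 1), sample(0:100, 1),
                          sample(0:100, 1), D_M = 0.05)
    u2 <- ca_step(u, co, flat(12), wall, flat(12))
    expect_identical(u2, u == 1)
  }
})

test_that("edge growth at full spread urbanizes exactly the >=3-neighbour cells", {
  u <- matrix(0, 9, 9); u[4:6, 4:6] <- 1
  co <- coefficient_set(0, 0, 100, 0, 0)
  oracle <- which(u == 0 & greengrowth:::neighbour_count(u == 1, 8) >= 3)
  set.seed(3)
  u2 <- ca_step(u, co, flat(9), flat(9), flat(9))
  expect_setequal(which(u2 & u == 0), oracle)
  expect_length(oracle, 4)   # the four side-centre ring cells of a 3x3 block
})

test_that("urban cells never de-urbanize across steps", {
  set.seed(4)
  u <- matrix(as.numeric(runif(400) < 0.05), 20, 20)
  co <- coefficient_set(40, 40, 40, 20, 40, D_M = 0.05)
  slope <- matrix(runif(400, 0, 30), 20, 20)
  excl <- matrix(sample(c(0, 50, 100), 400, TRUE), 20, 20)
  roads <- matrix(0, 20, 20); roads[10, ] <- 1
  cur <- u == 1
  for (i in 1:8) {
    nxt <- ca_step(cur, co, slope, excl, roads)
    expect_true(all(nxt[cur]))
    cur <- nxt
  }
})

test_that("slope gate forbids urbanization at or above the critical slope", {
  u <- matrix(0, 10, 10); u[5, 5] <- 1
  steep <- matrix(50, 10, 10)   # everywhere above critical 21
  co <- coefficient_set(100, 100, 100, 0, 0, D_M = 0.5)
  set.seed(5)
  expect_identical(ca_step(u, co, steep, flat(10), flat(10)), u == 1)
})

test_that("prediction likelihood is quantized, seeded and monotone in horizon", {
  syn <- generate_stack(landscape_params(rows = 60, cols = 60, seed = 8))
  st <- syn$stack
  co <- coefficient_set(20, 20, 20, 10, 20, D_M = 0.02)
  excl <- grid(matrix(0, 60, 60), 90)
  pred <- run_prediction(st$urban_2020, co, st$slope, excl, st$roads_2020,
                         st$lulc_2020, start_year = 2020, stop_year = 2030,
                         n_mc = 4, seed = 9)
  lik <- pred$likelihood$values
  expect_true(all(lik %in% (100 * (0:4) / 4)))
  expect_true(all(lik[st$urban_2020$values == 1] == 100))

  pred2 <- run_prediction(st$urban_2020, co, st$slope, excl, st$roads_2020,
                          st$lulc_2020, start_year = 2020, stop_year = 2030,
                          n_mc = 4, seed = 9)
  expect_identical(lik, pred2$likelihood$values)

  longer <- run_prediction(st$urban_2020, co, st$slope, excl, st$roads_2020,
                           st$lulc_2020, start_year = 2020, stop_year = 2035,
                           n_mc = 4, seed = 9)
  expect_true(all(longer$likelihood$values >= lik))

  # predicted LULC recodes likely cells urban
  expect_true(all(pred$predicted_lulc$values[lik >= 50] == 4))

  # degenerate run: no growth rules active
  frozen <- run_prediction(st$urban_2020, coefficient_set(0, 0, 0, 0, 0),
                           st$slope, excl, st$roads_2020,
                           start_year = 2020, stop_year = 2025, n_mc = 1,
                           seed = 1)
  expect_equal(frozen$likelihood$values, st$urban_2020$values * 100)
})

test_that("spontaneous growth scales linearly with the diffusion multiplier", {
  u <- matrix(0, 50, 50)
  co1 <- coefficient_set(50, 0, 0, 0, 0, D_M = 0.01)
  co2 <- coefficient_set(50, 0, 0, 0, 0, D_M = 0.02)
  news <- function(co) {
    mean(vapply(1:50, function(s) {
      set.seed(s)
      sum(ca_step(u, co, flat(50), flat(50), flat(50)))
    }, numeric(1)))
  }
  ratio <- news(co2) / news(co1)
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})

test_that("the diffusion-multiplier sequence enumerates as specified", {
  expect_length(dm_sequence(0.001, 0.003, 0.124), 42)
  expect_equal(dm_sequence(0.05, 0.01, 0.05), 0.05)
  expect_equal(dm_sequence(0.001, 0.003, 0.124)[42], 0.124)
})

test_that("the D_M sweep scores CFD against observed clustering", {
  syn <- generate_stack(landscape_params(rows = 60, cols = 60, seed = 10))
  sw <- dm_sweep(syn$stack, start = 0.004, step = 0.004, stop = 0.012,
                 n_mc = 2, seed = 11)
  expect_equal(nrow(sw$records), 3)
  expect_equal(sw$best_dm,
               sw$records$D_M[which.min(abs(sw$records$CFD))])
  expect_equal(sw$records$CFD,
               (sw$records$sim_clusters - sw$observed_clusters) /
                 sw$observed_clusters)
})

test_that("calibration recovers generating coefficients within one grid step", {
  # build an observed history with known coefficients, then search for them
  syn <- generate_stack(landscape_params(rows = 80, cols = 80, seed = 12))
  st <- syn$stack
  true_co <- coefficient_set(diffusion = 50, breed = 1, spread = 50,
                             slope_resistance = 1, road_gravity = 1,
                             D_M = 0.02)
  exv <- st$exclusion$values
  u <- st$urban_1990$values == 1
  hist_seed <- 77
  for (yr in 1991:2020) {
    rs <- vapply(1:4, function(rule)
      child_seed(hist_seed, "mc", 1, "yr", yr, "rule", rule), integer(1))
    u <- ca_step(u, true_co, st$slope$values, exv, st$roads_2020$values,
                 rule_seeds = rs)
    if (yr %in% c(2000, 2010, 2020)) {
      st[[paste0("urban_", yr)]] <- grid(u * 1, 90, kind = "binary")
      lv <- st[[paste0("lulc_", yr)]]$values
      lv[u] <- 4
      st[[paste0("lulc_", yr)]] <- grid(lv, 90, kind = "categorical",
                                        codes = 1:6)
    }
  }
  stages <- calibration_stages(
    steps = c(25), n_mc = c(2), keep_top = 3,
    initial = list(diffusion = seq(0, 100, 25), breed = 1,
                   spread = seq(0, 100, 25), slope_resistance = 1,
                   road_gravity = 1))
  cal <- ca_calibrate(st, stages = stages, D_M = 0.02, seed = 13)
  expect_lte(abs(cal$best$diffusion - 50), 25)
  expect_lte(abs(cal$best$spread - 50), 25)

  # single-point ranges produce exactly one record
  one <- calibration_stages(steps = c(25), n_mc = c(1), initial =
    list(diffusion = 10, breed = 1, spread = 10, slope_resistance = 1,
         road_gravity = 1))
  cal1 <- ca_calibrate(st, stages = one, D_M = 0.02, seed = 14)
  expect_equal(nrow(cal1$stages[[1]]), 1)
})

test_that("validation metrics hit their closed forms", {
  seed_u <- bin_grid(matrix(0, 4, 4))
  obs <- matrix(0, 4, 4); obs[1:2, 1:2] <- 1
  perfect <- grid(obs * 100, 90)
  v <- ca_validate(perfect, bin_grid(obs), seed_u)
  expect_equal(v$auc_roc, 1)
  expect_equal(v$auc_pr, 1)
  expect_equal(v$fom, 1)

  const <- grid(matrix(50, 4, 4), 90)
  expect_equal(ca_validate(const, bin_grid(obs), seed_u)$auc_roc, 0.5)

  # 4-cell toy: 1 hit, 1 miss, 1 false alarm -> FoM = 1/3
  obs4 <- bin_grid(matrix(c(1, 1, 0, 0), 2, 2))
  lik4 <- grid(matrix(c(80, 10, 90, 5), 2, 2), 90)
  expect_equal(ca_validate(lik4, obs4, bin_grid(matrix(0, 2, 2)))$fom, 1 / 3)

  expect_error(ca_validate(grid(matrix(0, 2, 2), 90),
                           bin_grid(matrix(0, 2, 2)),
                           bin_grid(matrix(0, 2, 2))),
               "undefined")
})

test_that("precision-recall area matches a hand-computed example", {
  expect_equal(greengrowth:::pr_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)),
               0.5 * 1 + 0.5 * (2 / 3))
  expect_equal(greengrowth:::pr_auc(c(4, 3, 2, 1), c(1, 1, 0, 0)), 1)
})
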