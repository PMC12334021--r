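sel_from <- function(mask, cellsize = 90) {
  lab <- greengrowth:::label_components(mask == 1, 8)
  structure(list(labels = grid(lab, cellsize),
                 table = data.frame(rank = seq_len(max(lab))),
                 total_ha = sum(mask) * cellsize^2 / 1e4),
            class = "gg_selection")
}

cores_from <- function(lab, cellsize = 90) {
  n <- max(lab)
  structure(list(labels = grid(lab, cellsize),
                 area_ha = tabulate(lab[lab > 0], n) * cellsize^2 / 1e4,
                 rep_points = matrix(1, n, 2,
                                     dimnames = list(NULL, c("row", "col"))),
                 n = n), class = "gg_cores")
}

test_that("affected percentages count high-value cells inside selections", {
  set.seed(1)
  v <- matrix(0, 10, 10)
  high <- sample(100, 10)
  v[high] <- 200
  sel_all <- sel_from((v > 150) * 1)
  expect_equal(percent_affected(grid(v, 90), sel_all), 100)

  none <- matrix(0, 10, 10); none[1, 1] <- ifelse(v[1, 1] > 150, 0, 1)
  expect_equal(percent_affected(grid(v, 90), sel_from(none * (v <= 150))), 0)

  m <- matrix(0, 10, 10)
  m[high[1:3]] <- 1
  expect_equal(percent_affected(grid(v, 90), sel_from(m)), 30)

  expect_equal(percent_affected(grid(matrix(0, 4, 4), 90), sel_all), 0)
})

test_that("affected core area is the covered fraction of all core cells", {
  lab <- matrix(0L, 10, 10)
  lab[1:10, 1:10] <- 1L           # 100 core cells
  cores <- cores_from(lab)
  m7 <- matrix(0, 10, 10); m7[1, 1:7] <- 1
  expect_equal(percent_core_area_affected(cores, sel_from(m7)), 7)
  expect_equal(percent_core_area_affected(cores,
                                          sel_from(matrix(1, 10, 10))), 100)
  empty_cores <- cores_from(matrix(0L, 10, 10))
  expect_error(percent_core_area_affected(empty_cores, sel_from(m7)),
               "no core")
})

test_that("perimeter-area ratio matches hand computations", {
  one <- matrix(0L, 3, 3); one[2, 2] <- 1L
  expect_equal(para_mn(grid(one, 90)), 360 / 0.81)
  block <- matrix(0L, 5, 5); block[2:4, 2:4] <- 1L
  expect_equal(para_mn(grid(block, 90)), 1080 / 7.29)
  two <- matrix(0L, 5, 9); two[2:4, 2:4] <- 1L; two[2:4, 6:8] <- 2L
  expect_equal(para_mn(grid(two, 90)), 1080 / 7.29)  # mean of equal patches
  expect_error(para_mn(grid(matrix(0L, 3, 3), 90)), "empty")
})

test_that("nearest-neighbour distance uses cell centres", {
  lab <- matrix(0L, 3, 9)
  lab[2, 2] <- 1L; lab[2, 7] <- 2L
  expect_equal(enn_mn(grid(lab, 90)), 450)
  adj <- matrix(0L, 3, 4); adj[2, 2] <- 1L; adj[2, 3] <- 2L
  expect_equal(enn_mn(grid(adj, 90)), 90)
  tri <- matrix(0L, 9, 9)
  tri[1, 1] <- 1L; tri[1, 3] <- 2L; tri[9, 9] <- 3L
  # A and B are each other's nearest; C reaches B
  dAB <- 2 * 90
  dCB <- sqrt(8^2 + 6^2) * 90
  expect_equal(enn_mn(grid(tri, 90)), mean(c(dAB, dAB, dCB)))
  expect_error(enn_mn(grid(matrix(1L, 2, 2), 90)), "two patches")
})

test_that("PARA and ENN match brute-force oracles on random rasters", {
  for (seed in 1:12) {
    lab <- random_patches(15, 15, 4, seed)
    if (max(lab) >= 1)
      expect_equal(para_mn(grid(lab, 90)), brute_para(lab, 90),
                   label = paste("para seed", seed))
    if (max(lab) >= 2)
      expect_equal(enn_mn(grid(lab, 90)), brute_enn(lab, 90),
                   label = paste("enn seed", seed))
  }
})

test_that("buffered core subsetting respects the distance threshold", {
  lab <- matrix(0L, 5, 40)
  lab[3, 2] <- 1L                  # adjacent to the selection
  lab[3, 30] <- 2L                 # ~2.5 km away at 90 m
  cores <- cores_from(lab)
  sel <- sel_from({m <- matrix(0, 5, 40); m[3, 3:4] <- 1; m})
  near <- cores_near_selection(cores, sel, buffer_m = 1000)
  expect_equal(near$n, 1)
  expect_equal(sum(near$labels$values > 0), 1)
  zero <- cores_near_selection(cores, sel, buffer_m = 0)
  expect_equal(zero$n, 0)          # neither core intersects directly
  direct <- cores_near_selection(cores, sel_from((lab == 1) * 1),
                                 buffer_m = 0)
  expect_equal(direct$n, 1)
})

test_that("scenario assessment assembles all seven criteria", {
  lab <- matrix(0L, 12, 12); lab[2:5, 2:5] <- 1L; lab[8:11, 8:11] <- 2L
  cores <- cores_from(lab)
  imp <- matrix(0, 12, 12); imp[2:5, 2:5] <- 200
  cur <- matrix(0, 12, 12); cur[6:7, ] <- 200

  sel <- sel_from({m <- matrix(0, 12, 12); m[2:3, 2:5] <- 1; m})
  rec <- assess_scenario(sel, cores, grid(imp, 90), grid(cur, 90))
  expect_equal(rec$pct_affected_cores_gt150, 50)       # 8 of 16 high cells
  expect_equal(rec$pct_affected_corridors_gt150, 0)
  expect_equal(rec$pct_affected_core_area, 100 * 8 / 32)
  expect_false(is.na(rec$para_mn_cores_1km))

  # empty selection: percentages zero, polygon metrics flagged absent
  none <- sel_from(matrix(0, 12, 12))
  rec0 <- assess_scenario(none, cores, grid(imp, 90), grid(cur, 90))
  expect_equal(rec0$pct_affected_core_area, 0)
  expect_true(is.na(rec0$para_mn_selected))
  expect_true(is.na(rec0$enn_mn_selected))

  # full selection: everything affected
  all_sel <- sel_from(matrix(1, 12, 12))
  rec1 <- assess_scenario(all_sel, cores, grid(imp, 90), grid(cur, 90))
  expect_equal(rec1$pct_affected_core_area, 100)
  expect_equal(rec1$pct_affected_corridors_gt150, 100)
})

test_that("adding polygons never decreases affected percentages", {
  set.seed(30)
  v <- matrix(runif(400, 0, 255), 20, 20)
  lab <- matrix(0L, 20, 20); lab[3:18, 3:18] <- 1L
  cores <- cores_from(lab)
  m1 <- matrix(0, 20, 20); m1[2:6, 2:6] <- 1
  m2 <- m1; m2[10:15, 10:15] <- 1
  s1 <- sel_from(m1); s2 <- sel_from(m2)
  expect_gte(percent_affected(grid(v, 90), s2),
             percent_affected(grid(v, 90), s1))
  expect_gte(percent_core_area_affected(cores, s2),
             percent_core_area_affected(cores, s1))
})
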