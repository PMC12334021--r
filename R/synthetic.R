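#' Parameters for the synthetic landscape generator
#'
#' The generator emulates the statistical structure of the study inputs:
#' a 1000 x 1000 grid at 90 m whose urban fraction grows from 4.25% to
#' 7.94% over four epochs (1990/2000/2010/2020) as a mixture of edge
#' accretion and scattered seeding, a connected road network that
#' densifies over the first three epochs and then stays static, a mostly
#' flat slope surface with one contiguous steep region, and green-space
#' patches of varied size and shape joined by thin connectors. The two
#' intermediate urban fractions are not reported for the study region and
#' default to interpolated values.
#'
#' @param rows,cols grid dimensions (default 1000 x 1000).
#' @param cellsize_m cell edge length in metres (default 90).
#' @param urban_fraction_by_epoch non-decreasing urban fractions, one per
#'   epoch (default `c(0.0425, 0.051, 0.065, 0.0794)`).
#' @param epochs epoch labels (default `c(1990, 2000, 2010, 2020)`).
#' @param n_green_patches number of green-space patch seeds (default 12).
#' @param green_fraction target green (forest/vegetation) fraction
#'   (default 0.35).
#' @param road_density_by_epoch number of road waypoints per epoch; the
#'   network densifies over the first three epochs then holds (default
#'   `c(12, 18, 24, 24)`).
#' @param steep_fraction fraction of the landscape in the contiguous
#'   steep region (default 0.05).
#' @param critical_slope_pct slope (percent) above which the growth model
#'   never urbanizes (default 21).
#' @param edge_growth_share share of new urban cells added by edge
#'   accretion, the rest scattered (default 0.8).
#' @param water_fraction,wetland_fraction,bare_fraction minor-class
#'   fractions.
#' @param pop_total total population to allocate across the four cardinal
#'   zones (default 1e6).
#' @param pop_skew named multiplier per zone applied to urban-area shares
#'   when allocating population; the default makes green-per-capita ratios
#'   differ across zones.
#' @param seed integer seed fixing all randomness.
#' @return a `gg_landscape_params` list.
#' @export
landscape_params <- function(rows = 1000, cols = 1000, cellsize_m = 90,
                             urban_fraction_by_epoch = c(0.0425, 0.051, 0.065, 0.0794),
                             epochs = c(1990, 2000, 2010, 2020),
                             n_green_patches = 12,
                             green_fraction = 0.35,
                             road_density_by_epoch = c(12, 18, 24, 24),
                             steep_fraction = 0.05,
                             critical_slope_pct = 21,
                             edge_growth_share = 0.8,
                             water_fraction = 0.04,
                             wetland_fraction = 0.03,
                             bare_fraction = 0.02,
                             pop_total = 1e6,
                             pop_skew = c(north = 1, west = 1.2, south = 1.5, east = 2),
                             seed = 1) {
  p <- as.list(environment())
  stopifnot(rows >= 1, cols >= 1, cellsize_m > 0,
            !is.unsorted(urban_fraction_by_epoch),
            length(urban_fraction_by_epoch) == length(epochs),
            all(urban_fraction_by_epoch >= 0 & urban_fraction_by_epoch <= 1),
            green_fraction >= 0, green_fraction <= 1,
            edge_growth_share >= 0, edge_growth_share <= 1)
  if (utils::tail(urban_fraction_by_epoch, 1) + green_fraction +
      water_fraction > 1)
    stop("infeasible params: urban + green + water fractions exceed 1")
  structure(p, class = "gg_landscape_params")
}

#' Shrink generator parameters to a smaller grid
#'
#' Keeps all fractional targets while dividing both grid dimensions by an
#' integer factor, for fast test-scale runs (e.g. 1000 -> 200 with factor
#' 5).
#'
#' @param params a [landscape_params()].
#' @param factor integer >= 1 dividing both `rows` and `cols`.
#' @return a [landscape_params()] on the smaller grid.
#' @export
shrink <- function(params, factor) {
  stopifnot(inherits(params, "gg_landscape_params"), factor >= 1)
  if (params$rows %% factor != 0 || params$cols %% factor != 0)
    stop("factor ", factor, " does not divide ", params$rows, "x", params$cols)
  params$rows <- params$rows %/% factor
  params$cols <- params$cols %/% factor
  params
}

# Rasterize the straight segment between two cells, 1 cell wide (Bresenham
# on the supercover so the line stays 8-connected).
line_cells <- function(r1, c1, r2, c2) {
  n <- max(abs(r2 - r1), abs(c2 - c1)) + 1
  cbind(round(seq(r1, r2, length.out = n)), round(seq(c1, c2, length.out = n)))
}

# Disk mask around a centre; radii may differ by axis for elongation.
paint_blob <- function(mask, r0, c0, rad_r, rad_c) {
  nr <- nrow(mask); nc <- ncol(mask)
  rr <- max(1, floor(r0 - rad_r)):min(nr, ceiling(r0 + rad_r))
  cc <- max(1, floor(c0 - rad_c)):min(nc, ceiling(c0 + rad_c))
  sub <- outer(((rr - r0) / rad_r)^2, ((cc - c0) / rad_c)^2, "+") <= 1
  mask[rr, cc] <- mask[rr, cc] | sub
  mask
}

# Grow a logical mask by edge accretion / scattering until it has n_target
# TRUE cells among `eligible`.
grow_mask <- function(mask, eligible, n_target, edge_share) {
  while ((need <- n_target - sum(mask)) > 0) {
    frontier <- which(!mask & eligible & neighbour_count(mask) > 0)
    n_edge <- min(length(frontier), round(need * edge_share))
    add <- if (n_edge > 0) frontier[sample.int(length(frontier), n_edge)] else integer(0)
    n_scatter <- need - n_edge
    if (n_scatter > 0) {
      pool <- setdiff(which(!mask & eligible), add)
      if (length(pool) == 0 && n_edge == 0) break
      add <- c(add, pool[sample.int(length(pool), min(n_scatter, length(pool)))])
    }
    if (length(add) == 0) break
    mask[add] <- TRUE
  }
  mask
}

#' Generate a complete synthetic layer stack
#'
#' Builds, for each epoch, a six-class categorical LULC layer (1
#' agriculture, 2 forest/vegetation, 3 wetland, 4 urban, 5 bare, 6 water),
#' a binary urban mask consistent with the LULC urban class, and a binary
#' road mask; plus one slope layer in percent and per-zone population
#' counts. Urban masks are monotone across epochs; new urban cells are a
#' mixture of edge accretion and scattered seeds; roads form a connected
#' network (random spanning tree over waypoints, rasterized one cell
#' wide) that densifies over the first three epochs.
#'
#' @param params a [landscape_params()].
#' @return a list with elements `stack` (a [layer_stack()]), `population`
#'   (named counts for north/west/south/east) and `params`.
#' @export
generate_stack <- function(params) {
  stopifnot(inherits(params, "gg_landscape_params"))
  p <- params
  set.seed(child_seed(p$seed, "synth"))
  nr <- p$rows; nc <- p$cols
  ncell <- nr * nc
  f <- matrix(FALSE, nr, nc)

  ## --- green-space patches with thin connectors ---------------------
  green <- f
  # patch radii spread over an order of magnitude; area budget ~ target
  w <- stats::runif(p$n_green_patches, 0.3, 1)^2
  budget <- p$green_fraction * ncell * 0.85   # connectors + noise fill the rest
  rad <- sqrt(budget * w / sum(w) / pi)
  ctr_r <- stats::runif(p$n_green_patches, 0.1, 0.9) * nr
  ctr_c <- stats::runif(p$n_green_patches, 0.1, 0.9) * nc
  for (i in seq_len(p$n_green_patches)) {
    elong <- stats::runif(1, 0.6, 1.6)
    green <- paint_blob(green, ctr_r[i], ctr_c[i], rad[i] * elong, rad[i] / elong)
  }
  # thin connectors: chain patches in a random order
  ord <- sample.int(p$n_green_patches)
  for (i in seq_len(p$n_green_patches - 1)) {
    a <- ord[i]; b <- ord[i + 1]
    cells <- line_cells(ctr_r[a], ctr_c[a], ctr_r[b], ctr_c[b])
    green[cells] <- TRUE
  }

  ## --- slope: mostly flat with one contiguous steep region ----------
  slope <- matrix(stats::runif(ncell, 0, 8), nr, nc)
  steep_rad <- sqrt(p$steep_fraction * ncell / pi)
  sr <- stats::runif(1, 0.2, 0.8) * nr; sc <- stats::runif(1, 0.2, 0.8) * nc
  steep <- paint_blob(f, sr, sc, steep_rad, steep_rad)
  slope[steep] <- stats::runif(sum(steep), p$critical_slope_pct + 4, 60)

  ## --- water and wetlands -------------------------------------------
  water <- f
  wr <- sqrt(p$water_fraction * ncell / pi)
  water <- paint_blob(water, stats::runif(1, 0.15, 0.85) * nr,
                      stats::runif(1, 0.15, 0.85) * nc, wr * 1.4, wr / 1.4)
  wet <- f
  for (i in 1:3)
    wet <- paint_blob(wet, stats::runif(1, 0.1, 0.9) * nr,
                      stats::runif(1, 0.1, 0.9) * nc,
                      sqrt(p$wetland_fraction * ncell / 3 / pi),
                      sqrt(p$wetland_fraction * ncell / 3 / pi))
  wet <- wet & !water
  bare <- matrix(stats::runif(ncell) < p$bare_fraction, nr, nc) & !water

  ## --- roads: spanning tree over waypoints, densifying --------------
  n_ep <- length(p$epochs)
  n_way <- pmin(p$road_density_by_epoch, nr * nc)
  n_way <- pmax(n_way, 2)
  way_r <- stats::runif(max(n_way), 0.05, 0.95) * nr
  way_c <- stats::runif(max(n_way), 0.05, 0.95) * nc
  roads <- vector("list", n_ep)
  rd <- f
  built <- 0
  for (e in seq_len(n_ep)) {
    k <- n_way[e]
    if (k > built) {
      pts <- cbind(way_r[1:k], way_c[1:k])
      dmat <- as.matrix(stats::dist(pts))
      g <- igraph::graph_from_adjacency_matrix(
        dmat * matrix(stats::runif(k * k, 0.5, 1.5), k, k),
        mode = "upper", weighted = TRUE)
      mst <- igraph::mst(g)
      el <- igraph::as_edgelist(mst, names = FALSE)
      for (j in seq_len(nrow(el))) {
        cells <- line_cells(pts[el[j, 1], 1], pts[el[j, 1], 2],
                            pts[el[j, 2], 1], pts[el[j, 2], 2])
        rd[cells] <- TRUE
      }
      built <- k
    }
    roads[[e]] <- rd
  }

  ## --- urban: monotone growth, edge accretion + scatter -------------
  eligible <- !water
  urban <- vector("list", n_ep)
  u <- f
  # first-epoch seeds: a few cluster centres near road waypoints
  n0 <- round(p$urban_fraction_by_epoch[1] * ncell)
  if (n0 > 0) {
    n_seed <- max(3, round(n0 / 400))
    si <- sample.int(built, min(n_seed, built))
    sr_ <- pmin(pmax(round(way_r[si] + stats::rnorm(length(si), 0, nr / 50)), 1), nr)
    sc_ <- pmin(pmax(round(way_c[si] + stats::rnorm(length(si), 0, nc / 50)), 1), nc)
    u[cbind(sr_, sc_)] <- TRUE
    u <- u & eligible
    if (!any(u)) u[which(eligible)[1]] <- TRUE
    u <- grow_mask(u, eligible, n0, p$edge_growth_share)
  }
  urban[[1]] <- u
  for (e in seq_len(n_ep)[-1]) {
    u <- grow_mask(u, eligible, round(p$urban_fraction_by_epoch[e] * ncell),
                   p$edge_growth_share)
    urban[[e]] <- u
  }

  ## --- assemble LULC per epoch --------------------------------------
  layers <- list()
  for (e in seq_len(n_ep)) {
    lulc <- matrix(1, nr, nc)                       # agriculture background
    lulc[bare] <- 5
    lulc[green] <- 2
    lulc[wet] <- 3
    lulc[urban[[e]]] <- 4
    lulc[water] <- 6
    yr <- p$epochs[e]
    layers[[paste0("lulc_", yr)]] <-
      grid(lulc, p$cellsize_m, kind = "categorical", codes = 1:6)
    layers[[paste0("urban_", yr)]] <-
      grid((urban[[e]] & !water) * 1, p$cellsize_m, kind = "binary")
    layers[[paste0("roads_", yr)]] <-
      grid(roads[[e]] * 1, p$cellsize_m, kind = "binary")
  }
  layers$slope <- grid(slope, p$cellsize_m, kind = "continuous")
  layers$exclusion <- grid(water * 100, p$cellsize_m, kind = "continuous")

  ## --- zone populations ---------------------------------------------
  zones <- zone_partition(layers$slope)
  ufin <- urban[[n_ep]]
  share <- vapply(c("north", "west", "south", "east"),
                  function(z) sum(ufin[zones$values == zone_code(z)]),
                  numeric(1))
  share <- share + 1   # guard against an empty zone
  share <- share * p$pop_skew[c("north", "west", "south", "east")]
  pop <- round(p$pop_total * share / sum(share))
  names(pop) <- c("north", "west", "south", "east")

  list(stack = layer_stack(layers), population = pop, params = p)
}
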