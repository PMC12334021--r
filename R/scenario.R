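#' Project urban land demand from population growth
#'
#' `hectares = pop_growth * per_capita_m2 / 10000 * fraction`. With the
#' projected growth of 530,000 persons at 450 m2 per capita this is
#' 23,850 ha, and the 10% compact variant is 2,385 ha.
#'
#' @param pop_growth projected population growth (persons).
#' @param per_capita_m2 built-plus-infrastructure area per capita
#'   (default 450).
#' @param fraction fraction of the full demand (default 1; 0.1 for the
#'   compact variant).
#' @return demand in hectares.
#' @export
project_urban_demand <- function(pop_growth, per_capita_m2 = 450,
                                 fraction = 1) {
  stopifnot(pop_growth >= 0, per_capita_m2 >= 0, fraction >= 0)
  pop_growth * per_capita_m2 / 1e4 * fraction
}

#' Compound population projection
#'
#' @param base current population.
#' @param rate annual growth rate (fraction, e.g. 0.0108).
#' @param years projection horizon in years.
#' @return projected population, rounded to the nearest integer.
#' @export
project_population <- function(base, rate, years) {
  stopifnot(rate >= 0)
  round(base * (1 + rate)^years)
}

#' Compact-city coefficient transform
#'
#' Halves diffusion, breed and road gravity (round-half-up by default)
#' and raises slope resistance by 50% (capped at 100); spread is left
#' unchanged. This concentrates growth: fewer scattered seeds, fewer new
#' centres, weaker road pull and stronger avoidance of sloped land.
#'
#' @param coeffs a [coefficient_set()].
#' @param reduce_ratio multiplier for diffusion, breed, road gravity
#'   (default 0.5).
#' @param slope_increase multiplier for slope resistance (default 1.5).
#' @param rounding `"half-up"` (default) or `"floor"` for the reduced
#'   coefficients.
#' @return a transformed [coefficient_set()].
#' @export
compact_coefficients <- function(coeffs, reduce_ratio = 0.5,
                                 slope_increase = 1.5,
                                 rounding = c("half-up", "floor")) {
  rounding <- match.arg(rounding)
  rnd <- if (rounding == "floor") floor else function(x) floor(x + 0.5)
  coefficient_set(
    diffusion = min(100, rnd(coeffs$diffusion * reduce_ratio)),
    breed = min(100, rnd(coeffs$breed * reduce_ratio)),
    spread = coeffs$spread,
    slope_resistance = min(100, rnd(coeffs$slope_resistance * slope_increase)),
    road_gravity = min(100, rnd(coeffs$road_gravity * reduce_ratio)),
    D_M = coeffs$D_M, critical_slope_pct = coeffs$critical_slope_pct)
}

zone_code <- function(zone) {
  c(north = 1L, east = 2L, south = 3L, west = 4L)[[zone]]
}

#' Partition the grid into four cardinal zones
#'
#' Each cell joins the cardinal quadrant of the vector from the grid
#' centre to the cell, with the 45-degree diagonals as boundaries. Cells
#' exactly on a diagonal are assigned clockwise starting at north (NE
#' diagonal to north, SE to east, SW to south, NW to west); a cell
#' exactly at the centre goes north.
#'
#' @param grid any [grid()] defining the shape.
#' @return a categorical [grid()] with codes 1 north, 2 east, 3 south,
#'   4 west.
#' @export
zone_partition <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  dy <- row_index(nr, nc) - cr       # positive = south of centre
  dx <- col_index(nr, nc) - cc       # positive = east of centre
  theta <- atan2(dx, -dy) * 180 / pi # 0 = north, 90 = east
  z <- matrix(3L, nr, nc)            # south by default
  z[theta > -45 & theta <= 45] <- 1L
  z[theta > 45 & theta <= 135] <- 2L
  z[theta > -135 & theta <= -45] <- 4L
  structure(list(values = z, cellsize_m = grid$cellsize_m, nodata = NA,
                 kind = "categorical", codes = 1:4),
            class = "gg_grid")
}

#' Green-space equity weights per cardinal zone
#'
#' For each zone, computes `r1` = green area within `buffer_m` of urban
#' divided by urban area, and `r2` = green area divided by population.
#' Zones are ranked by the mean of min-max-normalized `r1` and `r2`
#' (best-provisioned first; a zone with no urban area ranks last; ties
#' break in the fixed order north, west, south, east) and receive the
#' weights 0.4 / 0.3 / 0.2 / 0.1 in rank order, steering growth toward
#' the zones best provisioned with green space.
#'
#' @param lulc categorical [grid()] (green = class 2).
#' @param urban binary [grid()].
#' @param zones from [zone_partition()].
#' @param pop named population counts (north/west/south/east).
#' @param buffer_m buffer distance in metres (default 1000).
#' @param weights weights assigned best to worst (default
#'   `c(0.4, 0.3, 0.2, 0.1)`).
#' @return a `gg_zone_weights`: `weights` (named per zone), `table`
#'   (per-zone derivation: urban area, green area, r1, r2, rank).
#' @export
equity_weights <- function(lulc, urban, zones, pop, buffer_m = 1000,
                           weights = c(0.4, 0.3, 0.2, 0.1)) {
  stopifnot(all(c("north", "west", "south", "east") %in% names(pop)),
            all(pop > 0))
  zn <- c("north", "west", "south", "east")
  cell_ha <- lulc$cellsize_m^2 / 1e4
  green <- lulc$values == 2
  urb <- urban$values == 1
  near_urban <- dist_to(urb) * lulc$cellsize_m <= buffer_m
  tab <- data.frame(zone = zn, urban_ha = NA_real_, green_ha = NA_real_,
                    green_near_urban_ha = NA_real_, r1 = NA_real_,
                    r2 = NA_real_)
  for (i in seq_along(zn)) {
    inz <- zones$values == zone_code(zn[i])
    tab$urban_ha[i] <- sum(urb & inz) * cell_ha
    tab$green_ha[i] <- sum(green & inz) * cell_ha
    tab$green_near_urban_ha[i] <- sum(green & inz & near_urban) * cell_ha
    tab$r1[i] <- if (tab$urban_ha[i] > 0)
      tab$green_near_urban_ha[i] / tab$urban_ha[i] else NA_real_
    tab$r2[i] <- tab$green_ha[i] / pop[[zn[i]]]
  }
  norm01 <- function(x) {
    rng <- range(x, na.rm = TRUE)
    if (!is.finite(rng[1])) return(rep(0, length(x)))
    if (diff(rng) == 0) rep(0.5, length(x)) else (x - rng[1]) / diff(rng)
  }
  score <- (norm01(tab$r1) + norm01(tab$r2)) / 2
  score[is.na(tab$r1)] <- -Inf          # no urban area: ranked last
  ord <- order(-score, seq_along(zn))   # ties: fixed order N, W, S, E
  w <- numeric(4)
  w[ord] <- weights
  names(w) <- zn
  tab$rank <- match(seq_along(zn), ord)
  structure(list(weights = w, table = tab), class = "gg_zone_weights")
}

#' Apply zone weights to an urbanization likelihood layer
#'
#' Per-cell suitability = likelihood times the zone weight divided by the
#' maximum weight, preserving the 0-100 scale (the best zone keeps its
#' likelihood; others are scaled down).
#'
#' @param likelihood a [run_prediction()] result or 0-100 [grid()].
#' @param zones from [zone_partition()].
#' @param zw a [equity_weights()] result, or a named weight vector.
#' @return a continuous suitability [grid()] on 0-100.
#' @export
apply_weights <- function(likelihood, zones, zw) {
  lik <- if (inherits(likelihood, "gg_likelihood"))
    likelihood$likelihood else likelihood
  w <- if (inherits(zw, "gg_zone_weights")) zw$weights else zw
  wmax <- max(w)
  fac <- matrix(0, nrow(lik$values), ncol(lik$values))
  for (zn in names(w))
    fac[zones$values == zone_code(zn)] <- w[[zn]] / wmax
  grid(lik$values * fac, lik$cellsize_m, kind = "continuous")
}

#' Select urbanization polygons from a suitability surface
#'
#' Thresholds the suitability at `min_suit`, labels 8-connected
#' components, drops components below `min_area_ha`, ranks the rest by
#' mean suitability (ties by larger area, then by label), and keeps
#' either the first `n` polygons (`top_n` mode) or accumulates ranked
#' polygons up to an area cap. In `area_cap` mode the remainder after
#' the last whole polygon is filled with the highest-suitability
#' individual cells of the next-ranked polygon, so the cap is met
#' exactly when enough candidate area exists (the pixel-level compact
#' variant).
#'
#' @param suitability a 0-100 [grid()].
#' @param min_suit minimum suitability (default 50).
#' @param min_area_ha minimum polygon area in hectares (default 30).
#' @param mode `list(type = "top_n", n = 10)` or
#'   `list(type = "area_cap", cap_ha = ..., fill_cells = TRUE)`.
#' @return a `gg_selection`: `labels` (selected-polygon [grid()], labels
#'   are selection ranks), `table` (per-polygon area and mean
#'   suitability), `total_ha`.
#' @export
select_polygons <- function(suitability, min_suit = 50, min_area_ha = 30,
                            mode = list(type = "top_n", n = 10)) {
  stopifnot(inherits(suitability, "gg_grid"))
  v <- suitability$values
  cell_ha <- suitability$cellsize_m^2 / 1e4
  lab <- label_components(v >= min_suit, 8)
  out <- matrix(0L, nrow(v), ncol(v))
  empty <- structure(list(
    labels = grid(out, suitability$cellsize_m, kind = "continuous"),
    table = data.frame(rank = integer(0), area_ha = numeric(0),
                       mean_suit = numeric(0)),
    total_ha = 0), class = "gg_selection")
  if (max(lab) == 0) return(empty)
  n0 <- max(lab)
  area <- tabulate(lab[lab > 0], n0) * cell_ha
  msuit <- as.numeric(tapply(v[lab > 0], lab[lab > 0], mean))
  keep <- which(area >= min_area_ha)
  if (length(keep) == 0) return(empty)
  ord <- keep[order(-msuit[keep], -area[keep], keep)]
  sel_ids <- integer(0)
  partial <- NULL
  if (mode$type == "top_n") {
    sel_ids <- utils::head(ord, mode$n)
  } else if (mode$type == "area_cap") {
    cum <- 0
    for (id in ord) {
      if (cum + area[id] > mode$cap_ha) {
        if (isTRUE(mode$fill_cells %||% TRUE)) {
          n_fill <- floor((mode$cap_ha - cum) / cell_ha)
          if (n_fill > 0) partial <- list(id = id, n = n_fill)
        }
        break
      }
      cum <- cum + area[id]
      sel_ids <- c(sel_ids, id)
    }
  } else stop("unknown selection mode: ", mode$type)
  rnk <- 0
  rows <- list()
  for (id in sel_ids) {
    rnk <- rnk + 1
    out[lab == id] <- rnk
    rows[[rnk]] <- data.frame(rank = rnk, area_ha = area[id],
                              mean_suit = msuit[id])
  }
  if (!is.null(partial)) {
    cells <- which(lab == partial$id)
    cells <- cells[order(-v[cells])][seq_len(partial$n)]
    rnk <- rnk + 1
    out[cells] <- rnk
    rows[[rnk]] <- data.frame(rank = rnk, area_ha = partial$n * cell_ha,
                              mean_suit = mean(v[cells]))
  }
  tab <- if (length(rows)) do.call(rbind, rows)
  else data.frame(rank = integer(0), area_ha = numeric(0),
                  mean_suit = numeric(0))
  structure(list(labels = grid(out, suitability$cellsize_m,
                               kind = "continuous"),
                 table = tab, total_ha = sum(tab$area_ha)),
            class = "gg_selection")
}

#' @export
print.gg_selection <- function(x, ...) {
  cat(sprintf("<gg_selection> %d polygons, %.2f ha\n", nrow(x$table),
              x$total_ha))
  invisible(x)
}

#' The eight-scenario factory
#'
#' The full 2 x 2 x 2 design over exclusion variant (base vs
#' green-space-informed), coefficient variant (calibrated vs compact
#' transform) and likelihood weighting (unweighted vs equity-weighted),
#' named as in the study design.
#'
#' @return a data frame with columns `no`, `name`, `exclusion`,
#'   `coefficients`, `weighting`.
#' @export
scenario_table <- function() {
  data.frame(
    no = 1:8,
    name = c("Usual Growth", "Compact Growth", "Social Equity Growth",
             "Compact-Social Equity Growth", "MSPA-Informed Growth",
             "MSPA-Informed Compact Growth",
             "MSPA-Informed Social Equity Growth",
             "MSPA-Informed Compact-Social Equity Growth"),
    exclusion = rep(c("exclusion1", "exclusion2"), each = 4),
    coefficients = rep(c("calibrated", "compact"), 4),
    weighting = rep(rep(c("unweighted", "equity-weighted"), each = 2), 2),
    stringsAsFactors = FALSE)
}
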