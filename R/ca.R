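#' Growth coefficients for the cellular automaton
#'
#' The five classic growth coefficients, each an integer in 0-100, plus
#' the diffusion multiplier `D_M` that scales the number of
#' spontaneous-growth attempts, and the critical slope (percent) above
#' which urbanization is impossible.
#'
#' @param diffusion,breed,spread,slope_resistance,road_gravity integers
#'   in \[0, 100\].
#' @param D_M positive diffusion multiplier (default 0.005).
#' @param critical_slope_pct critical slope in percent (default 21).
#' @return a `gg_coeffs` list.
#' @export
coefficient_set <- function(diffusion = 1, breed = 1, spread = 1,
                            slope_resistance = 1, road_gravity = 1,
                            D_M = 0.005, critical_slope_pct = 21) {
  for (x in c(diffusion, breed, spread, slope_resistance, road_gravity))
    if (x < 0 || x > 100) stop("coefficients must lie in [0, 100]")
  if (D_M <= 0) stop("D_M must be positive")
  structure(list(diffusion = diffusion, breed = breed, spread = spread,
                 slope_resistance = slope_resistance,
                 road_gravity = road_gravity, D_M = D_M,
                 critical_slope_pct = critical_slope_pct),
            class = "gg_coeffs")
}

#' @export
print.gg_coeffs <- function(x, ...) {
  cat(sprintf(
    "<gg_coeffs> D %d B %d S %d SR %d RG %d | D_M %g, critical slope %g%%\n",
    x$diffusion, x$breed, x$spread, x$slope_resistance, x$road_gravity,
    x$D_M, x$critical_slope_pct))
  invisible(x)
}

# Vectorized urbanization gates. `cells` are candidate cell indices;
# returns the subset that passes both the exclusion gate (reject with
# probability exclusion/100; 100 always rejects) and the slope gate
# (reject outright at slope >= critical; otherwise accept with
# probability ((critical - slope)/critical)^(slope_resistance/25)).
pass_gates <- function(cells, excl, slope, coeffs) {
  if (length(cells) == 0) return(cells)
  e <- excl[cells]
  keep <- e < 100 & stats::runif(length(cells)) >= e / 100
  cells <- cells[keep]
  if (length(cells) == 0) return(cells)
  s <- slope[cells]
  cs <- coeffs$critical_slope_pct
  ok <- s < cs
  p <- rep(0, length(cells))
  p[ok] <- ((cs - s[ok]) / cs)^(coeffs$slope_resistance / 25)
  cells[stats::runif(length(cells)) < p]
}

# Attempt to urbanize up to `k` random eligible 8-neighbours of `cell`.
urbanize_neighbours <- function(cell, k, urban, excl, slope, coeffs) {
  nr <- nrow(urban); nc <- ncol(urban)
  r <- ((cell - 1) %% nr) + 1; co <- ((cell - 1) %/% nr) + 1
  off <- neighbour_offsets(8)
  r2 <- r + off[, 1]; c2 <- co + off[, 2]
  ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
  nb <- (c2[ok] - 1) * nr + r2[ok]
  nb <- nb[!urban[nb]]
  if (length(nb) == 0) return(integer(0))
  nb <- nb[sample.int(length(nb))]
  pass_gates(nb[seq_len(min(k, length(nb)))], excl, slope, coeffs)
}

#' One annual step of the growth automaton
#'
#' Applies the four growth rules in order:
#'
#' 1. **Spontaneous**: `round(D_M * diffusion * sqrt(rows^2 + cols^2))`
#'    uniformly random cells are each tested for urbanization.
#' 2. **New spreading centre**: each cell urbanized by rule 1 becomes a
#'    centre with probability `breed/100`, urbanizing up to two random
#'    eligible neighbours.
#' 3. **Edge**: every non-urban cell with at least three urban
#'    8-neighbours urbanizes with probability `spread/100`.
#' 4. **Road-influenced**: for `round(breed/100 * n_new)` trips (with
#'    `n_new` the cells newly urbanized by rules 1-3), a newly urbanized
#'    cell is picked at random; if a road cell lies within radius
#'    `road_gravity/100 * (rows + cols)/16`, a random walk along the road
#'    network runs for `max(1, round(road_walk_frac * n_attempts))` steps
#'    and up to two neighbours of the endpoint are tested for
#'    urbanization.
#'
#' Every urbanization attempt passes two gates: the exclusion gate
#' (reject with probability `exclusion/100`; 100 always rejects) and the
#' slope gate (reject outright at or above the critical slope, else
#' accept with probability
#' `((critical - slope)/critical)^(slope_resistance/25)`).
#'
#' The caller controls the RNG state; [run_prediction()] seeds one
#' substream per rule, year and Monte-Carlo run.
#'
#' @param urban logical or 0/1 matrix of urban cells.
#' @param coeffs a [coefficient_set()].
#' @param slope slope matrix in percent.
#' @param excl exclusion matrix 0-100.
#' @param roads logical or 0/1 road matrix.
#' @param road_walk_frac road-walk length as a fraction of the rule-1
#'   attempt count (default 0.05).
#' @param rule_seeds optional integer vector of four seeds, one per rule.
#' @return logical matrix of urban cells after the step.
#' @export
ca_step <- function(urban, coeffs, slope, excl, roads,
                    road_walk_frac = 0.05, rule_seeds = NULL) {
  u <- urban == 1
  nr <- nrow(u); nc <- ncol(u)
  n_attempts <- round(coeffs$D_M * coeffs$diffusion * sqrt(nr^2 + nc^2))

  # rule 1: spontaneous
  if (!is.null(rule_seeds)) set.seed(rule_seeds[1])
  new1 <- integer(0)
  if (n_attempts > 0 && coeffs$diffusion > 0) {
    cand <- sample.int(nr * nc, n_attempts, replace = TRUE)
    cand <- unique(cand[!u[cand]])
    new1 <- pass_gates(cand, excl, slope, coeffs)
    u[new1] <- TRUE
  }

  # rule 2: new spreading centres
  if (!is.null(rule_seeds)) set.seed(rule_seeds[2])
  new2 <- integer(0)
  if (length(new1) > 0 && coeffs$breed > 0) {
    centres <- new1[stats::runif(length(new1)) < coeffs$breed / 100]
    for (cell in centres) {
      got <- urbanize_neighbours(cell, 2, u, excl, slope, coeffs)
      u[got] <- TRUE
      new2 <- c(new2, got)
    }
  }

  # rule 3: edge growth
  if (!is.null(rule_seeds)) set.seed(rule_seeds[3])
  new3 <- integer(0)
  if (coeffs$spread > 0) {
    cand <- which(!u & neighbour_count(u, 8) >= 3)
    cand <- cand[stats::runif(length(cand)) < coeffs$spread / 100]
    new3 <- pass_gates(cand, excl, slope, coeffs)
    u[new3] <- TRUE
  }

  # rule 4: road-influenced growth
  if (!is.null(rule_seeds)) set.seed(rule_seeds[4])
  new_cells <- c(new1, new2, new3)
  n_trips <- round(coeffs$breed / 100 * length(new_cells))
  if (n_trips > 0 && coeffs$road_gravity > 0 && any(roads == 1)) {
    radius <- coeffs$road_gravity / 100 * (nr + nc) / 16
    walk_len <- max(1, round(road_walk_frac * max(n_attempts, 1)))
    road_idx <- which(roads == 1)
    rr <- ((road_idx - 1) %% nr) + 1; rc <- ((road_idx - 1) %/% nr) + 1
    for (trip in seq_len(n_trips)) {
      cell <- new_cells[sample.int(length(new_cells), 1)]
      pr <- ((cell - 1) %% nr) + 1; pc <- ((cell - 1) %/% nr) + 1
      d2 <- (rr - pr)^2 + (rc - pc)^2
      j <- which.min(d2)
      if (sqrt(d2[j]) > radius) next
      # random walk along road cells (8-connected)
      pos <- road_idx[j]
      for (stp in seq_len(walk_len)) {
        wr <- ((pos - 1) %% nr) + 1; wc <- ((pos - 1) %/% nr) + 1
        off <- neighbour_offsets(8)
        r2 <- wr + off[, 1]; c2 <- wc + off[, 2]
        ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
        nb <- (c2[ok] - 1) * nr + r2[ok]
        nb <- nb[roads[nb] == 1]
        if (length(nb) == 0) break
        pos <- nb[sample.int(length(nb), 1)]
      }
      got <- urbanize_neighbours(pos, 2, u, excl, slope, coeffs)
      u[got] <- TRUE
    }
  }
  u
}

#' Monte-Carlo prediction run
#'
#' Runs `n_mc` independent simulations of annual steps from `start_year`
#' to `stop_year`, each from the same seed-urban map, and reports the
#' per-cell urbanization likelihood (percent of runs urbanized by the
#' stop year; seed-urban cells are 100 by construction) and a predicted
#' LULC layer (the base LULC with cells of likelihood >= 50 recoded
#' urban).
#'
#' Each rule in each year of each run draws from its own seed substream
#' derived from `seed`, so extending the horizon replays the shared
#' prefix of the randomness and likelihood is monotone in years
#' simulated.
#'
#' @param seed_urban binary [grid()] of urban cells at `start_year`.
#' @param coeffs a [coefficient_set()].
#' @param slope slope [grid()] (percent).
#' @param excl a `gg_exclusion` or 0-100 [grid()].
#' @param roads binary road [grid()].
#' @param lulc base categorical LULC [grid()] for the predicted layer.
#' @param start_year,stop_year simulation horizon (`stop_year` >
#'   `start_year`).
#' @param n_mc number of Monte-Carlo runs (default 10).
#' @param seed master seed.
#' @param road_walk_frac see [ca_step()].
#' @return a `gg_likelihood`: `likelihood` ([grid()] 0-100),
#'   `predicted_lulc` ([grid()]), `n_mc`, `target_year`.
#' @export
run_prediction <- function(seed_urban, coeffs, slope, excl, roads, lulc = NULL,
                           start_year, stop_year, n_mc = 10, seed = 1,
                           road_walk_frac = 0.05) {
  stopifnot(stop_year > start_year, n_mc >= 1)
  ex <- if (inherits(excl, "gg_exclusion")) excl$grid$values else excl$values
  sl <- slope$values
  rd <- roads$values
  u0 <- seed_urban$values == 1
  freq <- matrix(0, nrow(u0), ncol(u0))
  years <- seq(start_year + 1, stop_year)
  for (mc in seq_len(n_mc)) {
    u <- u0
    for (yr in years) {
      rs <- vapply(1:4, function(rule)
        child_seed(seed, "mc", mc, "yr", yr, "rule", rule), integer(1))
      u <- ca_step(u, coeffs, sl, ex, rd, road_walk_frac, rule_seeds = rs)
    }
    freq <- freq + u
  }
  lik <- 100 * freq / n_mc
  pred <- NULL
  if (!is.null(lulc)) {
    pv <- lulc$values
    pv[lik >= 50] <- 4
    pred <- grid(pv, lulc$cellsize_m, kind = "categorical", codes = lulc$codes)
  }
  structure(list(likelihood = grid(lik, seed_urban$cellsize_m,
                                   kind = "continuous"),
                 predicted_lulc = pred, n_mc = n_mc, target_year = stop_year),
            class = "gg_likelihood")
}

#' The diffusion-multiplier test sequence
#'
#' Arithmetic sequence from `start` to `stop` in steps of `step`
#' (inclusive, robust to floating-point drift). The default sweep 0.001
#' by 0.003 to 0.124 enumerates 42 values.
#'
#' @param start,step,stop sweep specification.
#' @return numeric vector of D_M values.
#' @export
dm_sequence <- function(start = 0.001, step = 0.003, stop = 0.124) {
  stopifnot(start <= stop, step > 0)
  k <- floor((stop - start) / step + 1e-9)
  start + step * (0:k)
}

# 8-connected cluster count of a binary matrix.
cluster_count <- function(mask) max(label_components(mask == 1, 8), 0)

#' Sweep the diffusion multiplier against observed clustering
#'
#' For each D_M in the sequence, simulates growth from the first to the
#' last observed epoch with diffusion 100 and all other coefficients 1,
#' and scores the cluster fractional difference
#' `CFD = (simulated clusters - observed clusters) / observed clusters`
#' against the final-epoch urban map (8-connected clusters, mean over
#' Monte-Carlo runs). The best D_M minimizes `|CFD|`.
#'
#' @param stack a [layer_stack()] with urban epochs, slope, roads and
#'   exclusion.
#' @param excl a `gg_exclusion` (defaults to the stack's `exclusion`
#'   layer).
#' @param start,step,stop sweep bounds (defaults 0.001 / 0.003 / 0.124).
#' @param n_mc Monte-Carlo runs per D_M (default 5).
#' @param seed master seed.
#' @return a `gg_dm_sweep`: `records` (data frame of D_M, mean simulated
#'   clusters, CFD), `best_dm`, `observed_clusters`.
#' @export
dm_sweep <- function(stack, excl = NULL, start = 0.001, step = 0.003,
                     stop = 0.124, n_mc = 5, seed = 1) {
  urb_names <- stack_epochs(stack, "urban")
  stopifnot(length(urb_names) >= 2)
  first <- stack[[urb_names[1]]]
  last <- stack[[utils::tail(urb_names, 1)]]
  years <- as.integer(sub("urban_", "", c(urb_names[1], utils::tail(urb_names, 1))))
  obs <- cluster_count(last$values)
  if (obs == 0) stop("observed final-epoch urban map has zero clusters")
  ex <- if (is.null(excl)) stack$exclusion else excl
  road_last <- stack[[utils::tail(stack_epochs(stack, "roads"), 1)]]
  dms <- dm_sequence(start, step, stop)
  sim_cl <- numeric(length(dms))
  for (i in seq_along(dms)) {
    co <- coefficient_set(diffusion = 100, breed = 1, spread = 1,
                          slope_resistance = 1, road_gravity = 1,
                          D_M = dms[i])
    exv <- if (inherits(ex, "gg_exclusion")) ex$grid$values else ex$values
    cl <- vapply(seq_len(n_mc), function(mc) {
      u <- first$values == 1
      for (yr in seq(years[1] + 1, years[2])) {
        rs <- vapply(1:4, function(rule)
          child_seed(child_seed(seed, "dm", i), "mc", mc, "yr", yr,
                     "rule", rule), integer(1))
        u <- ca_step(u, co, stack$slope$values, exv, road_last$values,
                     rule_seeds = rs)
      }
      cluster_count(u)
    }, numeric(1))
    sim_cl[i] <- mean(cl)
  }
  cfd <- (sim_cl - obs) / obs
  records <- data.frame(D_M = dms, sim_clusters = sim_cl, CFD = cfd)
  structure(list(records = records, best_dm = dms[which.min(abs(cfd))],
                 observed_clusters = obs),
            class = "gg_dm_sweep")
}
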