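# Staged calibration of the growth coefficients and prediction validation.

# Squared Pearson correlation with a defined value for constant series:
# identical constants score 1, otherwise 0.
r_squared <- function(sim, obs) {
  if (stats::sd(sim) == 0 || stats::sd(obs) == 0)
    return(as.numeric(isTRUE(all.equal(as.numeric(sim), as.numeric(obs)))))
  stats::cor(sim, obs)^2
}

# Per-map urban statistics used by the fit metrics.
urban_stats <- function(u, slope) {
  n <- sum(u)
  if (n == 0)
    return(c(pop = 0, edges = 0, clusters = 0, xmean = 0, ymean = 0, slope = 0))
  nr <- nrow(u)
  idx <- which(u)
  r <- ((idx - 1) %% nr) + 1; co <- ((idx - 1) %/% nr) + 1
  edges <- sum(u & neighbour_count(!u, 8) > 0)
  c(pop = n, edges = edges, clusters = cluster_count(u),
    xmean = mean(co), ymean = mean(r), slope = mean(slope[idx]))
}

# Class-match score on six-class maps: fraction of cells whose predicted
# class equals observed, restricted to cells that changed in either map
# relative to the base LULC. 1 when nothing changed anywhere.
fmatch_score <- function(pred_lulc, obs_lulc, base_lulc) {
  changed <- pred_lulc != base_lulc | obs_lulc != base_lulc
  if (!any(changed)) return(1)
  mean(pred_lulc[changed] == obs_lulc[changed])
}

#' Stage specifications for calibration
#'
#' Three stages with progressively finer grid steps and more Monte-Carlo
#' runs, following the usual coarse/fine/final practice (default steps
#' 25/10/5 and 6/8/10 runs). The first stage explores `initial` values
#' per coefficient; later stages narrow to the hull of the top
#' survivors.
#'
#' @param steps grid step per stage.
#' @param n_mc Monte-Carlo runs per stage.
#' @param initial named list of candidate values for the first stage
#'   (default the full 0-100 range at the coarse step).
#' @param keep_top survivors kept after each stage (default 3).
#' @return a list of stage specs for [ca_calibrate()].
#' @export
calibration_stages <- function(steps = c(25, 10, 5), n_mc = c(6, 8, 10),
                               initial = NULL, keep_top = 3) {
  stopifnot(length(steps) == length(n_mc))
  if (is.null(initial))
    initial <- stats::setNames(rep(list(seq(0, 100, by = steps[1])), 5),
                               c("diffusion", "breed", "spread",
                                 "slope_resistance", "road_gravity"))
  lapply(seq_along(steps), function(i)
    list(step = steps[i], n_mc = n_mc[i], keep_top = keep_top,
         initial = if (i == 1) initial else NULL))
}

# Simulate one coefficient combination and return averaged fit metrics.
eval_combo <- function(co, first_urban, slope, exv, roads, control_years,
                       obs_stats, obs_final_count, lulc_base, lulc_obs,
                       n_mc, seed, road_walk_frac = 0.05) {
  years <- seq(control_years[1] + 1, utils::tail(control_years, 1))
  stat_sum <- 0
  final_count <- 0
  fmatch <- 0
  for (mc in seq_len(n_mc)) {
    u <- first_urban
    sim_stats <- list(urban_stats(u, slope))
    for (yr in years) {
      rs <- vapply(1:4, function(rule)
        child_seed(seed, "mc", mc, "yr", yr, "rule", rule), integer(1))
      u <- ca_step(u, co, slope, exv, roads, road_walk_frac, rule_seeds = rs)
      if (yr %in% control_years) sim_stats[[length(sim_stats) + 1]] <-
          urban_stats(u, slope)
    }
    stat_sum <- stat_sum + do.call(rbind, sim_stats)
    final_count <- final_count + sum(u)
    if (!is.null(lulc_base)) {
      pred <- lulc_base
      pred[u] <- 4
      fmatch <- fmatch + fmatch_score(pred, lulc_obs, lulc_base)
    }
  }
  sim <- stat_sum / n_mc
  final_count <- final_count / n_mc
  metrics <- c(
    compare = min(final_count, obs_final_count) /
      max(final_count, obs_final_count, 1),
    pop = r_squared(sim[, "pop"], obs_stats[, "pop"]),
    edges = r_squared(sim[, "edges"], obs_stats[, "edges"]),
    clusters = r_squared(sim[, "clusters"], obs_stats[, "clusters"]),
    slope = r_squared(sim[, "slope"], obs_stats[, "slope"]),
    xmean = r_squared(sim[, "xmean"], obs_stats[, "xmean"]),
    ymean = r_squared(sim[, "ymean"], obs_stats[, "ymean"]),
    fmatch = if (is.null(lulc_base)) 1 else fmatch / n_mc)
  c(metrics, OSM = prod(metrics))
}

#' Staged grid-search calibration of the growth coefficients
#'
#' Exhaustive grid search over each stage's candidate coefficient values.
#' Every combination is simulated from the first control year and scored
#' against the observed urban maps with eight fit metrics: `compare`
#' (ratio of final urban counts), `pop`, `edges`, `clusters`, `xmean`,
#' `ymean` (r-squared across control years of urban count, urban edge
#' count, cluster count and the urban centroid coordinates), `slope`
#' (r-squared of the mean slope of urbanized cells) and `fmatch`
#' (class-match score of predicted vs observed final LULC on changed
#' cells). Their product is the overall score used for ranking. After
#' each stage the top `keep_top` combinations are kept and the next
#' stage's candidate values span their hull at the finer step.
#'
#' @param stack a [layer_stack()] with >= 2 urban epochs, slope, roads.
#' @param excl a `gg_exclusion` or 0-100 [grid()] (defaults to the
#'   stack's `exclusion` layer).
#' @param stages from [calibration_stages()].
#' @param D_M diffusion multiplier (fixed during calibration).
#' @param critical_slope_pct critical slope passed to the automaton.
#' @param seed master seed.
#' @param road_walk_frac see [ca_step()].
#' @param max_combos cap on combinations per stage; larger grids are
#'   thinned to an evenly spaced subset (default unlimited).
#' @return a `gg_calibration`: `stages` (list of record data frames
#'   sorted by OSM), `best` (a [coefficient_set()]), `best_osm`.
#' @export
ca_calibrate <- function(stack, excl = NULL, stages = calibration_stages(),
                         D_M = 0.005, critical_slope_pct = 21, seed = 1,
                         road_walk_frac = 0.05, max_combos = Inf) {
  urb_names <- stack_epochs(stack, "urban")
  stopifnot(length(urb_names) >= 2)
  control_years <- as.integer(sub("urban_", "", urb_names))
  ex <- if (is.null(excl)) stack$exclusion else excl
  exv <- if (inherits(ex, "gg_exclusion")) ex$grid$values else ex$values
  slope <- stack$slope$values
  roads <- stack[[utils::tail(stack_epochs(stack, "roads"), 1)]]$values
  first_urban <- stack[[urb_names[1]]]$values == 1
  obs_stats <- do.call(rbind, lapply(urb_names, function(nm)
    urban_stats(stack[[nm]]$values == 1, slope)))
  obs_final_count <- sum(stack[[utils::tail(urb_names, 1)]]$values == 1)
  lulc_names <- stack_epochs(stack, "lulc")
  lulc_base <- if (length(lulc_names) >= 2) stack[[lulc_names[1]]]$values
  lulc_obs <- if (length(lulc_names) >= 2)
    stack[[utils::tail(lulc_names, 1)]]$values

  coef_names <- c("diffusion", "breed", "spread", "slope_resistance",
                  "road_gravity")
  values <- stages[[1]]$initial
  stopifnot(!is.null(values), all(coef_names %in% names(values)))
  stage_records <- list()
  survivors <- NULL
  for (si in seq_along(stages)) {
    sp <- stages[[si]]
    if (si > 1) {
      values <- lapply(coef_names, function(cn) {
        lo <- min(survivors[[cn]]); hi <- max(survivors[[cn]])
        unique(pmin(100, c(seq(lo, hi, by = sp$step), hi)))
      })
      names(values) <- coef_names
    }
    combos <- expand.grid(values[coef_names], KEEP.OUT.ATTRS = FALSE)
    if (nrow(combos) == 0) stop("empty range spec at stage ", si)
    if (nrow(combos) > max_combos)
      combos <- combos[round(seq(1, nrow(combos),
                                 length.out = max_combos)), , drop = FALSE]
    res <- t(vapply(seq_len(nrow(combos)), function(k) {
      co <- coefficient_set(
        diffusion = combos$diffusion[k], breed = combos$breed[k],
        spread = combos$spread[k],
        slope_resistance = combos$slope_resistance[k],
        road_gravity = combos$road_gravity[k], D_M = D_M,
        critical_slope_pct = critical_slope_pct)
      eval_combo(co, first_urban, slope, exv, roads, control_years,
                 obs_stats, obs_final_count, lulc_base, lulc_obs,
                 sp$n_mc, child_seed(seed, "stage", si, "combo", k),
                 road_walk_frac)
    }, numeric(9)))
    rec <- cbind(combos, as.data.frame(res))
    rec <- rec[order(-rec$OSM), ]
    rownames(rec) <- NULL
    stage_records[[si]] <- rec
    survivors <- utils::head(rec, sp$keep_top %||% 3)
  }
  best <- stage_records[[length(stages)]][1, ]
  structure(list(
    stages = stage_records,
    best = coefficient_set(
      diffusion = best$diffusion, breed = best$breed, spread = best$spread,
      slope_resistance = best$slope_resistance,
      road_gravity = best$road_gravity, D_M = D_M,
      critical_slope_pct = critical_slope_pct),
    best_osm = best$OSM),
    class = "gg_calibration")
}

# Average precision (area under the precision-recall curve) with tied
# scores grouped, by step integration.
pr_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1)
  if (npos == 0) return(NA_real_)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- fp <- 0
  ap <- 0
  r_prev <- 0
  for (th in thr) {
    sel <- scores == th
    tp <- tp + sum(labels[sel] == 1)
    fp <- fp + sum(labels[sel] == 0)
    prec <- tp / (tp + fp)
    rec <- tp / npos
    ap <- ap + (rec - r_prev) * prec
    r_prev <- rec
  }
  ap
}

#' Validate a prediction against an observed urban map
#'
#' Evaluation is restricted to cells that were non-urban at the seed
#' year. Reports the area under the ROC curve and the precision-recall
#' curve of the likelihood scores against observed urbanization, and the
#' figure of merit `hits / (hits + misses + false alarms)` of the binary
#' map `likelihood >= threshold` (hits = observed change predicted as
#' change; misses = observed change predicted persistent; false alarms =
#' observed persistence predicted as change).
#'
#' @param likelihood a [run_prediction()] result or a 0-100 [grid()].
#' @param observed_urban binary [grid()] at the target year.
#' @param seed_urban binary [grid()] at the start year.
#' @param threshold likelihood cutoff for the binary map (default 50).
#' @return list with `auc_roc`, `auc_pr`, `fom`.
#' @export
ca_validate <- function(likelihood, observed_urban, seed_urban,
                        threshold = 50) {
  lik <- if (inherits(likelihood, "gg_likelihood"))
    likelihood$likelihood$values else likelihood$values
  eval_cells <- seed_urban$values == 0
  scores <- lik[eval_cells]
  labels <- as.integer(observed_urban$values[eval_cells] == 1)
  pred_change <- scores >= threshold
  hits <- sum(labels == 1 & pred_change)
  misses <- sum(labels == 1 & !pred_change)
  fa <- sum(labels == 0 & pred_change)
  if (hits + misses + fa == 0)
    stop("no change cells: figure of merit undefined")
  auc_roc <- if (length(unique(scores)) < 2 || length(unique(labels)) < 2) 0.5
  else as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                      direction = "<")))
  list(auc_roc = auc_roc, auc_pr = pr_auc(scores, labels),
       fom = hits / (hits + misses + fa))
}
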