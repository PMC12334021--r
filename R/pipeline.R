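#' Pipeline configuration
#'
#' Bundles every stage parameter of the end-to-end run. Defaults are
#' sized for a shrunk synthetic landscape; `demand_levels` defaults to
#' the full-landscape demands (23,850 and 2,385 ha) scaled by the ratio
#' of the configured grid area to the reference 1000 x 1000 grid, so a
#' 200 x 200 run asks for the same fraction of its landscape.
#'
#' @param params a [landscape_params()] (the synthetic input generator).
#' @param out_dir output directory for artifacts (default a tempdir).
#' @param seed master seed; every stage derives a child seed from it.
#' @param demand_levels demand in hectares, one per level (default
#'   scaled 23,850 and 2,385).
#' @param edge_width,half_distance_m MSPA edge width (cells) and
#'   dispersal half-distance (m).
#' @param pair_budget maximum focal pairs for the current map.
#' @param excl_resistance named resistances for the base exclusion
#'   (water/wetland/roads).
#' @param dm_args list of arguments for [dm_sweep()] (set `run = FALSE`
#'   to skip and use `D_M`).
#' @param D_M fallback diffusion multiplier when the sweep is skipped.
#' @param stages calibration stage specs (see [calibration_stages()]);
#'   defaults to a compact three-value search suited to desk-scale
#'   grids.
#' @param max_combos cap on coefficient combinations evaluated per
#'   calibration stage.
#' @param predict_to target year (default 2050).
#' @param n_mc_predict Monte-Carlo runs for prediction (default 4).
#' @param min_suit,min_area_ha polygon selection thresholds.
#' @param topsis_iters weight-perturbation iterations in the ranking
#'   stage (default 500).
#' @return a `gg_pipeline_config` list.
#' @export
pipeline_config <- function(params = shrink(landscape_params(), 5),
                            out_dir = file.path(tempdir(), "greengrowth-run"),
                            seed = 1,
                            demand_levels = NULL,
                            edge_width = 1,
                            half_distance_m = 500,
                            pair_budget = 40,
                            excl_resistance = c(water = 100, wetland = 70,
                                                roads = 50),
                            dm_args = list(run = TRUE, start = 0.001,
                                           step = 0.003, stop = 0.124,
                                           n_mc = 2),
                            D_M = 0.005,
                            stages = NULL,
                            max_combos = 300,
                            predict_to = 2050,
                            n_mc_predict = 4,
                            min_suit = 50,
                            min_area_ha = 30,
                            topsis_iters = 500) {
  stopifnot(inherits(params, "gg_landscape_params"))
  if (is.null(demand_levels)) {
    scale <- (params$rows * params$cols) / 1e6
    demand_levels <- c(23850, 2385) * scale
  }
  if (is.null(stages))
    stages <- calibration_stages(
      steps = c(50, 25), n_mc = c(2, 2), keep_top = 2,
      initial = list(diffusion = c(1, 50, 100), breed = c(1, 50),
                     spread = c(1, 50, 100), slope_resistance = c(1, 50),
                     road_gravity = c(1, 50)))
  structure(as.list(environment()), class = "gg_pipeline_config")
}

write_artifact <- function(obj, path) {
  if (inherits(obj, "gg_grid")) write_grid(obj, path)
  else utils::write.csv(obj, path, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes the stages in order: synthetic landscape -> morphological
#' segmentation -> core importance -> corridor current -> exclusion
#' layers -> diffusion-multiplier sweep -> staged calibration (per
#' exclusion variant) -> Monte-Carlo prediction -> the eight scenarios ->
#' polygon selection per demand level -> impact assessment -> TOPSIS
#' ranking with weight perturbation. Every intermediate raster and table
#' is written under `config$out_dir` and recorded, with an md5 content
#' hash, in the returned manifest.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress (default TRUE).
#' @return a `gg_manifest`: `artifacts` (data frame of stage, file,
#'   md5), `rankings` (per demand level), `impacts`, `coeffs`, `best_dm`,
#'   `seed`, `out_dir`, plus in-memory stage objects in `objects`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(config, "gg_pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  note <- function(stage, name, obj) {
    path <- file.path(config$out_dir, name)
    write_artifact(obj, path)
    files[[length(files) + 1]] <<- data.frame(stage = stage, file = name,
                                              md5 = unname(tools::md5sum(path)))
  }
  say <- function(...) if (verbose)
    message(sprintf("[%5.1fs] ", as.numeric(difftime(Sys.time(), t0, units = "secs"))), ...)

  seed <- config$seed
  p <- config$params
  p$seed <- child_seed(seed, "synth")

  say("synthetic landscape ", p$rows, "x", p$cols)
  syn <- generate_stack(p)
  stack <- syn$stack
  epochs <- p$epochs
  final <- utils::tail(epochs, 1)
  for (nm in names(stack)) note("synth", paste0(nm, ".asc"), stack[[nm]])
  note("synth", "zone_population.csv",
       data.frame(zone = names(syn$population),
                  population = as.numeric(syn$population)))
  issues <- validate_stack(stack)
  if (nrow(issues) > 0)
    stop("invalid stack: ", paste(issues$issue, issues$detail, collapse = "; "))

  say("morphological segmentation")
  lulc_final <- stack[[paste0("lulc_", final)]]
  green <- grid((lulc_final$values == 2) * 1, lulc_final$cellsize_m,
                kind = "binary")
  seg <- mspa_segment(green, edge_width = config$edge_width)
  cores <- mspa_extract_cores(seg)
  if (cores$n < 2) stop("synthetic landscape yielded fewer than 2 core patches")
  note("mspa", "mspa_classes.asc", seg$map)
  note("mspa", "core_patches.asc", cores$labels)

  say("core importance (", cores$n, " patches)")
  pg <- build_patch_graph(cores, A_L = area_of_grid(green),
                          d_half = config$half_distance_m)
  imp <- compute_dpc(pg)
  imp_grid <- rasterize_importance(cores, imp)
  note("importance", "dpc.csv",
       data.frame(patch_id = seq_len(cores$n), area_ha = cores$area_ha,
                  dPC = imp$dPC))
  note("importance", "importance.asc", imp_grid)

  say("corridor current map")
  cond <- build_conductance(lulc_final, seg,
                            roads = stack[[paste0("roads_", final)]])
  cur <- cumulative_current(cond, cores, pair_budget = config$pair_budget,
                            seed = child_seed(seed, "current"))
  note("current", "current.asc", cur$byte)

  say("exclusion layers")
  er <- config$excl_resistance
  excl1 <- build_exclusion1(list(
    list(mask = grid((lulc_final$values == 6) * 1, lulc_final$cellsize_m,
                     kind = "binary"), resistance = er[["water"]]),
    list(mask = grid((lulc_final$values == 3) * 1, lulc_final$cellsize_m,
                     kind = "binary"), resistance = er[["wetland"]]),
    list(mask = stack[[paste0("roads_", final)]],
         resistance = er[["roads"]])))
  excl2 <- build_exclusion2(excl1, imp_grid, cur$byte)
  note("exclusion", "exclusion1.asc", excl1$grid)
  note("exclusion", "exclusion2.asc", excl2$grid)

  say("diffusion-multiplier sweep")
  best_dm <- config$D_M
  if (isTRUE(config$dm_args$run %||% TRUE)) {
    sw <- dm_sweep(stack, excl = excl1,
                   start = config$dm_args$start, step = config$dm_args$step,
                   stop = config$dm_args$stop,
                   n_mc = config$dm_args$n_mc %||% 2,
                   seed = child_seed(seed, "dm"))
    best_dm <- sw$best_dm
    note("dm_sweep", "dm_sweep.csv", sw$records)
  }

  say("calibration (D_M = ", best_dm, ")")
  calib <- list()
  for (ev in c("exclusion1", "exclusion2")) {
    ex <- if (ev == "exclusion1") excl1 else excl2
    cal <- ca_calibrate(stack, excl = ex, stages = config$stages,
                        D_M = best_dm,
                        critical_slope_pct = p$critical_slope_pct,
                        seed = child_seed(seed, "calib", ev),
                        max_combos = config$max_combos)
    calib[[ev]] <- cal
    note("calibrate", paste0("calibration_", ev, ".csv"),
         cal$stages[[length(cal$stages)]])
  }

  say("prediction to ", config$predict_to)
  zones <- zone_partition(stack$slope)
  zw <- equity_weights(lulc_final, stack[[paste0("urban_", final)]], zones,
                       syn$population)
  note("scenarios", "zone_weights.csv", zw$table)
  scen <- scenario_table()
  likelihoods <- list()
  for (ev in c("exclusion1", "exclusion2")) {
    ex <- if (ev == "exclusion1") excl1 else excl2
    for (cv in c("calibrated", "compact")) {
      co <- calib[[ev]]$best
      if (cv == "compact") co <- compact_coefficients(co)
      pred <- run_prediction(
        stack[[paste0("urban_", final)]], co, stack$slope, ex,
        stack[[paste0("roads_", final)]], lulc_final,
        start_year = final, stop_year = config$predict_to,
        n_mc = config$n_mc_predict,
        seed = child_seed(seed, "predict", ev, cv))
      likelihoods[[paste(ev, cv)]] <- pred
      note("predict", paste0("likelihood_", ev, "_", cv, ".asc"),
           pred$likelihood)
    }
  }

  say("scenario selection and impact assessment")
  impacts <- list()
  selections <- list()
  for (d in seq_along(config$demand_levels)) {
    cap <- config$demand_levels[d]
    for (i in seq_len(nrow(scen))) {
      s <- scen[i, ]
      pred <- likelihoods[[paste(s$exclusion, s$coefficients)]]
      suit <- if (s$weighting == "equity-weighted")
        apply_weights(pred, zones, zw) else pred$likelihood
      sel <- select_polygons(suit, min_suit = config$min_suit,
                             min_area_ha = config$min_area_ha,
                             mode = list(type = "area_cap", cap_ha = cap,
                                         fill_cells = TRUE))
      selections[[paste(d, s$name)]] <- sel
      rec <- assess_scenario(sel, cores, imp_grid, cur$byte)
      rec <- cbind(data.frame(scenario = s$name, demand_ha = cap,
                              selected_ha = sel$total_ha), rec)
      impacts[[length(impacts) + 1]] <- rec
    }
  }
  impacts <- do.call(rbind, impacts)
  note("impact", "impacts.csv", impacts)

  say("TOPSIS ranking")
  wtab <- utils::read.csv(system.file("extdata",
                                      "scenario_criteria_weights.csv",
                                      package = "greengrowth"))
  rankings <- list()
  for (d in seq_along(config$demand_levels)) {
    cap <- config$demand_levels[d]
    sub <- impacts[impacts$demand_ha == cap, ]
    vals <- as.matrix(sub[, wtab$criterion])
    rownames(vals) <- sub$scenario
    # criteria with no information (missing or identically zero) cannot be
    # normalized and are excluded from the ranking
    keep <- colSums(is.na(vals)) == 0 & apply(vals, 2, function(x) any(x != 0))
    if (!any(keep)) {
      # nothing distinguishes the scenarios at this demand level
      cl <- stats::setNames(rep(0.5, nrow(vals)), rownames(vals))
      rk <- structure(list(closeness = cl,
                           rank = rank(-cl, ties.method = "first"),
                           order = names(cl),
                           rank_freq = NULL,
                           modal_rank = rank(-cl, ties.method = "first")),
                      class = "gg_ranking")
    } else {
      dm <- decision_matrix(vals[, keep, drop = FALSE],
                            weights = wtab$weight[keep],
                            directions = wtab$direction[keep])
      rk <- weight_perturbation(dm, n_iter = config$topsis_iters,
                                seed = child_seed(seed, "topsis", d))
    }
    rankings[[as.character(cap)]] <- rk
    note("rank", paste0("ranking_", round(cap), "ha.csv"),
         data.frame(scenario = names(rk$closeness),
                    closeness = rk$closeness, rank = rk$rank,
                    modal_rank = rk$modal_rank, row.names = NULL))
  }

  artifacts <- do.call(rbind, files)
  manifest <- list(artifacts = artifacts, rankings = rankings,
                   impacts = impacts,
                   coeffs = lapply(calib, `[[`, "best"),
                   best_dm = best_dm, seed = seed, out_dir = config$out_dir,
                   objects = list(stack = stack, mspa = seg, cores = cores,
                                  importance = imp, importance_grid = imp_grid,
                                  current = cur, excl1 = excl1, excl2 = excl2,
                                  zone_weights = zw, selections = selections,
                                  population = syn$population))
  jsonlite::write_json(
    list(seed = seed, best_dm = best_dm,
         artifacts = artifacts),
    file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE,
    digits = NA)
  say("done")
  structure(manifest, class = "gg_manifest")
}
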