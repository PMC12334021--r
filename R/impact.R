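#' Percent of high-value cells affected by a selection
#'
#' `100 * (#cells with value > threshold inside selected polygons) /
#' (#cells with value > threshold anywhere)`; 0 when no cell exceeds the
#' threshold.
#'
#' @param value_map a 0-255 [grid()] (importance or current).
#' @param selection a [select_polygons()] result.
#' @param threshold high-value cutoff (default 150).
#' @return percentage in \[0, 100\].
#' @export
percent_affected <- function(value_map, selection, threshold = 150) {
  high <- value_map$values > threshold
  denom <- sum(high)
  if (denom == 0) return(0)
  100 * sum(high & selection$labels$values > 0) / denom
}

#' Percent of core area intersecting a selection
#'
#' @param cores a [mspa_extract_cores()] result.
#' @param selection a [select_polygons()] result.
#' @return percentage of total core area inside selected polygons.
#' @export
percent_core_area_affected <- function(cores, selection) {
  core_cells <- cores$labels$values > 0
  if (!any(core_cells)) stop("no core patches")
  100 * sum(core_cells & selection$labels$values > 0) / sum(core_cells)
}

#' Mean perimeter-area ratio of a patch set
#'
#' Per patch, the perimeter is the count of cell edges adjacent to
#' non-patch cells (grid borders included) times the cell size in
#' metres; the area is in hectares; PARA = perimeter / area (m/ha).
#' PARA_MN is the unweighted mean over patches. A single 90 m cell
#' scores 360 / 0.81 = 444.4.
#'
#' @param patches labeled [grid()] (0 background) or `gg_cores` /
#'   `gg_selection`.
#' @return mean perimeter-area ratio in metres per hectare.
#' @export
para_mn <- function(patches) {
  lab <- patch_labels(patches)
  v <- lab$values
  n <- max(v)
  if (n < 1) stop("empty patch set")
  cs <- lab$cellsize_m
  cell_ha <- cs^2 / 1e4
  para <- numeric(n)
  for (k in seq_len(n)) {
    m <- v == k
    # edges facing a different value or the grid border
    per <- sum(m & shift_mat(m, 1, 0, FALSE) == FALSE) +
      sum(m & shift_mat(m, -1, 0, FALSE) == FALSE) +
      sum(m & shift_mat(m, 0, 1, FALSE) == FALSE) +
      sum(m & shift_mat(m, 0, -1, FALSE) == FALSE)
    para[k] <- per * cs / (sum(m) * cell_ha)
  }
  mean(para)
}

#' Mean Euclidean nearest-neighbour distance of a patch set
#'
#' Per patch, the minimum distance between its cell centres and those of
#' any other patch (cell-centre convention: two cells five columns apart
#' at 90 m are 450 m apart); ENN_MN is the unweighted mean.
#'
#' @param patches labeled [grid()] or `gg_cores` / `gg_selection`.
#' @return mean nearest-neighbour distance in metres.
#' @export
enn_mn <- function(patches) {
  lab <- patch_labels(patches)
  v <- lab$values
  n <- max(v)
  if (n < 2) stop("ENN needs at least two patches")
  nr <- nrow(v)
  # nearest-neighbour distances are achieved at patch boundaries (cells
  # with any 4-neighbour outside their own patch, or on the grid border)
  same <- matrix(TRUE, nr, ncol(v))
  for (o in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
    same <- same & shift_mat(v, o[1], o[2], -1) == v
  idx <- which(v > 0 & !same)
  lb <- v[idx]
  r <- ((idx - 1) %% nr) + 1; co <- ((idx - 1) %/% nr) + 1
  enn <- rep(Inf, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d2 <- outer(r[lb == i], r[lb == j], "-")^2 +
      outer(co[lb == i], co[lb == j], "-")^2
    d <- sqrt(min(d2)) * lab$cellsize_m
    enn[i] <- min(enn[i], d)
    enn[j] <- min(enn[j], d)
  }
  mean(enn)
}

patch_labels <- function(patches) {
  if (inherits(patches, "gg_cores")) patches$labels
  else if (inherits(patches, "gg_selection")) patches$labels
  else if (inherits(patches, "gg_grid")) patches
  else stop("patches must be a labeled grid, gg_cores or gg_selection")
}

#' Core patches within a buffer of the selection
#'
#' @param cores a [mspa_extract_cores()] result.
#' @param selection a [select_polygons()] result.
#' @param buffer_m Euclidean buffer distance in metres (default 1000; 0
#'   keeps only directly intersecting cores).
#' @return a `gg_cores` subset (labels renumbered consecutively).
#' @export
cores_near_selection <- function(cores, selection, buffer_m = 1000) {
  sel <- selection$labels$values > 0
  cs <- cores$labels$cellsize_m
  lab <- cores$labels$values
  if (!any(sel) || cores$n == 0) keep <- integer(0)
  else {
    d <- dist_to(sel) * cs
    keep <- sort(unique(lab[lab > 0 & d <= buffer_m]))
  }
  new_lab <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(keep)) new_lab[lab == keep[i]] <- i
  structure(list(labels = grid(new_lab, cs, kind = "continuous"),
                 area_ha = cores$area_ha[keep],
                 rep_points = cores$rep_points[keep, , drop = FALSE],
                 n = length(keep)),
            class = "gg_cores")
}

#' Assemble the impact record for one scenario
#'
#' The seven criteria of the decision matrix: percent of high-current
#' corridor cells and high-importance core cells (> 150 on the 0-255
#' scale) falling inside the selected polygons, percent of core area
#' affected, PARA_MN and ENN_MN of the cores within 1 km of the
#' selection, and PARA_MN and ENN_MN of the selected polygons
#' themselves. Metrics that need patches are `NA` when the selection or
#' buffered core set is empty or a singleton.
#'
#' @param selection a [select_polygons()] result.
#' @param cores a [mspa_extract_cores()] result.
#' @param importance 0-255 importance [grid()].
#' @param current 0-255 current [grid()].
#' @param threshold high-value cutoff (default 150).
#' @param buffer_m buffer for the core metrics (default 1000).
#' @return one-row data frame with the seven criteria.
#' @export
assess_scenario <- function(selection, cores, importance, current,
                            threshold = 150, buffer_m = 1000) {
  near <- cores_near_selection(cores, selection, buffer_m)
  safe <- function(f, x) tryCatch(f(x), error = function(e) NA_real_)
  data.frame(
    pct_affected_corridors_gt150 = percent_affected(current, selection,
                                                    threshold),
    pct_affected_cores_gt150 = percent_affected(importance, selection,
                                                threshold),
    pct_affected_core_area = percent_core_area_affected(cores, selection),
    para_mn_cores_1km = safe(para_mn, near),
    enn_mn_cores_1km = safe(enn_mn, near),
    para_mn_selected = safe(para_mn, selection),
    enn_mn_selected = safe(enn_mn, selection))
}
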