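#' Build a patch graph from core patches
#'
#' Pairwise inter-patch distances are minimum edge-to-edge Euclidean
#' distances between patch cell sets, in metres: the distance between the
#' closest cell centres minus one cell size (the gap between cell edges),
#' floored at zero for adjacent patches. Direct dispersal probabilities
#' follow a negative-exponential kernel `p_ij = exp(-theta * d_ij)` with
#' `theta = log(2) / d_half`, so a pair exactly `d_half` metres apart has
#' probability 0.5.
#'
#' @param cores a [mspa_extract_cores()] result.
#' @param A_L total landscape area in hectares.
#' @param d_half half-dispersal distance in metres (default 500).
#' @return a `gg_patch_graph`: `n`, `area_ha`, `d_m` (distance matrix),
#'   `p` (dispersal probabilities, `p_ii = 1`), `A_L`.
#' @export
build_patch_graph <- function(cores, A_L, d_half = 500) {
  stopifnot(inherits(cores, "gg_cores"), cores$n >= 1, d_half > 0)
  if (A_L < sum(cores$area_ha))
    stop("A_L (", A_L, " ha) smaller than summed patch area")
  n <- cores$n
  lab <- cores$labels$values
  cs <- cores$labels$cellsize_m
  nr <- nrow(lab)
  d <- matrix(0, n, n)
  if (n >= 2) {
    # boundary cells suffice for edge-to-edge minima
    inner <- lab > 0 & neighbour_count(lab > 0, 4) == 4
    cells <- which(lab > 0 & !inner)
    lb <- lab[cells]
    r <- ((cells - 1) %% nr) + 1; co <- ((cells - 1) %/% nr) + 1
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      ri <- r[lb == i]; ci <- co[lb == i]
      rj <- r[lb == j]; cj <- co[lb == j]
      d2 <- outer(ri, rj, "-")^2 + outer(ci, cj, "-")^2
      # gap between cell edges: closest-centre distance minus one cell
      d[i, j] <- d[j, i] <- max(0, sqrt(min(d2)) - 1) * cs
    }
  }
  theta <- log(2) / d_half
  p <- exp(-theta * d)
  diag(p) <- 1
  structure(list(n = n, area_ha = cores$area_ha, d_m = d, p = p, A_L = A_L,
                 d_half = d_half),
            class = "gg_patch_graph")
}

#' Maximum product-probability paths between all patch pairs
#'
#' For every pair, the maximum over all patch sequences of the product of
#' step probabilities, computed as shortest paths on edge weights
#' `-log(p_ij)`.
#'
#' @param graph a [build_patch_graph()] result.
#' @return an `n x n` matrix `pstar` with unit diagonal.
#' @export
max_product_paths <- function(graph) {
  stopifnot(inherits(graph, "gg_patch_graph"))
  n <- graph$n
  if (n == 1) return(matrix(1, 1, 1))
  # full graph with explicit weights: a certain step (p = 1, weight 0)
  # must stay an edge, so the adjacency-matrix constructor cannot be used
  pairs <- t(utils::combn(n, 2))
  g <- igraph::make_full_graph(n)
  w <- -log(graph$p[pairs])
  pstar <- exp(-igraph::distances(g, weights = w, algorithm = "dijkstra"))
  diag(pstar) <- 1
  pstar
}

#' Probability of connectivity
#'
#' `PC = sum_i sum_j a_i a_j pstar_ij / A_L^2`, including the `i = j`
#' terms with `pstar_ii = 1`, so a single patch covering the whole
#' landscape gives `PC = 1`.
#'
#' @param graph a [build_patch_graph()] result.
#' @param pstar matrix from [max_product_paths()] (computed if missing).
#' @return the PC index in \[0, 1\].
#' @export
compute_pc <- function(graph, pstar = max_product_paths(graph)) {
  a <- graph$area_ha
  as.numeric(t(a) %*% pstar %*% a) / graph$A_L^2
}

#' Per-patch connectivity importance (dPC)
#'
#' For each patch, PC is recomputed with the patch removed (paths
#' re-solved on the reduced graph) and
#' `dPC_i = 100 * (PC - PC_remove_i) / PC`.
#'
#' @param graph a [build_patch_graph()] result.
#' @return a `gg_importance`: `PC`, `dPC` (percent, per patch),
#'   `PC_remove`, `pstar`.
#' @export
compute_dpc <- function(graph) {
  stopifnot(inherits(graph, "gg_patch_graph"), graph$n >= 1)
  pstar <- max_product_paths(graph)
  PC <- compute_pc(graph, pstar)
  n <- graph$n
  PC_remove <- numeric(n)
  for (i in seq_len(n)) {
    if (n == 1) { PC_remove[i] <- 0; next }
    sub <- graph
    keep <- setdiff(seq_len(n), i)
    sub$n <- n - 1
    sub$area_ha <- graph$area_ha[keep]
    sub$d_m <- graph$d_m[keep, keep, drop = FALSE]
    sub$p <- graph$p[keep, keep, drop = FALSE]
    PC_remove[i] <- compute_pc(sub)
  }
  dPC <- if (PC > 0) 100 * (PC - PC_remove) / PC else rep(0, n)
  structure(list(PC = PC, dPC = dPC, PC_remove = PC_remove, pstar = pstar),
            class = "gg_importance")
}

#' Paint per-patch importance onto the core raster
#'
#' Each patch is painted with its dPC linearly rescaled to 0-255 over the
#' observed dPC range; background stays 0. When all patches share the
#' same dPC the degenerate range is painted 255 (equal importance should
#' maximally resist urbanization rather than vanish).
#'
#' @param cores a [mspa_extract_cores()] result.
#' @param result a [compute_dpc()] result.
#' @return a continuous [grid()] with values in \[0, 255\].
#' @export
rasterize_importance <- function(cores, result) {
  stopifnot(inherits(cores, "gg_cores"), inherits(result, "gg_importance"))
  if (length(result$dPC) != cores$n)
    stop("dPC not available for every patch")
  lab <- cores$labels$values
  out <- matrix(0, nrow(lab), ncol(lab))
  if (cores$n > 0) {
    rng <- range(result$dPC)
    scaled <- if (diff(rng) == 0) rep(255, cores$n)
              else (result$dPC - rng[1]) / diff(rng) * 255
    sel <- lab > 0
    out[sel] <- scaled[lab[sel]]
  }
  grid(out, cores$labels$cellsize_m, kind = "continuous")
}
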