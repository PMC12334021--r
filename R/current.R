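#' Build a conductance surface from LULC and morphological classes
#'
#' Base conductance comes from the LULC class of each cell; cells that the
#' morphological segmentation classes as connecting structures (islet,
#' branch, loop, bridge) are overridden by connector values that sit above
#' the base forest value and increase in the order
#' islet < branch < loop < bridge. The default table encodes the class
#' ordering forest > wetland > water > agriculture > road > urban > bare;
#' the exact magnitudes are configuration.
#'
#' @param lulc a categorical [grid()] with codes 1 agriculture, 2 forest,
#'   3 wetland, 4 urban, 5 bare, 6 water.
#' @param mspa a [mspa_segment()] result aligned with `lulc`, or `NULL`
#'   to skip connector overrides.
#' @param class_values named vector of conductances for
#'   `agriculture, forest, wetland, urban, bare, water, road, islet,
#'   branch, loop, bridge`.
#' @param roads optional binary [grid()]; road cells take the `road`
#'   value (roads are linear features carried outside the LULC codes).
#' @return a continuous [grid()] of per-cell conductance (class
#'   `gg_conductance` is not used; plain grid).
#' @export
build_conductance <- function(lulc, mspa = NULL,
                              class_values = default_conductance(),
                              roads = NULL) {
  stopifnot(inherits(lulc, "gg_grid"))
  need <- c("agriculture", "forest", "wetland", "urban", "bare", "water")
  if (!all(need %in% names(class_values)))
    stop("class_values must cover: ", paste(need, collapse = ", "))
  v <- lulc$values
  codes <- sort(unique(as.vector(v)))
  if (!all(codes %in% 1:6)) stop("unmapped LULC class code: ",
                                 paste(setdiff(codes, 1:6), collapse = ", "))
  lut <- class_values[c("agriculture", "forest", "wetland", "urban",
                        "bare", "water")]
  cond <- matrix(lut[v], nrow(v), ncol(v))
  if (!is.null(roads)) {
    if (is.null(class_values[["road"]])) stop("class_values lacks road value")
    cond[roads$values == 1] <- class_values[["road"]]
  }
  if (!is.null(mspa)) {
    cls <- mspa$map$values
    for (nmc in c("islet", "branch", "loop", "bridge")) {
      if (is.na(class_values[nmc])) stop("class_values lacks ", nmc)
      cond[cls == mspa_classes()[[nmc]]] <- class_values[[nmc]]
    }
  }
  grid(cond, lulc$cellsize_m, kind = "continuous")
}

#' Default conductance table
#'
#' Only the ordering is fixed by the method (forest highest among base
#' classes, connectors above forest in the order
#' islet < branch < loop < bridge); magnitudes are configurable defaults.
#'
#' @return named numeric vector.
#' @export
default_conductance <- function() {
  c(forest = 100, bridge = 250, loop = 220, branch = 200, islet = 150,
    wetland = 80, water = 60, agriculture = 40, road = 10, urban = 5,
    bare = 5)
}

# Sparse graph Laplacian of the 4-neighbour lattice restricted to
# positive-conductance cells; edge conductance = mean of the two cells.
# Returns list(idx = node cell indices, L = Laplacian, edges = data frame
# of from/to/conductance in node numbering).
lattice_laplacian <- function(cond) {
  v <- cond
  nr <- nrow(v); nc <- ncol(v)
  pos <- which(v > 0)
  node <- integer(nr * nc)
  node[pos] <- seq_along(pos)
  from <- integer(0); to <- integer(0); g <- numeric(0)
  for (o in list(c(1, 0), c(0, 1))) {
    r <- ((pos - 1) %% nr) + 1; co <- ((pos - 1) %/% nr) + 1
    r2 <- r + o[1]; c2 <- co + o[2]
    ok <- r2 <= nr & c2 <= nc
    j <- (c2[ok] - 1) * nr + r2[ok]
    keep <- v[j] > 0
    from <- c(from, node[pos[ok]][keep])
    to <- c(to, node[j][keep])
    g <- c(g, (v[pos[ok]][keep] + v[j][keep]) / 2)
  }
  n <- length(pos)
  A <- Matrix::sparseMatrix(i = c(from, to), j = c(to, from), x = c(g, g),
                            dims = c(n, n))
  L <- Matrix::Diagonal(n, Matrix::rowSums(A)) - A
  list(idx = pos, node = node, L = L,
       edges = data.frame(from = from, to = to, g = g), nr = nr, nc = nc)
}

# Component membership of every node of the lattice graph.
lap_components <- function(lap) {
  n <- nrow(lap$L)
  g <- igraph::graph_from_edgelist(as.matrix(lap$edges[, 1:2]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::components(g)$membership
}

# Per-cell current magnitude from voltages: half the sum of absolute
# branch currents incident on each node; terminals forced to exactly 1.
cell_current <- function(lap, volt, s, t) {
  ib <- abs(lap$edges$g * (volt[lap$edges$from] - volt[lap$edges$to]))
  cur <- numeric(nrow(lap$L))
  agg <- tapply(c(ib, ib), c(lap$edges$from, lap$edges$to), sum)
  cur[as.integer(names(agg))] <- agg / 2
  cur[c(s, t)] <- 1
  cur
}

#' Solve the current map between one source/ground pair
#'
#' Injects one unit of current at the source cell and removes it at the
#' ground cell on the 4-neighbour lattice whose edge conductances are the
#' mean of the two cell conductances. Per-cell current is half the sum of
#' absolute branch currents incident on the cell; the source and ground
#' cells carry exactly 1 by construction.
#'
#' @param cond a conductance [grid()] (zero = absolute barrier).
#' @param source,ground cell coordinates `c(row, col)`.
#' @return a `gg_current`: `current` (continuous [grid()]) plus the raw
#'   values.
#' @export
solve_pair_current <- function(cond, source, ground) {
  stopifnot(inherits(cond, "gg_grid"))
  v <- cond$values
  nr <- nrow(v)
  si <- (source[2] - 1) * nr + source[1]
  ti <- (ground[2] - 1) * nr + ground[1]
  if (si == ti) stop("source and ground must differ")
  if (v[si] <= 0 || v[ti] <= 0) stop("source/ground must lie on positive conductance")
  lap <- lattice_laplacian(v)
  s <- lap$node[si]; t <- lap$node[ti]
  memb <- lap_components(lap)
  if (memb[s] != memb[t])
    stop("no path: source and ground are not connected through positive conductance")
  comp <- which(memb == memb[s])
  keep <- setdiff(comp, t)               # ground the t node
  ch <- Matrix::Cholesky(lap$L[keep, keep, drop = FALSE], LDL = FALSE)
  b <- numeric(nrow(lap$L)); b[s] <- 1
  volt <- rep(0, nrow(lap$L))
  volt[keep] <- as.numeric(Matrix::solve(ch, b[keep]))
  cur <- cell_current(lap, volt, s, t)
  out <- matrix(0, nr, ncol(v))
  out[lap$idx] <- cur
  structure(list(current = grid(out, cond$cellsize_m, kind = "continuous")),
            class = "gg_current")
}

#' Cumulative current over core focal-node pairs
#'
#' Sums pairwise current maps over all pairs of patch representative
#' points (or a seeded random subsample when pairs exceed `pair_budget`),
#' then linearly rescales the sum to 0-255. The Laplacian is factored
#' once per connected component and reused for every pair in it.
#'
#' @param cond conductance [grid()].
#' @param cores a [mspa_extract_cores()] result (>= 2 patches).
#' @param pair_budget maximum number of pairs to solve (default 200).
#' @param seed integer seed for pair subsampling.
#' @return a `gg_current`: `current` (raw summed current [grid()]),
#'   `byte` (0-255 rescaled [grid()]), `n_pairs`, `n_skipped`.
#' @export
cumulative_current <- function(cond, cores, pair_budget = 200, seed = 1) {
  stopifnot(inherits(cond, "gg_grid"), inherits(cores, "gg_cores"),
            cores$n >= 2)
  v <- cond$values
  nr <- nrow(v)
  pts <- cores$rep_points
  cells <- (pts[, "col"] - 1) * nr + pts[, "row"]
  # focal cells must sit on positive conductance; nudge to the nearest
  # positive cell of the same patch if needed
  for (k in seq_along(cells)) {
    if (v[cells[k]] <= 0) {
      lab <- cores$labels$values
      cand <- which(lab == k & v > 0)
      if (length(cand) == 0) next
      r <- ((cand - 1) %% nr) + 1; co <- ((cand - 1) %/% nr) + 1
      j <- which.min((r - pts[k, "row"])^2 + (co - pts[k, "col"])^2)
      cells[k] <- cand[j]
    }
  }
  pairs <- t(utils::combn(seq_along(cells), 2))
  if (nrow(pairs) > pair_budget) {
    set.seed(child_seed(seed, "pair-subsample"))
    pairs <- pairs[sample.int(nrow(pairs), pair_budget), , drop = FALSE]
  }
  lap <- lattice_laplacian(v)
  memb <- lap_components(lap)
  nodes <- lap$node[cells]
  total <- numeric(nrow(lap$L))
  n_done <- 0
  for (cm in unique(memb[nodes[nodes > 0]])) {
    in_comp <- nodes > 0 & memb[pmax(nodes, 1)] == cm
    pp <- pairs[in_comp[pairs[, 1]] & in_comp[pairs[, 2]], , drop = FALSE]
    if (nrow(pp) == 0) next
    comp <- which(memb == cm)
    ref <- nodes[which(in_comp)[1]]
    keep <- setdiff(comp, ref)           # ground one node of the component
    ch <- Matrix::Cholesky(lap$L[keep, keep, drop = FALSE], LDL = FALSE)
    for (q in seq_len(nrow(pp))) {
      s <- nodes[pp[q, 1]]; t <- nodes[pp[q, 2]]
      b <- numeric(nrow(lap$L)); b[s] <- 1; b[t] <- b[t] - 1
      volt <- rep(0, nrow(lap$L))
      volt[keep] <- as.numeric(Matrix::solve(ch, b[keep]))
      total <- total + cell_current(lap, volt, s, t)
      n_done <- n_done + 1
    }
  }
  n_skip <- nrow(pairs) - n_done
  if (n_done == 0) stop("all focal pairs disconnected")
  out <- matrix(0, nr, ncol(v))
  out[lap$idx] <- total
  mx <- max(out)
  byte <- if (mx > 0) out / mx * 255 else out
  structure(list(current = grid(out, cond$cellsize_m, kind = "continuous"),
                 byte = grid(byte, cond$cellsize_m, kind = "continuous"),
                 n_pairs = n_done, n_skipped = n_skip),
            class = "gg_current")
}
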