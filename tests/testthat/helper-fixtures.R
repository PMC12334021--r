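# Shared fixture builders and independent oracles.

bin_grid <- function(m, cellsize = 90) grid(m, cellsize, kind = "binary")

# A mask with a 5x5 solid square centred in a 9x9 field.
square_mask <- function() {
  m <- matrix(0, 9, 9)
  m[3:7, 3:7] <- 1
  m
}

# Two 5x5 squares joined by a 1-cell-wide line.
bridged_squares <- function() {
  m <- matrix(0, 11, 18)
  m[4:8, 2:6] <- 1
  m[4:8, 11:15] <- 1
  m[6, 7:10] <- 1
  m
}

# Brute-force Euclidean core oracle: foreground cells whose distance to
# the nearest background cell (image border counts as background) exceeds
# the edge width.
brute_core <- function(mask, edge_width) {
  nr <- nrow(mask); nc <- ncol(mask)
  bg <- which(mask == 0)
  br <- ((bg - 1) %% nr) + 1; bc <- ((bg - 1) %/% nr) + 1
  out <- matrix(FALSE, nr, nc)
  for (r in 1:nr) for (co in 1:nc) {
    if (mask[r, co] != 1) next
    d_border <- min(r, co, nr - r + 1, nc - co + 1)
    d_bg <- if (length(bg)) sqrt(min((br - r)^2 + (bc - co)^2)) else Inf
    out[r, co] <- min(d_border, d_bg) > edge_width
  }
  out
}

# Exhaustive maximum product-probability over all simple paths.
brute_pstar <- function(p) {
  n <- nrow(p)
  best <- matrix(0, n, n)
  diag(best) <- 1
  rec <- function(from, target, visited, prob, start) {
    for (k in seq_len(n)) {
      if (k %in% visited) next
      pr <- prob * p[from, k]
      if (k == target) {
        if (pr > best[start, target]) best[start, target] <<- pr
      } else {
        rec(k, target, c(visited, k), pr, start)
      }
    }
  }
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) rec(i, j, i, 1, i)
  best
}

# PC by direct double sum over a pstar table.
brute_pc <- function(a, pstar, A_L) {
  s <- 0
  for (i in seq_along(a)) for (j in seq_along(a))
    s <- s + a[i] * a[j] * pstar[i, j]
  s / A_L^2
}

# A patch graph built directly from areas and a probability matrix.
toy_graph <- function(a, p, A_L) {
  structure(list(n = length(a), area_ha = a, d_m = -log(p), p = p,
                 A_L = A_L, d_half = 500),
            class = "gg_patch_graph")
}

# Dense direct solve of the lattice circuit for small grids: voltages via
# base::solve on the full Laplacian with the ground row/column removed,
# then per-cell half-sum of absolute incident branch currents.
brute_pair_current <- function(cond, source, ground) {
  nr <- nrow(cond); nc <- ncol(cond)
  idx <- which(cond > 0)
  node <- integer(nr * nc); node[idx] <- seq_along(idx)
  n <- length(idx)
  L <- matrix(0, n, n)
  edges <- NULL
  for (o in list(c(1, 0), c(0, 1))) {
    for (cell in idx) {
      r <- ((cell - 1) %% nr) + 1; co <- ((cell - 1) %/% nr) + 1
      r2 <- r + o[1]; c2 <- co + o[2]
      if (r2 > nr || c2 > nc) next
      j <- (c2 - 1) * nr + r2
      if (cond[j] <= 0) next
      g <- (cond[cell] + cond[j]) / 2
      a <- node[cell]; b <- node[j]
      L[a, a] <- L[a, a] + g; L[b, b] <- L[b, b] + g
      L[a, b] <- L[a, b] - g; L[b, a] <- L[b, a] - g
      edges <- rbind(edges, c(a, b, g))
    }
  }
  s <- node[(source[2] - 1) * nr + source[1]]
  t <- node[(ground[2] - 1) * nr + ground[1]]
  b <- numeric(n); b[s] <- 1
  keep <- setdiff(seq_len(n), t)
  v <- numeric(n)
  v[keep] <- solve(L[keep, keep], b[keep])
  cur <- numeric(n)
  for (e in seq_len(nrow(edges))) {
    ib <- abs(edges[e, 3] * (v[edges[e, 1]] - v[edges[e, 2]]))
    cur[edges[e, 1]] <- cur[edges[e, 1]] + ib
    cur[edges[e, 2]] <- cur[edges[e, 2]] + ib
  }
  cur <- cur / 2
  cur[c(s, t)] <- 1
  out <- matrix(0, nr, nc)
  out[idx] <- cur
  out
}

# Per-patch perimeter (m) and area (ha) by direct cell enumeration.
brute_para <- function(lab, cellsize) {
  n <- max(lab)
  vals <- numeric(n)
  nr <- nrow(lab); nc <- ncol(lab)
  for (k in seq_len(n)) {
    per <- 0; cells <- 0
    for (r in 1:nr) for (co in 1:nc) {
      if (lab[r, co] != k) next
      cells <- cells + 1
      for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r2 <- r + o[1]; c2 <- co + o[2]
        outside <- r2 < 1 || r2 > nr || c2 < 1 || c2 > nc
        if (outside || lab[r2, c2] != k) per <- per + 1
      }
    }
    vals[k] <- per * cellsize / (cells * cellsize^2 / 1e4)
  }
  mean(vals)
}

brute_enn <- function(lab, cellsize) {
  n <- max(lab)
  nr <- nrow(lab)
  idx <- which(lab > 0)
  r <- ((idx - 1) %% nr) + 1; co <- ((idx - 1) %/% nr) + 1
  lb <- lab[idx]
  enn <- rep(Inf, n)
  for (i in seq_along(idx)) for (j in seq_along(idx)) {
    if (lb[i] == lb[j]) next
    d <- sqrt((r[i] - r[j])^2 + (co[i] - co[j])^2) * cellsize
    enn[lb[i]] <- min(enn[lb[i]], d)
  }
  mean(enn)
}

# A labeled raster with a few random rectangular patches.
random_patches <- function(nr, nc, n_patches, seed) {
  set.seed(seed)
  lab <- matrix(0L, nr, nc)
  k <- 0
  for (i in seq_len(n_patches)) {
    h <- sample(1:3, 1); w <- sample(1:3, 1)
    r0 <- sample(1:(nr - h), 1); c0 <- sample(1:(nc - w), 1)
    patch <- lab[r0:(r0 + h), c0:(c0 + w)]
    if (any(patch != 0)) next
    k <- k + 1
    lab[r0:(r0 + h), c0:(c0 + w)] <- k
  }
  lab
}

# Small complete landscape stack for integration-style tests.
small_stack <- function(seed = 1, rows = 100, cols = 100) {
  generate_stack(landscape_params(rows = rows, cols = cols, seed = seed))
}
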