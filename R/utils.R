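# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed and a tag
#'
#' Stages, Monte-Carlo runs and growth rules each draw from their own
#' substream so that any stage can be re-run in isolation with identical
#' results. The child seed is a deterministic 31-bit hash of the master
#' seed and a character tag.
#'
#' @param seed integer master seed.
#' @param ... tag components (coerced to character and concatenated).
#' @return an integer in [0, 2^31 - 1] usable with [set.seed()].
#' @export
child_seed <- function(seed, ...) {
  tag <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- 0
  for (k in utf8ToInt(tag)) h <- (h * 131 + k) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

# Shift a matrix by (dr, dc), padding with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Offsets of the 8- or 4-neighbourhood.
neighbour_offsets <- function(connectivity = 8) {
  if (connectivity == 4) {
    cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  } else {
    cbind(dr = rep(-1:1, each = 3), dc = rep(-1:1, 3))[-5, , drop = FALSE]
  }
}

# Count neighbours of each cell that are TRUE in `mask` (logical matrix).
neighbour_count <- function(mask, connectivity = 8) {
  m <- mask * 1
  off <- neighbour_offsets(connectivity)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(off))) out <- out + shift_mat(m, off[i, 1], off[i, 2])
  out
}

# Connected-component labelling of a logical matrix via the lattice graph.
# Returns an integer matrix: 0 = background, 1..k = component labels
# (labels are consecutive, ordered by first cell in column-major order).
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0) return(lab)
  pos <- integer(nr * nc)
  pos[idx] <- seq_along(idx)
  off <- neighbour_offsets(connectivity)
  # keep each undirected edge once
  off <- off[off[, 1] > 0 | (off[, 1] == 0 & off[, 2] > 0), , drop = FALSE]
  r <- ((idx - 1) %% nr) + 1
  co <- ((idx - 1) %/% nr) + 1
  efrom <- integer(0); eto <- integer(0)
  for (i in seq_len(nrow(off))) {
    r2 <- r + off[i, 1]; c2 <- co + off[i, 2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    j <- (c2[ok] - 1) * nr + r2[ok]
    keep <- mask[j]
    efrom <- c(efrom, pos[idx[ok]][keep])
    eto <- c(eto, pos[j][keep])
  }
  g <- igraph::graph_from_edgelist(cbind(efrom, eto), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  # relabel so component ids increase with first occurrence
  first <- tapply(seq_along(comp), comp, min)
  relab <- integer(length(first))
  relab[order(first)] <- seq_along(first)
  lab[idx] <- relab[comp]
  lab
}

# Euclidean distance (in cells) of every cell to the nearest TRUE cell of
# `target`; Inf where no target exists. Wraps EBImage::distmap with a
# 1-cell pad; `outside` controls whether beyond-the-grid counts as target
# (TRUE for distance-to-background in the morphological segmentation,
# where off-map is background by convention).
dist_to <- function(target, outside = FALSE) {
  if (!any(target) && !outside)
    return(matrix(Inf, nrow(target), ncol(target)))
  nr <- nrow(target); nc <- ncol(target)
  pad <- matrix(if (outside) 0 else 1, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- 1 - (target * 1)
  d <- EBImage::distmap(pad, metric = "euclidean")
  matrix(d, nr + 2, nc + 2)[2:(nr + 1), 2:(nc + 1)]
}

# Morphological dilation by k iterations of the 4/8-neighbourhood
# (Chebyshev/Manhattan balls). Includes the mask itself.
dilate <- function(mask, k = 1, connectivity = 8) {
  out <- mask
  for (i in seq_len(k)) out <- out | neighbour_count(out, connectivity) > 0
  out
}

# Row/column coordinate matrices.
row_index <- function(nr, nc) matrix(rep(seq_len(nr), nc), nr, nc)
col_index <- function(nr, nc) matrix(rep(seq_len(nc), each = nr), nr, nc)

`%||%` <- function(a, b) if (is.null(a)) b else a
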