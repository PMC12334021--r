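#' Morphological segmentation of a green-space mask
#'
#' Classifies every foreground cell of a binary mask into one of seven
#' morphological classes, in the spirit of morphological spatial pattern
#' analysis:
#'
#' * **core** — foreground whose Euclidean distance to background exceeds
#'   `edge_width` cells;
#' * **islet** — foreground component containing no core;
#' * **edge** — non-core foreground within the `edge_width`-fold
#'   8-neighbour dilation of a core, bordering the outer background;
#' * **perforation** — as edge, but bordering a hole enclosed by the
#'   component;
#' * **bridge** — connector component touching two or more distinct core
#'   components;
#' * **loop** — connector attaching to the same core component at two or
#'   more separate places;
#' * **branch** — connector attached at exactly one place.
#'
#' Connector subdivision uses component analysis of the non-core
#' foreground (which core components a connector touches, and at how many
#' distinct attachment regions) rather than geodesic skeletons; this is a
#' deliberate simplification that matches the canonical classes on
#' corridor-like structures at coarse resolution.
#'
#' Class codes in the output map: 0 background, 1 core, 2 islet,
#' 3 perforation, 4 edge, 5 loop, 6 bridge, 7 branch (see
#' [mspa_classes()]).
#'
#' @param mask a binary [grid()] (1 = green space).
#' @param edge_width positive integer edge width in cells (default 1).
#' @param connectivity 4 or 8 (default 8), used for component labelling.
#' @return a `gg_mspa` object: a categorical [grid()] of class codes with
#'   fields `edge_width` and `connectivity`.
#' @export
mspa_segment <- function(mask, edge_width = 1, connectivity = 8) {
  stopifnot(inherits(mask, "gg_grid"), edge_width >= 1,
            connectivity %in% c(4, 8))
  v <- mask$values
  if (!all(v %in% c(0, 1))) stop("mask must be binary")
  fg <- v == 1
  nr <- nrow(fg); nc <- ncol(fg)
  code <- matrix(0L, nr, nc)
  if (any(fg)) {
    d_bg <- dist_to(!fg, outside = TRUE)   # off-map counts as background
    core <- fg & d_bg > edge_width
    comp <- label_components(fg, connectivity)
    core_comp <- unique(comp[core])
    islet <- fg & !(comp %in% core_comp)

    # split background into outer (touching the border) and holes
    bgcomp <- label_components(!fg, connectivity = 4)
    border_ids <- unique(c(bgcomp[1, ], bgcomp[nr, ], bgcomp[, 1], bgcomp[, nc]))
    hole <- !fg & !(bgcomp %in% setdiff(border_ids, 0L))

    boundary <- fg & !core & !islet & dilate(core, edge_width)
    near_hole <- dilate(hole, edge_width)
    near_outer <- dilate(!fg & !hole, edge_width)
    perforation <- boundary & near_hole & !near_outer
    edge <- boundary & !perforation

    connector <- fg & !core & !islet & !boundary
    code[edge] <- 4L
    code[perforation] <- 3L
    code[core] <- 1L
    code[islet] <- 2L

    if (any(connector)) {
      core_lab <- label_components(core, connectivity)
      # assign each boundary (edge/perforation) cell to its nearest core
      # component so connectors can be attributed through the edge ring
      conn_lab <- label_components(connector, connectivity)
      off <- neighbour_offsets(8)
      for (k in seq_len(max(conn_lab))) {
        cells <- which(conn_lab == k)
        r <- ((cells - 1) %% nr) + 1
        co <- ((cells - 1) %/% nr) + 1
        # attachment cells: non-connector foreground 8-adjacent to this
        # connector component
        att <- matrix(FALSE, nr, nc)
        for (i in seq_len(nrow(off))) {
          r2 <- r + off[i, 1]; c2 <- co + off[i, 2]
          ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
          att[cbind(r2[ok], c2[ok])] <- TRUE
        }
        att <- att & fg & conn_lab == 0 & !islet
        natt <- sum(att)
        if (natt == 0) { code[cells] <- 7L; next }   # free-floating: branch
        # which core components does it reach (via touched cells' nearest core)
        att_idx <- which(att)
        touched <- core_lab[att_idx]
        zero <- touched == 0
        if (any(zero)) {
          near <- nearest_label(core_lab, att_idx[zero])
          touched[zero] <- near
        }
        touched <- unique(touched[touched > 0])
        if (length(touched) >= 2) code[cells] <- 6L        # bridge
        else {
          # loop vs branch: number of separate attachment regions
          n_regions <- max(label_components(att, 8))
          code[cells] <- if (n_regions >= 2) 5L else 7L
        }
      }
    }
  }
  g <- grid(code, mask$cellsize_m, kind = "categorical", codes = 0:7)
  structure(list(map = g, edge_width = edge_width,
                 connectivity = connectivity),
            class = "gg_mspa")
}

# For each index in `idx` (cells with label 0), the label of the nearest
# labelled cell (Euclidean, ties by first in column-major order).
nearest_label <- function(lab, idx) {
  pos <- which(lab > 0)
  if (length(pos) == 0) return(rep(0L, length(idx)))
  nr <- nrow(lab)
  pr <- ((pos - 1) %% nr) + 1; pc <- ((pos - 1) %/% nr) + 1
  qr <- ((idx - 1) %% nr) + 1; qc <- ((idx - 1) %/% nr) + 1
  vapply(seq_along(idx), function(i) {
    d2 <- (pr - qr[i])^2 + (pc - qc[i])^2
    lab[pos[which.min(d2)]]
  }, integer(1))
}

#' Morphological class codes
#'
#' @return named integer vector mapping class names to raster codes.
#' @export
mspa_classes <- function() {
  c(background = 0L, core = 1L, islet = 2L, perforation = 3L, edge = 4L,
    loop = 5L, bridge = 6L, branch = 7L)
}

#' @export
print.gg_mspa <- function(x, ...) {
  tab <- table(factor(x$map$values, levels = mspa_classes(),
                      labels = names(mspa_classes())))
  cat(sprintf("<gg_mspa> edge_width %d, %d-connectivity\n",
              x$edge_width, x$connectivity))
  print(tab)
  invisible(x)
}

#' Extract core patches from a segmentation
#'
#' Unions the included classes (by default core, edge and perforation —
#' the classes retained for protection), labels connected components, and
#' reports per-patch areas and a representative point (the patch cell
#' closest to the patch centroid, used later as a circuit focal node).
#'
#' @param mspa a [mspa_segment()] result.
#' @param include character vector of class names (default
#'   `c("core", "edge", "perforation")`).
#' @return a `gg_cores` object: `labels` (integer [grid()], 0 background),
#'   `area_ha` (per-patch areas), `rep_points` (matrix of row/col), `n`.
#' @export
mspa_extract_cores <- function(mspa, include = c("core", "edge", "perforation")) {
  stopifnot(inherits(mspa, "gg_mspa"), length(include) >= 1)
  codes <- mspa_classes()[include]
  if (anyNA(codes)) stop("unknown class name in include")
  sel <- matrix(mspa$map$values %in% codes,
                nrow(mspa$map$values), ncol(mspa$map$values))
  lab <- label_components(sel, mspa$connectivity)
  n <- max(lab)
  cell_ha <- mspa$map$cellsize_m^2 / 1e4
  area <- numeric(n)
  reps <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("row", "col")))
  if (n > 0) {
    nr <- nrow(lab)
    idx <- which(lab > 0)
    lb <- lab[idx]
    r <- ((idx - 1) %% nr) + 1; co <- ((idx - 1) %/% nr) + 1
    area <- as.numeric(tabulate(lb, n)) * cell_ha
    for (k in seq_len(n)) {
      sel_k <- lb == k
      cr <- mean(r[sel_k]); cc <- mean(co[sel_k])
      j <- which.min((r[sel_k] - cr)^2 + (co[sel_k] - cc)^2)
      reps[k, ] <- c(r[sel_k][j], co[sel_k][j])
    }
  }
  structure(list(labels = grid(lab, mspa$map$cellsize_m, kind = "continuous"),
                 area_ha = area, rep_points = reps, n = n),
            class = "gg_cores")
}

#' @export
print.gg_cores <- function(x, ...) {
  cat(sprintf("<gg_cores> %d patches, %.2f ha total\n", x$n, sum(x$area_ha)))
  invisible(x)
}
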